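#' Sliding windows along one chromosome
#'
#' Windows of `window_size` bp advanced by `step` bp: starts at
#' 1, 1+step, 1+2*step, ..., emitted while the start lies on the
#' chromosome; trailing windows are truncated at the chromosome end.
#' Each window also carries its `center`, the coordinate its fitted value
#' is attributed to (a multiple of the step when `window_size/2` is, so
#' reported region endpoints land on the step grid).
#'
#' @param chrom_length chromosome length in bp.
#' @param window_size window width in bp (default 1 Mb).
#' @param step advance in bp (default 10 kb); must not exceed
#'   `window_size`.
#' @return data frame with `start`, `end` (1-based inclusive), `center`;
#'   attributes `window_size`, `step`.
#' @export
#' @examples
#' w <- make_windows(2e6, 1e6, 1e4)
#' nrow(w)  # 200
make_windows <- function(chrom_length, window_size = 1e6, step = 1e4) {
  if (!(window_size >= step && step > 0))
    stop("need window_size >= step > 0")
  if (chrom_length < 1) stop("chrom_length must be positive")
  starts <- seq(1, chrom_length, by = step)
  out <- data.frame(
    start = starts,
    end = pmin(starts + window_size - 1, chrom_length),
    # nominal center, uncapped so centers stay distinct and grid-aligned
    # for trailing truncated windows
    center = starts - 1 + window_size / 2
  )
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  out
}

# multi-chromosome window table
.genome_windows <- function(chrom_lengths, window_size = 1e6, step = 1e4) {
  out <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    w <- make_windows(chrom_lengths[[ch]], window_size, step)
    cbind(chrom = ch, w, stringsAsFactors = FALSE)
  }))
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  out
}

#' Fit a per-site statistic in sliding windows
#'
#' `mean`: the unweighted average of the statistic over the sites falling
#' in each window. `distance_weighted`: a tricube-kernel weighted average
#' with weights `(1 - (d/h)^3)^3`, `d` the distance from the site to the
#' window center and `h = window_size / 2`, giving sites near the window
#' center more influence (a distance-based fit for the powered
#' Euclidean-distance track). Windows containing no sites are marked
#' missing (`NA`), never zero-filled.
#'
#' @param sites a site table carrying the statistic column, sorted by
#'   position within each chromosome.
#' @param statistic column name to fit (e.g. `"delta_snp_index"`,
#'   `"ed_powered"`).
#' @param windows a window table from [make_windows()] (with or without a
#'   `chrom` column) whose `window_size`/`step` attributes are set.
#' @param fit_method `"mean"` or `"distance_weighted"`.
#' @return A `scan_track` data frame: `chrom`, `window_start`,
#'   `window_end`, `center`, `n_sites`, `fitted`; attributes `statistic`,
#'   `fit_method`, `window_size`, `step`.
#' @export
fit_track <- function(sites, statistic, windows,
                      fit_method = c("mean", "distance_weighted")) {
  fit_method <- match.arg(fit_method)
  stopifnot(statistic %in% names(sites))
  ws <- attr(windows, "window_size")
  if (is.null(ws)) stop("windows must come from make_windows()")
  if (is.null(windows$chrom)) {
    windows$chrom <- if (nrow(sites)) sites$chrom[1] else "chr1"
  }
  h <- ws / 2

  res <- lapply(unique(windows$chrom), function(ch) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    s <- sites[sites$chrom == ch, , drop = FALSE]
    pos <- s$pos
    if (is.unsorted(pos)) stop("sites must be sorted by position")
    x <- s[[statistic]]
    lo <- findInterval(w$start - 0.5, pos) + 1L
    hi <- findInterval(w$end + 0.5 - 1e-9, pos)
    n <- pmax(hi - lo + 1L, 0L)
    fitted <- rep(NA_real_, nrow(w))
    for (i in which(n > 0)) {
      xi <- x[lo[i]:hi[i]]
      if (fit_method == "mean") {
        fitted[i] <- mean(xi)
      } else {
        d <- abs(pos[lo[i]:hi[i]] - w$center[i])
        wt <- (1 - pmin(d / h, 1)^3)^3
        fitted[i] <- if (sum(wt) > 0) sum(wt * xi) / sum(wt) else mean(xi)
      }
    }
    data.frame(chrom = ch, window_start = w$start, window_end = w$end,
               center = w$center, n_sites = n, fitted = fitted,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "statistic") <- statistic
  attr(out, "fit_method") <- fit_method
  attr(out, "window_size") <- ws
  attr(out, "step") <- attr(windows, "step")
  class(out) <- c("scan_track", "data.frame")
  out
}

#' Monte-Carlo null envelope for the delta SNP-index
#'
#' Simulates the no-QTL null of a bulked-segregant F2 design: in each
#' replicate, each bulk's pooled allele frequency is the mean of
#' `2 * bulk_size` Bernoulli(1/2) draws (free Mendelian segregation among
#' the pooled chromosomes), read counts are Binomial(depth, frequency),
#' and the delta SNP-index is the difference of the two read fractions.
#' The envelope at each level is the corresponding quantile of
#' `|delta|`.
#'
#' @param depth_aa,depth_ab sequencing depths of the L- and S-pool.
#' @param bulk_size individuals per bulk.
#' @param levels envelope levels in (0, 1), ascending.
#' @param reps Monte-Carlo replicates (at least 1,000).
#' @param seed optional seed; the caller's RNG stream is left untouched
#'   when it is supplied.
#' @return list of class `threshold_set`: `method = "null_envelope"`,
#'   `levels`, `values` (one threshold per level), plus the simulation
#'   parameters.
#' @export
null_envelope_delta <- function(depth_aa, depth_ab, bulk_size,
                                levels = c(0.90, 0.95, 0.99),
                                reps = 10000, seed = NULL) {
  stopifnot(depth_aa >= 1, depth_ab >= 1, bulk_size >= 1,
            all(levels > 0 & levels < 1), !is.unsorted(levels))
  if (reps < 1000) stop("reps too small: need at least 1,000")
  delta <- .with_seed(seed, {
    f_aa <- rbinom(reps, 2 * bulk_size, 0.5) / (2 * bulk_size)
    f_ab <- rbinom(reps, 2 * bulk_size, 0.5) / (2 * bulk_size)
    rbinom(reps, depth_aa, f_aa) / depth_aa -
      rbinom(reps, depth_ab, f_ab) / depth_ab
  })
  structure(list(
    method = "null_envelope",
    levels = levels,
    values = setNames(quantile(abs(delta), levels, names = FALSE, type = 7),
                      paste0("q", levels * 100)),
    depth_aa = depth_aa, depth_ab = depth_ab,
    bulk_size = bulk_size, reps = reps
  ), class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Threshold set (", x$method, ")\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Median-plus-k-standard-deviations threshold for a fitted track
#'
#' The genome-wide association threshold used for the powered
#' Euclidean-distance track: the median of all non-missing fitted window
#' values plus `n_sd` sample standard deviations (n-1 denominator).
#'
#' @param fitted_values fitted window values; `NA` (empty windows) are
#'   excluded.
#' @param n_sd number of standard deviations to add (default 3).
#' @return scalar threshold.
#' @export
#' @examples
#' ed_threshold_median_sd(c(0, 2))  # 1 + 3 * sqrt(2)
ed_threshold_median_sd <- function(fitted_values, n_sd = 3) {
  v <- fitted_values[!is.na(fitted_values)]
  if (length(v) < 2) stop("need at least 2 non-missing fitted values")
  median(v) + n_sd * sd(v)
}

#' Empirical-quantile threshold for a fitted track
#'
#' The `q`-quantile of the non-missing fitted window values, with linear
#' interpolation between order statistics (R quantile type 7). Used to
#' refine broad associated regions to their strongest windows.
#'
#' @param fitted_values fitted window values; `NA` excluded.
#' @param q quantile level, strictly inside (0, 1) (default 0.99).
#' @return scalar threshold.
#' @export
ed_threshold_quantile <- function(fitted_values, q = 0.99) {
  if (!(length(q) == 1 && q > 0 && q < 1))
    stop("q must lie strictly inside (0, 1)")
  v <- fitted_values[!is.na(fitted_values)]
  if (length(v) == 0) stop("no non-missing fitted values")
  quantile(v, q, names = FALSE, type = 7)
}
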