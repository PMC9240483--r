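#' Call above-threshold association regions from a fitted track
#'
#' Maximal runs of consecutive windows with `fitted >= threshold` are
#' merged into one region. A region spans the center coordinates of the
#' windows in its run, so region endpoints sit on the window grid, a
#' single-window run yields a point-like region, and runs separated by
#' even one below-threshold window stay distinct (no gap bridging) and
#' never overlap. Missing windows (no sites) count as below threshold.
#'
#' @param track a `scan_track` from [fit_track()].
#' @param threshold finite scalar, or one value per window.
#' @param method_label label stored in the result (`"snp_index"`, `"ed"`,
#'   ...); defaults to the track's statistic.
#' @param two_sided compare `|fitted|` against the threshold (use for the
#'   signed delta SNP-index track).
#' @return An `association_regions` data frame: `chrom`, `start_bp`,
#'   `end_bp`, `method`, `threshold_used`, `peak_value`, `n_windows`,
#'   `length_mb`.
#' @export
call_regions <- function(track, threshold,
                         method_label = attr(track, "statistic"),
                         two_sided = FALSE) {
  if (!all(is.finite(threshold))) stop("threshold must be finite")
  stopifnot(length(threshold) %in% c(1L, nrow(track)))
  fitted <- if (two_sided) abs(track$fitted) else track$fitted
  above <- !is.na(fitted) & fitted >= threshold
  thr_scalar <- if (length(threshold) == 1) threshold else NA_real_

  pieces <- lapply(unique(track$chrom), function(ch) {
    sel <- track$chrom == ch
    ab <- above[sel]
    if (!any(ab)) return(NULL)
    ctr <- track$center[sel]
    fit <- fitted[sel]
    r <- rle(ab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    data.frame(
      chrom = ch,
      start_bp = ctr[starts[runs]],
      end_bp = ctr[ends[runs]],
      method = method_label,
      threshold_used = thr_scalar,
      peak_value = vapply(runs, function(k)
        max(fit[starts[k]:ends[k]]), 0.0),
      n_windows = r$lengths[runs],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), method = character(0),
                      threshold_used = numeric(0), peak_value = numeric(0),
                      n_windows = integer(0), stringsAsFactors = FALSE)
  out$length_mb <- (out$end_bp - out$start_bp) / 1e6
  class(out) <- c("association_regions", "data.frame")
  out
}

#' Region length in megabases
#'
#' The reporting convention is `(end - start) / 1e6` on the window-grid
#' endpoints — the convention that reproduces published BSA-seq interval
#' lengths from their printed endpoints — so a point-like single-window
#' region has length 0.
#'
#' @param region a one-or-more-row region data frame with `start_bp`,
#'   `end_bp` (or a list with those fields).
#' @return numeric length(s) in Mb.
#' @export
#' @examples
#' region_length_mb(list(start_bp = 10880000, end_bp = 36410000))  # 25.53
region_length_mb <- function(region) {
  (region$end_bp - region$start_bp) / 1e6
}

# each track's regions must be sorted and pairwise non-overlapping
.check_region_list <- function(r, label) {
  for (ch in unique(r$chrom)) {
    x <- r[r$chrom == ch, , drop = FALSE]
    if (is.unsorted(x$start_bp, strictly = TRUE) && nrow(x) > 1)
      stop(label, ": regions must be sorted by start within chromosome")
    if (nrow(x) > 1 && any(x$start_bp[-1] <= x$end_bp[-nrow(x)]))
      stop(label, ": regions overlap within chromosome")
    if (any(x$start_bp > x$end_bp)) stop(label, ": start_bp > end_bp")
  }
  invisible(r)
}

#' Intersect two tracks' association regions
#'
#' Standard closed-interval intersection per chromosome; commutative and
#' idempotent. Inputs must each be internally sorted and non-overlapping.
#'
#' @param regions_a,regions_b `association_regions` data frames.
#' @return An `association_regions` data frame labeled
#'   `method = "intersection"`.
#' @export
intersect_tracks <- function(regions_a, regions_b) {
  .check_region_list(regions_a, "regions_a")
  .check_region_list(regions_b, "regions_b")
  chroms <- intersect(unique(regions_a$chrom), unique(regions_b$chrom))
  pieces <- lapply(chroms, function(ch) {
    a <- regions_a[regions_a$chrom == ch, ]
    b <- regions_b[regions_b$chrom == ch, ]
    ia <- IRanges::IRanges(start = a$start_bp, end = a$end_bp)
    ib <- IRanges::IRanges(start = b$start_bp, end = b$end_bp)
    ov <- IRanges::intersect(ia, ib)
    if (length(ov) == 0) return(NULL)
    data.frame(chrom = ch, start_bp = IRanges::start(ov),
               end_bp = IRanges::end(ov), method = "intersection",
               threshold_used = NA_real_, peak_value = NA_real_,
               n_windows = NA_integer_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), method = character(0),
                      threshold_used = numeric(0), peak_value = numeric(0),
                      n_windows = integer(0), stringsAsFactors = FALSE)
  out$length_mb <- (out$end_bp - out$start_bp) / 1e6
  class(out) <- c("association_regions", "data.frame")
  out
}

#' Count genes overlapping a region
#'
#' A gene is counted when its interval overlaps the region by at least
#' one base pair (closed 1-based intervals on both sides); a gene starting
#' exactly one base past the region end is not counted.
#'
#' @param region a single region (one-row data frame or list with `chrom`,
#'   `start_bp`, `end_bp`).
#' @param gene_intervals data frame from [read_gene_intervals()].
#' @return integer count.
#' @export
count_genes <- function(region, gene_intervals) {
  if (is.null(gene_intervals) || nrow(gene_intervals) == 0) return(0L)
  sum(gene_intervals$chrom == region$chrom[[1]] &
        gene_intervals$start <= region$end_bp[[1]] &
        gene_intervals$end >= region$start_bp[[1]])
}

# vectorised gene counts for a whole region table
.region_gene_counts <- function(regions, gene_intervals) {
  vapply(seq_len(nrow(regions)), function(i)
    count_genes(regions[i, ], gene_intervals), 0L)
}
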