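#' Configuration for a full BSA-seq scan
#'
#' Assembles and validates all pipeline parameters. Input is either a VCF
#' (`vcf` plus `sample_roles`) or, when `vcf` is `NULL`, a simulated
#' experiment drawn from `sim` — which is how the pipeline validates
#' itself against known ground truth.
#'
#' @param vcf path to a four-sample VCF, or `NULL` to simulate.
#' @param gff optional GFF3 annotation for per-region gene counts.
#' @param sample_roles named vector mapping the roles `parent_L`,
#'   `parent_S`, `bulk_L`, `bulk_S` to the VCF sample names.
#' @param sim a [sim_config()] used when `vcf` is `NULL`.
#' @param out_dir optional directory for artifacts (ledgers, tracks,
#'   thresholds, regions, manifest); nothing is written when `NULL`.
#' @param window_size,step sliding-window geometry in bp.
#' @param fit_delta,fit_ed fit method per track (`"mean"` /
#'   `"distance_weighted"`).
#' @param ed_exponent exponent applied to the Euclidean distance before
#'   fitting (default 2, the squared distance).
#' @param envelope_levels,envelope_reps Monte-Carlo null-envelope levels
#'   and replicate count for the delta SNP-index thresholds.
#' @param envelope_region_level envelope level used to call delta regions
#'   (default 0.99).
#' @param ed_quantile empirical quantile used to call (refined) ED
#'   regions (default 0.99).
#' @param ed_n_sd standard deviations above the median for the broad ED
#'   threshold (default 3).
#' @param bulk_size bulk size for the null envelope; defaults to the
#'   simulator's when simulating.
#' @param min_depth per-bulk depth floor used by both filters.
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   absent they are taken from the simulation or rounded up from the
#'   largest observed position.
#' @param seed master seed; one RNG stream per stage is derived from it,
#'   so e.g. changing `envelope_reps` does not perturb the simulated data.
#' @return list of class `bsa_scan_config`.
#' @export
bsa_scan_config <- function(vcf = NULL, gff = NULL,
                            sample_roles = c(parent_L = "parent_L",
                                             parent_S = "parent_S",
                                             bulk_L = "bulk_L",
                                             bulk_S = "bulk_S"),
                            sim = sim_config(),
                            out_dir = NULL,
                            window_size = 1e6, step = 1e4,
                            fit_delta = "mean",
                            fit_ed = "distance_weighted",
                            ed_exponent = 2,
                            envelope_levels = c(0.90, 0.95, 0.99),
                            envelope_reps = 10000,
                            envelope_region_level = 0.99,
                            ed_quantile = 0.99,
                            ed_n_sd = 3,
                            bulk_size = NULL,
                            min_depth = 4,
                            chrom_lengths = NULL,
                            seed = 1L) {
  stopifnot(window_size >= step, step > 0,
            all(envelope_levels > 0 & envelope_levels < 1),
            envelope_region_level %in% envelope_levels ||
              (envelope_region_level > 0 && envelope_region_level < 1),
            ed_quantile > 0, ed_quantile < 1, ed_exponent >= 1)
  if (!is.null(vcf) && !file.exists(vcf)) stop("vcf not found: ", vcf)
  if (!is.null(gff) && !file.exists(gff)) stop("gff not found: ", gff)
  if (is.null(bulk_size))
    bulk_size <- if (is.null(vcf)) sim$bulk_size else 50L
  structure(list(
    vcf = vcf, gff = gff, sample_roles = sample_roles, sim = sim,
    out_dir = out_dir, window_size = window_size, step = step,
    fit_delta = fit_delta, fit_ed = fit_ed, ed_exponent = ed_exponent,
    envelope_levels = envelope_levels, envelope_reps = envelope_reps,
    envelope_region_level = envelope_region_level,
    ed_quantile = ed_quantile, ed_n_sd = ed_n_sd,
    bulk_size = as.integer(bulk_size), min_depth = min_depth,
    chrom_lengths = chrom_lengths, seed = as.integer(seed)
  ), class = "bsa_scan_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [bsa_scan_config()]; a `sim`
#' block maps onto [sim_config()].
#'
#' @param path YAML file path.
#' @return list of class `bsa_scan_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$sample_roles)) y$sample_roles <- unlist(y$sample_roles)
  if (!is.null(y$chrom_lengths)) y$chrom_lengths <- unlist(y$chrom_lengths)
  do.call(bsa_scan_config, y)
}

#' Run the full two-track BSA-seq scan
#'
#' Executes simulate/read -> filter (both tracks) -> per-site statistics
#' -> sliding-window fitting -> thresholds -> region calling ->
#' intersection, deterministically under the configured seed. Delta
#' SNP-index regions are called two-sided against the Monte-Carlo null
#' envelope; powered-ED regions against the empirical quantile threshold
#' (with the broad median-plus-SD threshold also reported); the candidate
#' set is the intersection of the two tracks' regions.
#'
#' @param config a [bsa_scan_config()].
#' @return list of class `bsa_scan`: `sites_n`, `truth` (when simulated),
#'   `ledgers`, `tracks` (`delta`, `ed`), `thresholds`, `regions`
#'   (`snp_index`, `ed_broad`, `ed`, `intersection`), `genes` (when a GFF
#'   was given), and `manifest`.
#' @export
run_full_scan <- function(config) {
  stopifnot(inherits(config, "bsa_scan_config"))
  truth <- NULL
  if (is.null(config$vcf)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- .derive_seed(config$seed, 1L)
    sim <- simulate_bulk_sites(sim_cfg)
    sites <- sim$sites
    truth <- sim$truth
  } else {
    sites <- read_bulk_vcf(config$vcf, config$sample_roles)
  }
  if (nrow(sites) == 0) stop("stage variant_io: no usable sites")

  chrom_lengths <- config$chrom_lengths
  if (is.null(chrom_lengths)) chrom_lengths <- attr(sites, "chrom_lengths")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(sites$pos, sites$chrom, function(p)
      ceiling(max(p) / config$step) * config$step)
    chrom_lengths <- setNames(as.numeric(chrom_lengths),
                              names(chrom_lengths))
  }

  f_snp <- apply_filters(sites, "snp_index", config$min_depth)
  f_ed <- apply_filters(sites, "ed", config$min_depth)

  snp_sites <- site_statistics(f_snp$sites, k = config$ed_exponent)
  ed_sites <- site_statistics(f_ed$sites, k = config$ed_exponent)

  windows <- .genome_windows(chrom_lengths, config$window_size, config$step)
  delta_track <- fit_track(snp_sites, "delta_snp_index", windows,
                           config$fit_delta)
  ed_track <- fit_track(ed_sites, "ed_powered", windows, config$fit_ed)

  envelope <- null_envelope_delta(
    depth_aa = max(1, round(mean(snp_sites$depth_aa))),
    depth_ab = max(1, round(mean(snp_sites$depth_ab))),
    bulk_size = config$bulk_size,
    levels = config$envelope_levels,
    reps = config$envelope_reps,
    seed = .derive_seed(config$seed, 2L)
  )
  lev_i <- match(config$envelope_region_level, envelope$levels)
  delta_thr <- unname(envelope$values[lev_i])
  ed_thr_broad <- ed_threshold_median_sd(ed_track$fitted, config$ed_n_sd)
  ed_thr_q <- ed_threshold_quantile(ed_track$fitted, config$ed_quantile)

  snp_regions <- call_regions(delta_track, delta_thr,
                              method_label = "snp_index", two_sided = TRUE)
  ed_regions_broad <- call_regions(ed_track, ed_thr_broad,
                                   method_label = "ed_broad")
  ed_regions <- call_regions(ed_track, ed_thr_q, method_label = "ed")
  intersection <- intersect_tracks(snp_regions, ed_regions)

  genes <- NULL
  if (!is.null(config$gff)) {
    genes <- read_gene_intervals(config$gff)
    for (nm in c("snp_regions", "ed_regions_broad", "ed_regions",
                 "intersection")) {
      r <- get(nm)
      r$gene_count <- .region_gene_counts(r, genes)
      assign(nm, r)
    }
  }

  result <- structure(list(
    sites_n = nrow(sites),
    truth = truth,
    ledgers = list(snp_index = f_snp$ledger, ed = f_ed$ledger),
    tracks = list(delta = delta_track, ed = ed_track),
    thresholds = list(delta_envelope = envelope,
                      ed_median_sd = ed_thr_broad,
                      ed_quantile = ed_thr_q),
    regions = list(snp_index = snp_regions, ed_broad = ed_regions_broad,
                   ed = ed_regions, intersection = intersection),
    genes = genes,
    manifest = list(
      package_version = as.character(utils::packageVersion("bsascan")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      window_size = config$window_size, step = config$step,
      fit_delta = config$fit_delta, fit_ed = config$fit_ed,
      ed_exponent = config$ed_exponent,
      envelope = list(levels = config$envelope_levels,
                      reps = config$envelope_reps),
      input = if (is.null(config$vcf)) "simulated" else config$vcf
    )
  ), class = "bsa_scan")

  if (!is.null(config$out_dir)) .write_scan_artifacts(result, config)
  result
}

.write_scan_artifacts <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$out_dir, ...)
  jsonlite::write_json(
    lapply(result$ledgers, function(l)
      list(track = l$track, total_in = l$total_in,
           removed_by_reason = as.list(l$removed_by_reason),
           retained = l$retained)),
    p("filter_ledgers.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(result$tracks))
    write.table(result$tracks[[nm]], p(paste0("track_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  thr <- result$thresholds
  jsonlite::write_json(
    list(delta_envelope = as.list(thr$delta_envelope$values),
         ed_median_sd = thr$ed_median_sd,
         ed_quantile = thr$ed_quantile),
    p("thresholds.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(result$regions)) {
    write_region_tsv(result$regions[[nm]],
                     p(paste0("regions_", nm, ".tsv")))
    write_region_bed(result$regions[[nm]],
                     p(paste0("regions_", nm, ".bed")))
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$truth))
    jsonlite::write_json(result$truth, p("truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat("BSA-seq scan:", x$sites_n, "input sites\n")
  cat("  SNP-index track retained:", x$ledgers$snp_index$retained, "\n")
  cat("  ED track retained:       ", x$ledgers$ed$retained, "\n")
  env <- x$thresholds$delta_envelope$values
  cat("  delta null envelope:",
      paste(names(env), round(env, 4), sep = "=", collapse = "  "), "\n")
  cat("  ED thresholds: median+SD =",
      round(x$thresholds$ed_median_sd, 4),
      " quantile =", round(x$thresholds$ed_quantile, 4), "\n")
  for (nm in names(x$regions))
    cat(sprintf("  regions[%s]: %d\n", nm, nrow(x$regions[[nm]])))
  invisible(x)
}
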