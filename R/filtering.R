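#' Filter-ledger constructor
#'
#' An auditable account of one filtering pass: how many sites entered, how
#' many each reason removed, and how many remain. The retained count is
#' always computed as `total_in - sum(removed_by_reason)`, so the ledger
#' arithmetic is self-consistent by construction and each site is counted
#' under exactly one reason.
#'
#' @param track `"snp_index"` or `"ed"`.
#' @param total_in number of sites entering the filter.
#' @param removed_by_reason named integer vector of removal counts.
#' @return list of class `filter_ledger` with fields `track`, `total_in`,
#'   `removed_by_reason`, `retained`.
#' @export
#' @examples
#' filter_ledger("snp_index", 2337510,
#'               c(multi_allelic = 5201, identical_in_bulks = 772175,
#'                 low_depth = 23119, parent_uninformative = 311069))
filter_ledger <- function(track = c("snp_index", "ed"), total_in,
                          removed_by_reason) {
  track <- match.arg(track)
  stopifnot(length(total_in) == 1, total_in >= 0,
            all(removed_by_reason >= 0),
            !is.null(names(removed_by_reason)))
  retained <- total_in - sum(removed_by_reason)
  if (retained < 0) stop("removal counts exceed total_in")
  structure(list(track = track,
                 total_in = as.numeric(total_in),
                 removed_by_reason = removed_by_reason,
                 retained = as.numeric(retained)),
            class = "filter_ledger")
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("Filter ledger (", x$track, " track)\n", sep = "")
  cat("  sites in:      ", format(x$total_in, big.mark = ","), "\n")
  for (r in names(x$removed_by_reason))
    cat(sprintf("  - %-22s %s\n", r,
                format(x$removed_by_reason[[r]], big.mark = ",")))
  cat("  retained:      ", format(x$retained, big.mark = ","), "\n")
  invisible(x)
}

# canonical reason order per track; also the classification precedence
.reasons_snp_index <- c("multi_allelic", "identical_in_bulks",
                        "low_depth", "parent_uninformative")
.reasons_ed <- c("low_depth", "identical_in_bulks", "multi_aligned")

#' Classify sites for the SNP-index filtering track
#'
#' Assigns each site its first matching removal reason, in fixed
#' precedence: `multi_allelic` (more than one ALT allele),
#' `identical_in_bulks` (no signal between pools: the two bulks' allele
#' read fractions are equal at integer-depth resolution, hence trivially
#' on the same side of 0.5), `low_depth` (either bulk's total depth below
#' `min_depth`), `parent_uninformative` (a parent not homozygous, or the
#' parents share the same allele, so the site cannot be oriented), else
#' `PASS`.
#'
#' @param sites a `bulk_sites` table.
#' @param min_depth minimum per-bulk total depth (default 4: sites with a
#'   read number below four are removed).
#' @return character vector: a reason or `"PASS"` per site.
#' @export
classify_snp_index_track <- function(sites, min_depth = 4) {
  stopifnot(inherits(sites, "bulk_sites"))
  reason <- rep("PASS", nrow(sites))
  set <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    reason[reason == "PASS" & cond] <<- label
  }
  set(sites$n_alt_alleles > 1, "multi_allelic")
  # allele read fraction per bulk, orientation-free (ALT-base fraction);
  # defined for biallelic SNPs, which is all that reaches this reason
  bases <- c("A", "C", "G", "T")
  ai <- match(sites$alt, bases)
  ri <- cbind(seq_len(nrow(sites)), ai)
  f_aa <- as.matrix(sites[, c("aa_A", "aa_C", "aa_G", "aa_T")])[ri] /
    pmax(sites$depth_aa, 1)
  f_ab <- as.matrix(sites[, c("ab_A", "ab_C", "ab_G", "ab_T")])[ri] /
    pmax(sites$depth_ab, 1)
  set(sites$depth_aa > 0 & sites$depth_ab > 0 &
        abs(f_aa - f_ab) < 1e-9, "identical_in_bulks")
  set(sites$depth_aa < min_depth | sites$depth_ab < min_depth, "low_depth")
  set(sites$orientation != "ok", "parent_uninformative")
  reason
}

#' Classify sites for the Euclidean-distance filtering track
#'
#' Precedence: `low_depth` (read support below `min_depth` in any bulk
#' pool), `identical_in_bulks` (identical per-base read-frequency vectors
#' in the two bulks, i.e. zero distance by construction), `multi_aligned`
#' (more than one ALT allele), else `PASS`. The parents are not consulted:
#' the Euclidean-distance statistic is defined on raw base frequencies and
#' this track's ledger has no parental filter.
#'
#' @inheritParams classify_snp_index_track
#' @return character vector: a reason or `"PASS"` per site.
#' @export
classify_ed_track <- function(sites, min_depth = 4) {
  stopifnot(inherits(sites, "bulk_sites"))
  reason <- rep("PASS", nrow(sites))
  set <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    reason[reason == "PASS" & cond] <<- label
  }
  set(sites$depth_aa < min_depth | sites$depth_ab < min_depth, "low_depth")
  fa <- as.matrix(sites[, c("aa_A", "aa_C", "aa_G", "aa_T")]) /
    pmax(sites$depth_aa, 1)
  fb <- as.matrix(sites[, c("ab_A", "ab_C", "ab_G", "ab_T")]) /
    pmax(sites$depth_ab, 1)
  ident <- sites$depth_aa > 0 & sites$depth_ab > 0 &
    apply(abs(fa - fb), 1, max) < 1e-9
  set(ident, "identical_in_bulks")
  set(sites$n_alt_alleles > 1, "multi_aligned")
  reason
}

#' Apply one filtering track and return retained sites plus its ledger
#'
#' Every input site ends up exactly once: either retained (`PASS`) or in a
#' single removal bucket, so the ledger partition
#' `retained = total_in - sum(removed)` holds on every run.
#'
#' @param sites a non-empty `bulk_sites` table.
#' @param track `"snp_index"` or `"ed"`.
#' @param min_depth minimum per-bulk depth passed to the classifier.
#' @return list with `sites` (the retained `bulk_sites`) and `ledger`
#'   (a [filter_ledger()]).
#' @export
apply_filters <- function(sites, track = c("snp_index", "ed"),
                          min_depth = 4) {
  track <- match.arg(track)
  if (nrow(sites) == 0) stop("empty site table")
  reason <- switch(track,
                   snp_index = classify_snp_index_track(sites, min_depth),
                   ed = classify_ed_track(sites, min_depth))
  canonical <- switch(track, snp_index = .reasons_snp_index,
                      ed = .reasons_ed)
  removed <- vapply(canonical, function(r) sum(reason == r), 0L)
  keep <- sites[reason == "PASS", , drop = FALSE]
  class(keep) <- class(sites)
  attr(keep, "chrom_lengths") <- attr(sites, "chrom_lengths")
  list(sites = keep,
       ledger = filter_ledger(track, nrow(sites), removed))
}
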