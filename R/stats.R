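#' SNP-index of a bulk at one site
#'
#' The fraction of a bulk's reads carrying the L-parent allele:
#' `L / (L + S)`. Near 0.5 when the bulk segregates freely; pulled toward
#' 0 or 1 near a locus under phenotypic selection.
#'
#' @param L_depth,S_depth reads supporting the L- and S-parent alleles
#'   (vectorised).
#' @return numeric in `[0, 1]`.
#' @export
#' @examples
#' snp_index(30, 10)  # 0.75
snp_index <- function(L_depth, S_depth) {
  stopifnot(all(L_depth >= 0), all(S_depth >= 0))
  tot <- L_depth + S_depth
  if (any(tot == 0))
    stop("zero total depth; low-depth sites must be filtered upstream")
  L_depth / tot
}

#' Delta SNP-index between the two bulks
#'
#' `SNPindex(aa) - SNPindex(ab)`: zero under the null, approaching +/-1 at
#' a fully selected locus.
#'
#' @param idx_aa,idx_ab SNP-indices of the L-pool (`aa`) and S-pool (`ab`),
#'   each in `[0, 1]` (vectorised).
#' @return numeric in `[-1, 1]`.
#' @export
delta_snp_index <- function(idx_aa, idx_ab) {
  if (any(idx_aa < 0 | idx_aa > 1 | idx_ab < 0 | idx_ab > 1, na.rm = TRUE))
    stop("SNP-index values must lie in [0, 1]")
  idx_aa - idx_ab
}

#' Per-base read frequencies of a bulk at one site
#'
#' @param base_depths reads supporting A, C, G, T: a length-4 vector or an
#'   n-by-4 matrix (columns in A, C, G, T order).
#' @return frequencies of the same shape, each row summing to 1.
#' @export
#' @examples
#' base_frequencies(c(A = 8, C = 0, G = 2, T = 0))
base_frequencies <- function(base_depths) {
  if (is.null(dim(base_depths)))
    base_depths <- matrix(base_depths, nrow = 1,
                          dimnames = list(NULL, names(base_depths)))
  stopifnot(ncol(base_depths) == 4, all(base_depths >= 0))
  tot <- rowSums(base_depths)
  if (any(tot == 0))
    stop("zero total depth; low-depth sites must be filtered upstream")
  f <- base_depths / tot
  if (nrow(f) == 1) drop(f) else f
}

#' Euclidean distance between the bulks' base frequencies
#'
#' The square root of the summed squared differences of the four base
#' frequencies between bulks. Zero when the bulks are identical; at most
#' `sqrt(2)` for a biallelic site (and bounded by 2 in general).
#'
#' @param freqs_aa,freqs_ab length-4 frequency vectors (or n-by-4
#'   matrices), each (row) summing to 1.
#' @return non-negative numeric.
#' @export
#' @examples
#' euclidean_distance(c(1, 0, 0, 0), c(0, 1, 0, 0))  # sqrt(2)
euclidean_distance <- function(freqs_aa, freqs_ab) {
  if (is.null(dim(freqs_aa))) freqs_aa <- matrix(freqs_aa, nrow = 1)
  if (is.null(dim(freqs_ab))) freqs_ab <- matrix(freqs_ab, nrow = 1)
  stopifnot(ncol(freqs_aa) == 4, ncol(freqs_ab) == 4,
            nrow(freqs_aa) == nrow(freqs_ab))
  if (any(abs(rowSums(freqs_aa) - 1) > 1e-6) ||
      any(abs(rowSums(freqs_ab) - 1) > 1e-6))
    stop("frequency vectors must sum to 1")
  out <- sqrt(rowSums((freqs_aa - freqs_ab)^2))
  if (length(out) == 1) unname(out) else out
}

#' Raise the Euclidean distance to a power
#'
#' Powering the distance (default: squaring) suppresses genome-wide
#' background noise relative to true peaks before window fitting.
#'
#' @param ed non-negative distance value(s).
#' @param k exponent, at least 1 (default 2).
#' @return `ed^k`.
#' @export
ed_power <- function(ed, k = 2) {
  if (any(ed < 0)) stop("ed must be non-negative")
  stopifnot(k >= 1)
  ed^k
}

#' Per-site association statistics table
#'
#' Appends `snp_index_aa`, `snp_index_ab`, `delta_snp_index`, `ed` and
#' `ed_powered` to a site table. The SNP-index trio requires parental
#' orientation and is `NA` at unoriented sites (which the SNP-index
#' filtering track removes); the Euclidean distance is computed from raw
#' base frequencies and is defined at every site with reads in both bulks.
#'
#' @param sites a `bulk_sites` table with positive depth in both bulks.
#' @param k exponent for [ed_power()].
#' @return `sites` with the five statistic columns appended.
#' @export
site_statistics <- function(sites, k = 2) {
  stopifnot(inherits(sites, "bulk_sites"))
  if (any(sites$depth_aa == 0 | sites$depth_ab == 0))
    stop("zero-depth sites present; apply the filtering stage first")
  ok <- sites$orientation == "ok"
  idx_aa <- idx_ab <- rep(NA_real_, nrow(sites))
  if (any(ok)) {
    idx_aa[ok] <- snp_index(sites$Laa[ok], sites$Saa[ok])
    idx_ab[ok] <- snp_index(sites$Lab[ok], sites$Sab[ok])
  }
  fa <- base_frequencies(as.matrix(sites[, c("aa_A", "aa_C", "aa_G", "aa_T")]))
  fb <- base_frequencies(as.matrix(sites[, c("ab_A", "ab_C", "ab_G", "ab_T")]))
  if (is.null(dim(fa))) fa <- matrix(fa, nrow = 1)
  if (is.null(dim(fb))) fb <- matrix(fb, nrow = 1)
  ed <- euclidean_distance(fa, fb)
  sites$snp_index_aa <- idx_aa
  sites$snp_index_ab <- idx_ab
  sites$delta_snp_index <- idx_aa - idx_ab
  sites$ed <- ed
  sites$ed_powered <- ed_power(ed, k)
  sites
}
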