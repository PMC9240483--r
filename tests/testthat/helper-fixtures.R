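# Handcrafted site tables for unit tests: sensible defaults give an
# oriented biallelic A/G site (parent L homozygous REF).
hand_sites <- function(ad_bulk_L, ad_bulk_S,
                       ref = "A", alt = "G",
                       gt_parent_L = "0/0", gt_parent_S = "1/1",
                       ad_parent_L = "30,0", ad_parent_S = "0,30",
                       chrom = "chr1", pos = NULL) {
  n <- max(length(ad_bulk_L), length(ad_bulk_S))
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  bulk_site_table(
    chrom = rep_len(chrom, n), pos = pos,
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    gt_parent_L = rep_len(gt_parent_L, n),
    gt_parent_S = rep_len(gt_parent_S, n),
    ad_parent_L = rep_len(ad_parent_L, n),
    ad_parent_S = rep_len(ad_parent_S, n),
    ad_bulk_L = rep_len(ad_bulk_L, n),
    ad_bulk_S = rep_len(ad_bulk_S, n)
  )
}

# Small, fast simulation design for structural tests.
small_sim <- function(...) {
  sim_config(n_individuals = 200, bulk_size = 40, n_chromosomes = 1,
             chrom_length_bp = 2e6, marker_spacing_bp = 1e5,
             qtl_chrom = "chr1", qtl_pos_bp = 1e6, ...)
}

# A random site table with a mix of clean, low-depth, identical,
# multi-allelic and parent-uninformative sites, for partition properties.
random_mixed_sites <- function(n = 300, seed = 1) {
  set.seed(seed)
  ad2 <- function(a, b) paste0(a, ",", b)
  kind <- sample(c("clean", "low", "ident", "multi", "unif"), n,
                 replace = TRUE)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  alt[kind == "multi"] <- vapply(which(kind == "multi"), function(i)
    paste(sample(setdiff(c("A", "C", "G", "T"), ref[i]), 2),
          collapse = ","), "")
  gtL <- ifelse(kind == "unif", "0/1", "0/0")
  adbL <- character(n); adbS <- character(n)
  for (i in seq_len(n)) {
    if (kind[i] == "low") {
      adbL[i] <- ad2(2, 1); adbS[i] <- ad2(30, 31)
    } else if (kind[i] == "ident") {
      adbL[i] <- ad2(20, 20); adbS[i] <- ad2(35, 35)
    } else {
      a <- sample(5:60, 1); b <- sample(5:60, 1)
      adbL[i] <- ad2(a, b); adbS[i] <- ad2(b + 1, a)
    }
    if (kind[i] == "multi") {
      adbL[i] <- paste0(adbL[i], ",2"); adbS[i] <- paste0(adbS[i], ",1")
    }
  }
  pad <- function(k, extra) ifelse(k == "multi", paste0(extra, ",0"), extra)
  bulk_site_table(
    chrom = rep("chr1", n), pos = sort(sample(1:5e6, n)),
    ref = ref, alt = alt,
    gt_parent_L = gtL, gt_parent_S = rep("1/1", n),
    ad_parent_L = pad(kind, "25,0"), ad_parent_S = pad(kind, "0,25"),
    ad_bulk_L = adbL, ad_bulk_S = adbS
  )
}
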