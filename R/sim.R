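#' Simulation parameters for a bulked-segregant F2 experiment
#'
#' Bundles every knob of the ground-truth simulator: population and bulk
#' sizes, genome layout, QTL placement and effect size, sequencing depths
#' and error rate, and the recombination map density. Defaults emulate the
#' study design the package is validated against: an F2 of 1,307 plants
#' segregating for one large-effect grain-length QTL explaining 54.85% of
#' the phenotypic variance, bulks of the 50 most extreme individuals at
#' ~70x pooled coverage, parents at ~35x.
#'
#' @param n_individuals F2 population size.
#' @param bulk_size number of extreme individuals per bulk; must be at most
#'   `n_individuals / 2`.
#' @param n_chromosomes number of simulated chromosomes.
#' @param chrom_length_bp chromosome length(s) in bp; recycled to
#'   `n_chromosomes`.
#' @param marker_spacing_bp distance between simulated SNP markers (bp).
#' @param qtl_chrom,qtl_pos_bp location of the causal QTL; the position is
#'   snapped to the nearest marker.
#' @param pve proportion of phenotypic variance explained by the QTL,
#'   in `[0, 1)`.
#' @param mean_depth_bulk mean pooled sequencing depth per bulk; a single
#'   value or one per bulk `c(L, S)`.
#' @param mean_depth_parent mean sequencing depth per parent; a single
#'   value or one per parent `c(L, S)`.
#' @param seq_error_rate per-read probability of reporting the other allele.
#' @param recomb_rate_cM_per_Mb genetic map density (cM/Mb).
#' @param pheno_mean_mm,pheno_sd_mm mean and total standard deviation of
#'   the phenotype (mm grain-length scale). The additive effect `a` is set
#'   from `pve` so that `a^2/2 = pve * pheno_sd_mm^2` under the F2 1:2:1
#'   genotype frequencies.
#' @param frac_parent_uninformative fraction of markers emitted as
#'   parent-uninformative noise sites (parents identical or heterozygous),
#'   so the downstream filtering ledgers have material to remove.
#' @param frac_multiallelic fraction of markers emitted with a second,
#'   low-support ALT allele.
#' @param seed integer seed making the whole simulation reproducible.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 200, chrom_length_bp = 2e6,
#'                   qtl_pos_bp = 1e6, seed = 1)
sim_config <- function(n_individuals = 1307,
                       bulk_size = 50,
                       n_chromosomes = 3,
                       chrom_length_bp = 30e6,
                       marker_spacing_bp = 20000,
                       qtl_chrom = "chr3",
                       qtl_pos_bp = 23.2e6,
                       pve = 0.5485,
                       mean_depth_bulk = 70,
                       mean_depth_parent = 35,
                       seq_error_rate = 0.001,
                       recomb_rate_cM_per_Mb = 4.0,
                       pheno_mean_mm = 10.2,
                       pheno_sd_mm = 1.43,
                       frac_parent_uninformative = 0.05,
                       frac_multiallelic = 0.01,
                       seed = 1L) {
  chrom_length_bp <- rep_len(as.numeric(chrom_length_bp), n_chromosomes)
  chroms <- paste0("chr", seq_len(n_chromosomes))
  if (is.numeric(qtl_chrom)) qtl_chrom <- paste0("chr", qtl_chrom)
  stopifnot(
    n_individuals >= 2, bulk_size >= 1,
    n_chromosomes >= 1, all(chrom_length_bp > 0),
    marker_spacing_bp > 0,
    all(mean_depth_bulk > 0), all(mean_depth_parent > 0),
    seq_error_rate >= 0, seq_error_rate < 0.5,
    recomb_rate_cM_per_Mb >= 0, pheno_sd_mm > 0,
    frac_parent_uninformative >= 0, frac_parent_uninformative < 1,
    frac_multiallelic >= 0, frac_multiallelic < 1
  )
  if (bulk_size > n_individuals / 2)
    stop("bulk_size must be at most n_individuals / 2")
  if (!(pve >= 0 && pve < 1)) stop("pve must be in [0, 1)")
  if (!qtl_chrom %in% chroms) stop("qtl_chrom is not a simulated chromosome")
  if (qtl_pos_bp < 1 || qtl_pos_bp > chrom_length_bp[match(qtl_chrom, chroms)])
    stop("qtl_pos_bp lies outside its chromosome")
  structure(list(
    n_individuals = as.integer(n_individuals),
    bulk_size = as.integer(bulk_size),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp,
    chroms = chroms,
    marker_spacing_bp = as.numeric(marker_spacing_bp),
    qtl_chrom = qtl_chrom,
    qtl_pos_bp = as.numeric(qtl_pos_bp),
    pve = pve,
    mean_depth_bulk = rep_len(mean_depth_bulk, 2),
    mean_depth_parent = rep_len(mean_depth_parent, 2),
    seq_error_rate = seq_error_rate,
    recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
    pheno_mean_mm = pheno_mean_mm,
    pheno_sd_mm = pheno_sd_mm,
    frac_parent_uninformative = frac_parent_uninformative,
    frac_multiallelic = frac_multiallelic,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate one gamete from a heterozygous parent
#'
#' Draws a recombinant haplotype under the Haldane model (no crossover
#' interference): the crossover count on the chromosome is Poisson with
#' mean equal to the map length in Morgans, crossover positions are uniform
#' on the genetic map, and the gamete copies one of the two parental
#' haplotypes between crossovers, starting from either with probability 1/2.
#'
#' @param parent_haplotypes list of two equal-length vectors (or a 2-row
#'   matrix), the parent's phased haplotypes at the mapped markers.
#' @param map_cM non-decreasing genetic-map positions (cM), one per marker.
#' @return A vector of the same length as `map_cM`: the gamete's allele at
#'   each marker.
#' @export
#' @examples
#' set.seed(1)
#' simulate_gamete(list(rep("L", 5), rep("S", 5)), map_cM = seq(0, 100, 25))
simulate_gamete <- function(parent_haplotypes, map_cM) {
  if (is.matrix(parent_haplotypes))
    parent_haplotypes <- list(parent_haplotypes[1, ], parent_haplotypes[2, ])
  h1 <- parent_haplotypes[[1]]
  h2 <- parent_haplotypes[[2]]
  m <- length(map_cM)
  if (m == 0) stop("empty marker list")
  if (length(h1) != m || length(h2) != m)
    stop("haplotype length does not match the genetic map")
  if (is.unsorted(map_cM)) stop("map_cM must be non-decreasing")
  len_morgan <- (map_cM[m] - map_cM[1]) / 100
  k <- rpois(1, len_morgan)
  start <- sample.int(2, 1)
  if (k == 0) {
    seg <- rep(start, m)
  } else {
    xo <- sort(runif(k, map_cM[1], map_cM[m]))
    seg <- (start - 1 + findInterval(map_cM, xo)) %% 2 + 1
  }
  out <- h1
  out[seg == 2] <- h2[seg == 2]
  out
}

# Batch gamete simulation for the (L x S) F1, whose haplotypes are all-L /
# all-S on every chromosome: the gamete's origin at a marker is determined
# solely by the starting haplotype and the parity of crossovers before it.
# Returns an n_gametes x n_markers logical matrix, TRUE = L origin.
.sim_f1_gametes <- function(n_gametes, map_cM) {
  m <- length(map_cM)
  len_morgan <- (map_cM[m] - map_cM[1]) / 100
  ks <- rpois(n_gametes, len_morgan)
  starts <- sample.int(2, n_gametes, replace = TRUE) - 1L
  out <- matrix(FALSE, n_gametes, m)
  for (g in seq_len(n_gametes)) {
    if (ks[g] == 0) {
      out[g, ] <- starts[g] == 0L
    } else {
      xo <- sort(runif(ks[g], map_cM[1], map_cM[m]))
      out[g, ] <- ((starts[g] + findInterval(map_cM, xo)) %% 2) == 0L
    }
  }
  out
}

#' Simulate an F2 population segregating for one additive QTL
#'
#' Each F2 individual is formed from two independent F1 gametes
#' ([simulate_gamete()] semantics under the Haldane map). The phenotype is
#' `mu + a * (g - 1) + e`, where `g` counts L-parent alleles at the QTL
#' marker, `e ~ Normal(0, sigma_e)`, and `a`, `sigma_e` are set from the
#' configured PVE so the additive QTL variance (`a^2/2` under 1:2:1 F2
#' genotype frequencies) is `pve` of the total phenotypic variance.
#'
#' @param config a [sim_config()].
#' @return A list of class `f2_population`: `markers` (data frame with
#'   chrom, pos, cM, is_qtl), `haplotypes` (per chromosome, two
#'   individuals-by-markers logical matrices, `TRUE` = L-parent origin),
#'   `phenotype`, `qtl_genotype` (0/1/2 L-allele count), `qtl`
#'   (chrom/pos actually used), and `config`.
#' @export
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$pve >= 1) stop("pve must be < 1")
  set.seed(config$seed)
  n <- config$n_individuals

  markers <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(ci) {
    pos <- seq(config$marker_spacing_bp, config$chrom_length_bp[ci],
               by = config$marker_spacing_bp)
    data.frame(chrom = config$chroms[ci], pos = pos,
               cM = pos / 1e6 * config$recomb_rate_cM_per_Mb,
               stringsAsFactors = FALSE)
  }))
  qc <- markers$chrom == config$qtl_chrom
  qi <- which(qc)[which.min(abs(markers$pos[qc] - config$qtl_pos_bp))]
  markers$is_qtl <- seq_len(nrow(markers)) == qi

  haplotypes <- lapply(config$chroms, function(ch) {
    map <- markers$cM[markers$chrom == ch]
    list(hapA = .sim_f1_gametes(n, map), hapB = .sim_f1_gametes(n, map))
  })
  names(haplotypes) <- config$chroms

  qch <- haplotypes[[config$qtl_chrom]]
  q_local <- which(markers$pos[markers$chrom == config$qtl_chrom] ==
                     markers$pos[qi])[1]
  g <- qch$hapA[, q_local] + qch$hapB[, q_local]

  a <- sqrt(2 * config$pve) * config$pheno_sd_mm
  sigma_e <- sqrt(1 - config$pve) * config$pheno_sd_mm
  phenotype <- config$pheno_mean_mm + a * (g - 1) + rnorm(n, 0, sigma_e)

  structure(list(
    markers = markers,
    haplotypes = haplotypes,
    phenotype = phenotype,
    qtl_genotype = as.integer(g),
    qtl = list(chrom = config$qtl_chrom, pos = markers$pos[qi],
               additive_effect = a, sigma_e = sigma_e),
    config = config
  ), class = "f2_population")
}

#' Select the two extreme bulks from a phenotype vector
#'
#' The L-pool is the `bulk_size` individuals with the largest phenotypes,
#' the S-pool the `bulk_size` smallest. Ties are broken by ascending
#' individual index; the L-pool is assigned first and the S-pool is drawn
#' from the remaining individuals, so the pools are always disjoint.
#'
#' @param phenotypes numeric vector of finite phenotypes.
#' @param bulk_size pool size; must be at most `length(phenotypes) / 2`.
#' @return list with sorted integer index vectors `L_pool` and `S_pool`.
#' @export
#' @examples
#' select_bulks(c(5, 1, 4, 2, 3, 6), bulk_size = 2)
select_bulks <- function(phenotypes, bulk_size) {
  n <- length(phenotypes)
  stopifnot(is.numeric(phenotypes), all(is.finite(phenotypes)), bulk_size >= 1)
  if (bulk_size > n / 2) stop("bulk_size must be at most half the population")
  idx <- seq_len(n)
  l_order <- idx[order(-phenotypes, idx)]
  L_pool <- sort(l_order[seq_len(bulk_size)])
  rest <- setdiff(idx, L_pool)
  s_order <- rest[order(phenotypes[rest], rest)]
  S_pool <- sort(s_order[seq_len(bulk_size)])
  list(L_pool = L_pool, S_pool = S_pool)
}

# Vectorised pooled read sampling: total depth Poisson(mean_depth), reads
# supporting the L allele Binomial(D, p(1-e) + (1-p)e). Returns a 2-column
# matrix (L reads, S reads).
.pool_depths <- function(p, mean_depth, error_rate) {
  d <- rpois(length(p), mean_depth)
  pl <- p * (1 - error_rate) + (1 - p) * error_rate
  l <- rbinom(length(p), d, pl)
  cbind(L = l, S = d - l)
}

#' Simulate pooled allele depths at one site
#'
#' Computes the pooled L-allele frequency from the pool members' genotypes
#' at a marker, then samples a total read depth `D ~ Poisson(mean_depth)`
#' and L-supporting reads `~ Binomial(D, p(1-e) + (1-p)e)` with symmetric
#' sequencing error `e`.
#'
#' @param population an [simulate_f2()] result.
#' @param pool integer indices of the pooled individuals.
#' @param chrom,pos marker location (must match a simulated marker).
#' @param mean_depth mean pooled depth.
#' @param error_rate per-read error probability.
#' @return Named integer vector `c(L = , S = )` of allele read counts.
#' @export
simulate_read_depths <- function(population, pool, chrom, pos,
                                 mean_depth, error_rate = 0.001) {
  stopifnot(inherits(population, "f2_population"))
  if (length(pool) == 0) stop("empty pool")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  mk <- population$markers
  j <- which(mk$chrom == chrom & mk$pos == pos)
  if (length(j) != 1) stop("no such marker: ", chrom, ":", pos)
  local <- sum(mk$chrom == chrom & mk$pos <= pos)
  hp <- population$haplotypes[[chrom]]
  p <- mean(hp$hapA[pool, local] + hp$hapB[pool, local]) / 2
  d <- .pool_depths(p, mean_depth, error_rate)
  c(L = unname(d[1, "L"]), S = unname(d[1, "S"]))
}

#' Simulate a complete bulked-segregant sequencing experiment
#'
#' Runs the full generative model: F2 segregation, phenotypes, extreme-bulk
#' selection, pooled and parental read sampling, and assembly into the
#' oriented per-site table the analysis modules consume. A configurable
#' fraction of markers is emitted as parent-uninformative or multi-allelic
#' noise so the filtering ledgers have realistic material to remove.
#'
#' @param config a [sim_config()].
#' @param keep_population keep the (large) `f2_population` object in the
#'   result.
#' @return list with `sites` (a `bulk_sites` table, see
#'   [bulk_site_table()]), `truth` (ground-truth manifest: QTL location,
#'   PVE, seed, bulk membership), and optionally `population`.
#' @export
simulate_bulk_sites <- function(config, keep_population = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  pop <- simulate_f2(config)
  bulks <- select_bulks(pop$phenotype, config$bulk_size)
  mk <- pop$markers
  m <- nrow(mk)
  err <- config$seq_error_rate

  # pooled L-allele frequency per marker, per bulk
  p_pool <- function(pool) {
    unlist(lapply(config$chroms, function(ch) {
      hp <- pop$haplotypes[[ch]]
      (colSums(hp$hapA[pool, , drop = FALSE]) +
         colSums(hp$hapB[pool, , drop = FALSE])) / (2 * length(pool))
    }), use.names = FALSE)
  }
  p_aa <- p_pool(bulks$L_pool)
  p_ab <- p_pool(bulks$S_pool)

  d_aa <- .pool_depths(p_aa, config$mean_depth_bulk[1], err)
  d_ab <- .pool_depths(p_ab, config$mean_depth_bulk[2], err)

  # site classes: informative / parent-uninformative / multi-allelic
  qtl_i <- which(mk$is_qtl)
  n_unif <- round(config$frac_parent_uninformative * m)
  n_multi <- round(config$frac_multiallelic * m)
  pool_i <- setdiff(seq_len(m), qtl_i)
  special <- sample(pool_i, min(n_unif + n_multi, length(pool_i)))
  unif_i <- special[seq_len(min(n_unif, length(special)))]
  multi_i <- setdiff(special, unif_i)
  # half of uninformative sites: both parents share the REF allele (site is
  # monomorphic in the cross); other half: the L parent is heterozygous.
  unif_mono <- unif_i[seq_len(floor(length(unif_i) / 2))]
  unif_het <- setdiff(unif_i, unif_mono)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt1 <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  l_is_ref <- runif(m) < 0.5

  # parent reads: homozygous support with symmetric error
  p_depth <- function(mean_depth) {
    d <- rpois(m, mean_depth)
    own <- rbinom(m, d, 1 - err)
    cbind(own = own, other = d - own)
  }
  dp_l <- p_depth(config$mean_depth_parent[1])
  dp_s <- p_depth(config$mean_depth_parent[2])

  ad_pair <- function(own_is_ref, own, other) {
    ifelse(own_is_ref, paste0(own, ",", other), paste0(other, ",", own))
  }
  ad_pL <- ad_pair(l_is_ref, dp_l[, "own"], dp_l[, "other"])
  ad_pS <- ad_pair(!l_is_ref, dp_s[, "own"], dp_s[, "other"])
  gt_pL <- ifelse(l_is_ref, "0/0", "1/1")
  gt_pS <- ifelse(l_is_ref, "1/1", "0/0")

  ad_bL <- ad_pair(l_is_ref, d_aa[, "L"], d_aa[, "S"])
  ad_bS <- ad_pair(l_is_ref, d_ab[, "L"], d_ab[, "S"])

  # monomorphic noise sites: parents both REF-homozygous, bulks REF + error
  if (length(unif_mono)) {
    k <- length(unif_mono)
    gt_pL[unif_mono] <- gt_pS[unif_mono] <- "0/0"
    redraw <- function(mean_depth) {
      d <- rpois(k, mean_depth)
      r <- rbinom(k, d, 1 - err)
      paste0(r, ",", d - r)
    }
    ad_pS[unif_mono] <- redraw(config$mean_depth_parent[2])
    ad_bL[unif_mono] <- redraw(config$mean_depth_bulk[1])
    ad_bS[unif_mono] <- redraw(config$mean_depth_bulk[2])
  }
  # heterozygous-parent noise sites: the L parent is called 0/1
  if (length(unif_het)) {
    k <- length(unif_het)
    gt_pL[unif_het] <- "0/1"
    d <- rpois(k, config$mean_depth_parent[1])
    r <- rbinom(k, d, 0.5)
    ad_pL[unif_het] <- paste0(r, ",", d - r)
  }
  # multi-allelic noise sites: a second ALT with a few stray reads
  alt <- alt1
  if (length(multi_i)) {
    alt2 <- vapply(multi_i, function(i)
      sample(setdiff(bases, c(ref[i], alt1[i])), 1), "")
    alt[multi_i] <- paste0(alt1[multi_i], ",", alt2)
    extra <- rpois(length(multi_i), 2) + 1L
    ad_pL[multi_i] <- paste0(ad_pL[multi_i], ",0")
    ad_pS[multi_i] <- paste0(ad_pS[multi_i], ",0")
    ad_bL[multi_i] <- paste0(ad_bL[multi_i], ",", extra)
    ad_bS[multi_i] <- paste0(ad_bS[multi_i], ",",
                             rpois(length(multi_i), 2) + 1L)
  }

  sites <- bulk_site_table(
    chrom = mk$chrom, pos = mk$pos, ref = ref, alt = alt,
    gt_parent_L = gt_pL, gt_parent_S = gt_pS,
    ad_parent_L = ad_pL, ad_parent_S = ad_pS,
    ad_bulk_L = ad_bL, ad_bulk_S = ad_bS
  )
  attr(sites, "chrom_lengths") <-
    setNames(config$chrom_length_bp, config$chroms)

  truth <- list(
    qtl_chrom = pop$qtl$chrom, qtl_pos_bp = pop$qtl$pos,
    pve = config$pve, seed = config$seed,
    L_pool = bulks$L_pool, S_pool = bulks$S_pool,
    additive_effect = pop$qtl$additive_effect,
    phenotype_range_mm = range(pop$phenotype)
  )
  out <- list(sites = sites, truth = truth)
  if (keep_population) out$population <- pop
  out
}

#' Write simulated sites as a four-sample VCF
#'
#' Emits VCFv4.2 with samples in the fixed order `parent_L`, `parent_S`,
#' `bulk_L`, `bulk_S` and `FORMAT GT:AD:DP`. The output round-trips through
#' [read_bulk_vcf()] with every allele-depth integer preserved, and is
#' byte-identical for identical simulated input.
#'
#' @param sites a `bulk_sites` table (from [simulate_bulk_sites()] or
#'   [bulk_site_table()]), sorted by chromosome and position.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_simulated_vcf <- function(sites, path) {
  stopifnot(inherits(sites, "bulk_sites"))
  o <- order(sites$chrom, sites$pos)
  if (!identical(o, seq_len(nrow(sites))))
    stop("sites must be sorted by (chrom, pos)")
  cl <- attr(sites, "chrom_lengths")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsascan-simulator",
    if (!is.null(cl))
      sprintf("##contig=<ID=%s,length=%d>", names(cl), as.integer(cl)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "parent_L", "parent_S", "bulk_L", "bulk_S", sep = "\t")
  )
  fmt_sample <- function(gt, ad) {
    dp <- vapply(strsplit(ad, ",", fixed = TRUE),
                 function(x) sum(as.integer(x)), 0L)
    paste0(gt, ":", ad, ":", dp)
  }
  body <- if (nrow(sites) == 0) character(0) else
    paste(sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE),
          ".", sites$ref, sites$alt, ".", "PASS", ".", "GT:AD:DP",
          fmt_sample(sites$gt_parent_L, sites$ad_parent_L),
          fmt_sample(sites$gt_parent_S, sites$ad_parent_S),
          fmt_sample("./.", sites$ad_bulk_L),
          fmt_sample("./.", sites$ad_bulk_S),
          sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
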