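test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(bulk_size = 700), "bulk_size")
  expect_error(sim_config(pve = 1), "pve")
  expect_error(sim_config(pve = -0.1), "pve")
  expect_error(sim_config(qtl_pos_bp = 31e6), "outside")
  expect_error(sim_config(mean_depth_bulk = 0))
})

test_that("gamete simulation follows the Haldane map function", {
  # single marker, zero map length: gamete is one parental haplotype,
  # each with probability ~ 1/2
  set.seed(42)
  draws <- replicate(400, simulate_gamete(list("L", "S"), 0))
  expect_true(all(draws %in% c("L", "S")))
  expect_gt(mean(draws == "L"), 0.4)
  expect_lt(mean(draws == "L"), 0.6)

  # two markers 100 cM apart: recombinant fraction ~ (1 - exp(-2)) / 2
  par <- list(c("L", "L"), c("S", "S"))
  set.seed(7)
  rec <- replicate(10000, {
    g <- simulate_gamete(par, c(0, 100))
    g[1] != g[2]
  })
  expect_lt(abs(mean(rec) - (1 - exp(-2)) / 2), 0.02)

  # tight linkage: essentially no recombination
  set.seed(8)
  rec0 <- replicate(10000, {
    g <- simulate_gamete(par, c(0, 0.001))
    g[1] != g[2]
  })
  expect_lt(mean(rec0), 0.005)

  expect_error(simulate_gamete(list(character(0), character(0)),
                               numeric(0)), "empty")
})

test_that("F2 genotypes segregate 1:2:1 and the QTL explains its PVE", {
  cfg <- sim_config(n_individuals = 10000, bulk_size = 50,
                    n_chromosomes = 1, chrom_length_bp = 2e6,
                    marker_spacing_bp = 2e5, qtl_chrom = "chr1",
                    qtl_pos_bp = 1e6, pve = 0.5485, seed = 11)
  pop <- simulate_f2(cfg)
  for (j in c(1, 5, 10)) {
    hp <- pop$haplotypes$chr1
    g <- hp$hapA[, j] + hp$hapB[, j]
    tab <- tabulate(g + 1, 3)
    expect_gt(chisq.test(tab, p = c(0.25, 0.5, 0.25))$p.value, 0.001)
    expect_true(all(abs(tab / 10000 - c(0.25, 0.5, 0.25)) < 0.02))
  }
  # squared phenotype-genotype correlation recovers the configured PVE
  cfg2 <- sim_config(n_individuals = 2000, bulk_size = 50,
                     n_chromosomes = 1, chrom_length_bp = 2e6,
                     marker_spacing_bp = 1e5, qtl_chrom = "chr1",
                     qtl_pos_bp = 1e6, pve = 0.5485, seed = 3)
  pop2 <- simulate_f2(cfg2)
  expect_lt(abs(cor(pop2$phenotype, pop2$qtl_genotype)^2 - 0.5485), 0.05)
  # null effect
  cfg0 <- sim_config(n_individuals = 2000, bulk_size = 50,
                     n_chromosomes = 1, chrom_length_bp = 2e6,
                     marker_spacing_bp = 1e5, qtl_chrom = "chr1",
                     qtl_pos_bp = 1e6, pve = 0, seed = 4)
  pop0 <- simulate_f2(cfg0)
  expect_lt(abs(cor(pop0$phenotype, pop0$qtl_genotype)), 0.08)
})

test_that("bulk selection takes the phenotypic extremes, deterministically", {
  b <- select_bulks(1:200, 50)
  expect_identical(b$L_pool, 151:200)
  expect_identical(b$S_pool, 1:50)

  # all-ties: L-pool gets the lowest indices, S-pool is disjoint
  tie <- select_bulks(rep(1, 10), 2)
  expect_identical(tie$L_pool, 1:2)
  expect_identical(tie$S_pool, 3:4)
  expect_length(intersect(tie$L_pool, tie$S_pool), 0)

  # study-design ordering: extremes do not interleave when there are no ties
  set.seed(5)
  ph <- rnorm(1307, 10.2, 1.4)
  bb <- select_bulks(ph, 50)
  expect_gt(min(ph[bb$L_pool]), max(ph[bb$S_pool]))

  expect_error(select_bulks(1:10, 6), "half")
})

test_that("pooled read sampling matches its binomial expectations", {
  set.seed(9)
  # p = 0.5: mean L-read fraction ~ 0.5
  d <- bsascan:::.pool_depths(rep(0.5, 10000), 70, 0.001)
  expect_lt(abs(mean(d[, "L"] / rowSums(d)) - 0.5), 0.01)
  # p = 0 with error 0.001 at high depth: mean fraction ~ error rate
  d0 <- bsascan:::.pool_depths(rep(0, 1000), 1000, 0.001)
  expect_lt(abs(mean(d0[, "L"] / rowSums(d0)) - 0.001), 5e-4)
  # degenerate frequency, no error: no S reads ever
  d1 <- bsascan:::.pool_depths(rep(1, 200), 50, 0)
  expect_true(all(d1[, "S"] == 0))

  # exported per-site interface
  pop <- simulate_f2(small_sim(seed = 2))
  rd <- simulate_read_depths(pop, pool = 1:40, chrom = "chr1",
                             pos = 1e5, mean_depth = 70)
  expect_named(rd, c("L", "S"))
  expect_true(all(rd >= 0))
  expect_error(simulate_read_depths(pop, integer(0), "chr1", 1e5, 70),
               "empty pool")
})

test_that("simulated VCF output is deterministic and round-trips", {
  cfg <- small_sim(seed = 21)
  s1 <- simulate_bulk_sites(cfg)
  s2 <- simulate_bulk_sites(cfg)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_simulated_vcf(s1$sites, f1)
  write_simulated_vcf(s2$sites, f2)
  expect_identical(readLines(f1), readLines(f2))

  rt <- read_bulk_vcf(f1)
  expect_equal(nrow(rt), nrow(s1$sites))
  for (col in c("Laa", "Saa", "Lab", "Sab", "depth_aa", "depth_ab",
                "ad_bulk_L", "ad_bulk_S", "orientation"))
    expect_identical(rt[[col]], s1$sites[[col]])

  # empty table still yields a valid header-only VCF
  empty <- s1$sites[0, ]
  f0 <- tempfile(fileext = ".vcf")
  write_simulated_vcf(empty, f0)
  expect_equal(nrow(read_bulk_vcf(f0)), 0)

  # unsorted input is rejected
  shuffled <- s1$sites[rev(seq_len(nrow(s1$sites))), ]
  class(shuffled) <- class(s1$sites)
  expect_error(write_simulated_vcf(shuffled, tempfile()), "sorted")
  unlink(c(f0, f1, f2))
})

test_that("under no QTL the per-site delta at the QTL marker stays in the 95% envelope", {
  env <- null_envelope_delta(70, 70, bulk_size = 40,
                             levels = c(0.95), reps = 20000, seed = 99)
  inside <- 0
  for (s in 1:20) {
    sim <- simulate_bulk_sites(small_sim(pve = 0, seed = 500 + s))
    q <- sim$sites[sim$sites$pos == sim$truth$qtl_pos_bp, ]
    d <- q$Laa / (q$Laa + q$Saa) - q$Lab / (q$Lab + q$Sab)
    inside <- inside + (abs(d) <= env$values[[1]])
  }
  expect_gte(inside, 18)
})
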