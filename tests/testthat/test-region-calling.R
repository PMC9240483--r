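# a hand-built scan track: 12 windows, 10-kb step, centers on the grid
toy_track <- function(fitted, chrom = "chr1") {
  n <- length(fitted)
  out <- data.frame(chrom = chrom,
                    window_start = 1 + (seq_len(n) - 1) * 1e4,
                    window_end = (seq_len(n) - 1) * 1e4 + 1e6,
                    center = (seq_len(n) - 1) * 1e4 + 5e5,
                    n_sites = 5L, fitted = fitted)
  attr(out, "statistic") <- "toy"
  attr(out, "window_size") <- 1e6
  attr(out, "step") <- 1e4
  class(out) <- c("scan_track", "data.frame")
  out
}
mk_regions <- function(chrom, start, end) {
  r <- data.frame(chrom = chrom, start_bp = start, end_bp = end,
                  method = "x", threshold_used = NA_real_,
                  peak_value = NA_real_, n_windows = NA_integer_,
                  stringsAsFactors = FALSE)
  r$length_mb <- (r$end_bp - r$start_bp) / 1e6
  class(r) <- c("association_regions", "data.frame")
  r
}

test_that("region calling merges consecutive above-threshold windows", {
  f <- rep(0, 12)
  expect_equal(nrow(call_regions(toy_track(f), 0.5)), 0)

  all_up <- call_regions(toy_track(rep(1, 12)), 0.5)
  expect_equal(nrow(all_up), 1)
  expect_equal(all_up$start_bp, 5e5)
  expect_equal(all_up$end_bp, 5e5 + 11 * 1e4)
  expect_equal(all_up$n_windows, 12)

  # runs at windows {3,4,5} and {9}: two regions, the second point-like
  f2 <- rep(0, 12); f2[c(3, 4, 5, 9)] <- 1
  r <- call_regions(toy_track(f2), 0.5, method_label = "ed")
  expect_equal(nrow(r), 2)
  expect_equal(r$start_bp, c(5e5 + 2e4, 5e5 + 8e4))
  expect_equal(r$end_bp, c(5e5 + 4e4, 5e5 + 8e4))
  expect_equal(r$n_windows, c(3L, 1L))
  expect_equal(r$length_mb, c(0.02, 0))
  expect_equal(r$method, c("ed", "ed"))
  # a run separated by one below-threshold window is never bridged
  expect_true(r$start_bp[2] > r$end_bp[1])

  # NA windows count as below threshold
  f3 <- c(1, NA, 1, rep(0, 9))
  expect_equal(nrow(call_regions(toy_track(f3), 0.5)), 2)

  # two-sided calling for the signed delta track
  f4 <- rep(0, 12); f4[4] <- -0.9
  expect_equal(nrow(call_regions(toy_track(f4), 0.5, two_sided = TRUE)), 1)
  expect_equal(nrow(call_regions(toy_track(f4), 0.5)), 0)

  expect_error(call_regions(toy_track(f), Inf), "finite")
})

test_that("region lengths follow the end-minus-start megabase convention", {
  expect_equal(region_length_mb(list(start_bp = 10880000,
                                     end_bp = 36410000)), 25.53)
  expect_equal(region_length_mb(list(start_bp = 23160000,
                                     end_bp = 23190000)), 0.03)
  expect_equal(region_length_mb(list(start_bp = 23830000,
                                     end_bp = 24030000)), 0.20)
  expect_equal(region_length_mb(list(start_bp = 5e6, end_bp = 5e6)), 0)
})

test_that("track intersection is the standard interval intersection", {
  a <- mk_regions("chr1", 10, 30)
  b <- mk_regions("chr1", 20, 40)
  ab <- intersect_tracks(a, b)
  expect_equal(ab$start_bp, 20)
  expect_equal(ab$end_bp, 30)
  expect_equal(ab$method, "intersection")

  expect_equal(nrow(intersect_tracks(mk_regions("chr1", 1, 5),
                                     mk_regions("chr1", 10, 20))), 0)
  expect_equal(nrow(intersect_tracks(mk_regions("chr1", 1, 5),
                                     mk_regions("chr2", 1, 5))), 0)

  # containment: the narrow track's regions survive unchanged
  broad <- mk_regions("chr3", 10880000, 36410000)
  narrow <- mk_regions("chr3", c(23160000, 23830000),
                       c(23190000, 24030000))
  int <- intersect_tracks(broad, narrow)
  expect_equal(int$start_bp, narrow$start_bp)
  expect_equal(int$end_bp, narrow$end_bp)

  # commutative and idempotent
  ba <- intersect_tracks(b, a)
  expect_equal(ab$start_bp, ba$start_bp)
  expect_equal(ab$end_bp, ba$end_bp)
  aa <- intersect_tracks(a, a)
  expect_equal(aa$start_bp, a$start_bp)
  expect_equal(aa$end_bp, a$end_bp)

  bad <- mk_regions("chr1", c(10, 5), c(20, 8))
  expect_error(intersect_tracks(bad, a), "sorted")
  over <- mk_regions("chr1", c(10, 15), c(20, 30))
  expect_error(intersect_tracks(over, a), "overlap")
})

test_that("gene counting uses at-least-one-bp overlap on closed intervals", {
  region <- list(chrom = "chr1", start_bp = 1000, end_bp = 2000)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0))
  expect_equal(count_genes(region, empty), 0L)

  genes <- data.frame(
    chrom = c(rep("chr1", 8), "chr2", "chr2"),
    start = c(900, 1000, 1500, 1990, 2001, 100, 2500, 1200,
              1000, 1500),
    end = c(1100, 1200, 1600, 2300, 2100, 500, 2600, 1300,
            1100, 1600),
    gene_id = paste0("g", 1:10))
  # overlapping: g1 g2 g3 g4 g8; abutting at end+1 (g5) is excluded
  expect_equal(count_genes(region, genes), 5L)
  expect_equal(count_genes(list(chrom = "chr1", start_bp = 10,
                                end_bp = 20), genes), 0L)
})

test_that("raising the threshold only ever shrinks the called regions", {
  set.seed(88)
  f <- abs(rnorm(200, 0, 1)) + 0.2 * sin(seq_len(200) / 6)
  tr <- toy_track(f)
  thr <- sort(runif(6, 0.2, 2.5))
  cover <- function(r) {
    if (nrow(r) == 0) return(integer(0))
    unlist(lapply(seq_len(nrow(r)), function(i)
      seq(r$start_bp[i], r$end_bp[i], by = 1e4)))
  }
  prev <- cover(call_regions(tr, thr[1]))
  total_prev <- Inf
  for (t in thr[-1]) {
    r <- call_regions(tr, t)
    cur <- cover(r)
    expect_true(all(cur %in% prev))
    # non-overlap and additivity of lengths within one call
    if (nrow(r) > 1)
      expect_true(all(r$start_bp[-1] > r$end_bp[-nrow(r)]))
    expect_equal(sum(r$length_mb), sum(r$end_bp - r$start_bp) / 1e6)
    total <- sum(r$end_bp - r$start_bp)
    expect_lte(total, if (is.finite(total_prev)) total_prev else total)
    prev <- cur
    total_prev <- total
  }
})
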