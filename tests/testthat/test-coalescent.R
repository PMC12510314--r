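test_that("demographic model validation", {
  expect_error(demographic_model(t_bottleneck_end = 2000, t_split = 1000),
               "t_bottleneck_end")
  expect_error(demographic_model(N_anc = -1), "N_anc")
  expect_error(demographic_model(r = 1e-8), "r = 0")
})

test_that("zero mutation rate yields zero segregating sites", {
  m <- demographic_model(mu = 0)
  for (s in 1:10) {
    hm <- simulate_coalescent_window(m, 3000, 2, 2, seed = s)
    expect_equal(ncol(hm$alleles), 0L)
  }
})

test_that("simulation is deterministic in the seed", {
  m <- demographic_model()
  a <- simulate_coalescent_window(m, 3000, 6, 6, seed = 99)
  b <- simulate_coalescent_window(m, 3000, 6, 6, seed = 99)
  expect_identical(a, b)
  c <- simulate_coalescent_window(m, 3000, 6, 6, seed = 100)
  expect_false(identical(a$positions, c$positions))
})

test_that("single-population diversity matches the coalescent expectation", {
  # E[pi per site] = 4 N mu; 300 replicates put the Monte-Carlo SE near 3%
  N <- 150000; mu <- 3e-8
  m <- demographic_model(N_teosinte = N, mu = mu)
  pis <- vapply(1:300, function(s) {
    hm <- simulate_coalescent_window(m, 2000, 10, 0, seed = 1000 + s)
    nucleotide_diversity(hm$alleles, 2000)
  }, numeric(1))
  expect_equal(mean(pis), 4 * N * mu, tolerance = 0.10)
})

test_that("a severe bottleneck depresses maize diversity and raises FST", {
  n_rep <- 150
  bott <- demographic_model(N_maize_bottleneck = 1500)   # N_anc / 100
  flat <- demographic_model(N_maize_bottleneck = 150000)
  stat1 <- function(model, off) {
    res <- vapply(1:n_rep, function(s) {
      hm <- simulate_coalescent_window(model, 3000, 10, 10, seed = off + s)
      st <- vigorkit:::.site_stats(hm$alleles, hm$pop_labels == "teosinte",
                                   hm$pop_labels == "maize")
      d <- sum(st$d[st$segregating])
      c(fst = if (d > 0) sum(st$a[st$segregating]) / d else NA,
        pit = sum(st$pi1) / 3000, pim = sum(st$pi2) / 3000)
    }, numeric(3))
    list(fst = mean(res["fst", ], na.rm = TRUE),
         ratio_mt = mean(res["pim", ] / res["pit", ], na.rm = TRUE))
  }
  b <- stat1(bott, 5000)
  f <- stat1(flat, 6000)
  expect_lt(b$ratio_mt, 1)          # pi_maize / pi_teosinte < 1
  expect_gt(b$fst, f$fst)           # elevated FST vs constant-size control
})

test_that("permutation threshold endpoints and calibration behave", {
  m <- demographic_model()
  hm <- simulate_coalescent_window(m, 5000, 8, 8, seed = 17)
  thr <- permutation_threshold(hm, 2000, 500, min_sites = 1, n_perm = 100,
                               alpha = 0.05, seed = 2)
  maxima <- attr(thr, "max_fst")
  expect_length(maxima, 100)
  # alpha = 1 -> the minimum of the permuted maxima
  thr_min <- permutation_threshold(hm, 2000, 500, min_sites = 1, n_perm = 100,
                                   alpha = 1, seed = 2)
  expect_equal(as.numeric(thr_min), min(maxima))
  expect_error(permutation_threshold(hm, 2000, 500, n_perm = 10), "n_perm")

  # strong planted differentiation exceeds its permutation threshold
  set.seed(8)
  al <- cbind(matrix(rbinom(16 * 10, 1, 0.5), 16, 10),
              rep(c(0, 1), each = 8))
  hm_sel <- haplotype_matrix(al, c(seq(100, 1000, by = 100), 2500),
                             rep(c("teosinte", "maize"), each = 8),
                             region_end = 4000)
  obs <- max(window_scan(hm_sel, 2000, 500, 1)$fst, na.rm = TRUE)
  thr_sel <- permutation_threshold(hm_sel, 2000, 500, min_sites = 1,
                                   n_perm = 200, alpha = 0.05, seed = 3)
  expect_gt(obs, thr_sel)
})

test_that("bottleneck thresholds are the stated order statistics", {
  m <- demographic_model(N_maize_bottleneck = 1500)
  thr <- bottleneck_threshold(m, 3000, n_sim = 200, n1 = 8, n2 = 8,
                              alpha = 0.05, seed = 4)
  fsts <- thr$fst[is.finite(thr$fst)]
  # type-4 quantile: h = n * p lands on an order statistic when integral
  expect_equal(thr$fst_threshold,
               quantile(fsts, 0.95, type = 4, names = FALSE))
  expect_true(is.finite(thr$pi_ratio_threshold))
  expect_error(bottleneck_threshold(m, 3000, n_sim = 50), "n_sim")
})
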