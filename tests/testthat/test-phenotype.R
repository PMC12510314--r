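test_that("germination curves summarize replicates with mean and SE", {
  tr <- data.frame(genotype = "G", treatment = "AA",
                   replicate = rep(1:3, each = 2),
                   time_h = rep(c(48, 60), 3),
                   n_germinated = c(50, 50, 50, 50, 50, 50), n_total = 50)
  gc <- germination_percent(tr)
  expect_equal(gc$mean_pct, c(100, 100))
  expect_equal(gc$se_pct, c(0, 0))

  tr2 <- data.frame(genotype = "G", treatment = "AA", replicate = 1:3,
                    time_h = 72, n_germinated = c(40, 45, 50), n_total = 50)
  gc2 <- germination_percent(tr2)
  expect_equal(gc2$mean_pct, 90)
  expect_equal(gc2$se_pct, 10 / sqrt(3))
})

test_that("generated germination curves are monotone and summaries too", {
  tr <- gen_germination("wt", seq(48, 144, by = 12), 3, 50,
                        list(wt = c(t50 = 70, slope = 0.15, max_pct = 95)),
                        seed = 2)
  for (r in 1:3) {
    expect_true(all(diff(tr$n_germinated[tr$replicate == r]) >= 0))
  }
  gc <- germination_percent(tr)
  expect_true(all(diff(gc$mean_pct) >= 0))
  expect_true(all(gc$mean_pct >= 0 & gc$mean_pct <= 100))
})

test_that("timepoint tests: identity, stars, and equal-variance agreement", {
  tr <- data.frame(genotype = "G", treatment = "AA",
                   replicate = rep(1:3, each = 2),
                   time_h = rep(c(48, 60), 3),
                   n_germinated = rep(c(10, 30), 3), n_total = 50)
  tt <- timepoint_tests(tr, tr)
  expect_equal(tt$p, c(1, 1))
  expect_equal(tt$stars, c("", ""))

  a <- data.frame(genotype = "a", treatment = "AA", replicate = 1:3,
                  time_h = 60, n_germinated = c(10, 20, 30), n_total = 50)
  b <- data.frame(genotype = "b", treatment = "AA", replicate = 1:3,
                  time_h = 60, n_germinated = c(40, 50, 30), n_total = 50)
  w <- timepoint_tests(a, b)
  s <- timepoint_tests(a, b, var_equal = TRUE)
  # equal sample variances: Welch and Student agree exactly
  expect_equal(w$p, s$p)
})

test_that("a t50 shift produces stars at intermediate timepoints", {
  hits <- vapply(1:20, function(s) {
    tr <- gen_germination(c("early", "late"), seq(48, 144, by = 12), 3, 50,
                          list(early = c(60, 0.2, 95), late = c(84, 0.2, 95)),
                          seed = 3000 + s)
    tt <- timepoint_tests(tr[tr$genotype == "early", ],
                          tr[tr$genotype == "late", ])
    mid <- tt$time_h >= 60 & tt$time_h <= 84
    any(tt$p[mid] < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("haplotype calling follows the amplicon-length rule", {
  expect_equal(call_haplotype(c(365, 2682, 1500)),
               c("Hap_C7-2", "Hap_Z58", "other"))
  expect_equal(call_haplotype(c(365 - 50, 365 + 51)), c("Hap_C7-2", "other"))
  expect_error(call_haplotype(0), "> 0")
})

test_that("haplotype frequencies match the published 73/27 split", {
  calls <- rep(c("Hap_C7-2", "Hap_Z58"), c(221, 80))
  fr <- haplotype_frequencies(calls)
  expect_equal(fr$percent[fr$haplotype == "Hap_C7-2"], 73L)
  expect_equal(fr$percent[fr$haplotype == "Hap_Z58"], 27L)
  expect_equal(fr$n, c(221L, 80L))

  expect_equal(haplotype_frequencies("Hap_Z58")$percent, 100L)
  # order invariance
  expect_equal(haplotype_frequencies(rev(calls)), fr)
})

test_that("Bonferroni threshold reproduces the eGWAS cutoff", {
  expect_equal(signif(bonferroni_threshold(2965911, 1.0), 3), 3.37e-7)
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(20, 0.05), 2.5e-3)
})

test_that("germination generator endpoints", {
  z <- gen_germination("g", c(48, 72), 2, 30,
                       list(g = c(60, 0.2, 0)), seed = 1)
  expect_true(all(z$n_germinated == 0))

  step <- gen_germination("g", c(48, 60.01, 144), 2, 30,
                          list(g = c(60, Inf, 100)), seed = 1)
  expect_equal(step$n_germinated[step$time_h == 48], c(0, 0))
  expect_equal(step$n_germinated[step$time_h == 144], c(30, 30))

  expect_error(gen_germination("g", c(72, 48), 2, 30,
                               list(g = c(60, 0.2, 50))), "increasing")
  expect_error(gen_germination("g", c(48, 72), 2, 30,
                               list(g = c(60, 0.2, 120))), "max_pct")
})
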