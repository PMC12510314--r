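test_that("site FST components match the long-hand Weir-Cockerham transcription", {
  # frozen worked example: pop1 (ref, alt) = (6, 4), pop2 = (9, 1)
  comp <- site_fst(c(6, 4), c(9, 1))
  expect_equal(unname(comp["a"]), 2 / 75, tolerance = 1e-10)
  expect_equal(unname(comp["d"]), 0.21, tolerance = 1e-10)
  expect_equal(unname(comp["a"] / comp["d"]), 0.1269841, tolerance = 1e-6)

  set.seed(21)
  for (i in 1:50) {
    n1 <- sample(4:40, 1); n2 <- sample(4:40, 1)
    a1 <- sample(0:n1, 1); a2 <- sample(0:n2, 1)
    got <- site_fst(c(n1 - a1, a1), c(n2 - a2, a2))
    want <- wc_haploid_oracle(n1 - a1, a1, n2 - a2, a2)
    if (a1 + a2 == 0 || a1 + a2 == n1 + n2) want <- c(a = 0, d = 0)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("site FST endpoints: no differentiation <= 0, fixation = 1", {
  eq <- site_fst(c(10, 10), c(10, 10))
  expect_lte(eq[["a"]] / eq[["d"]], 0)
  fix <- site_fst(c(0, 20), c(20, 0))
  expect_equal(fix[["a"]] / fix[["d"]], 1)
  mono <- site_fst(c(20, 0), c(20, 0))
  expect_equal(unname(mono), c(0, 0))
  expect_error(site_fst(c(1, 0), c(5, 5)), ">= 2")
})

test_that("nucleotide diversity equals the exhaustive pairwise oracle", {
  expect_equal(nucleotide_diversity(matrix(1, 5, 4), 100), 0)
  # 2 haplotypes, 1 difference, 100 bp
  expect_equal(nucleotide_diversity(rbind(c(0, 0), c(0, 1)), 100), 0.01)

  set.seed(31)
  m <- matrix(rbinom(200, 1, 0.3), 10, 20)
  expect_equal(nucleotide_diversity(m, 500), pi_pairwise_oracle(m, 500))
  # with missing data, per-site pairwise-complete oracle
  m[sample(200, 30)] <- NA
  expect_equal(nucleotide_diversity(m, 500), pi_sitewise_oracle(m, 500))
})

test_that("window tiling matches the counting oracle", {
  hm <- haplotype_matrix(rbind(c(0, 1), c(1, 0), c(0, 0), c(1, 1)),
                         c(1, 10000), rep(c("teosinte", "maize"), 2),
                         region_start = 1, region_end = 10000)
  sc <- window_scan(hm, 3000, 100, min_sites = 1)
  expect_equal(nrow(sc), floor((10000 - 3000) / 100) + 1)   # 71
  expect_equal(sc$start, seq(1, 7001, by = 100))
  expect_equal(sc$end - sc$start, rep(3000, 71))
})

test_that("monomorphic data give undefined FST and zero diversity", {
  al <- matrix(0, 8, 5)
  al[, 3] <- 1   # monomorphic alt in everyone
  hm <- haplotype_matrix(al, c(10, 500, 1000, 2000, 2900),
                         rep(c("teosinte", "maize"), each = 4),
                         region_end = 3000)
  sc <- window_scan(hm, 1000, 500, min_sites = 0)
  expect_true(all(is.na(sc$fst)))
  expect_true(all(sc$pi_pop1 == 0 & sc$pi_pop2 == 0))
})

test_that("a single polymorphic site appears exactly in covering windows", {
  al <- matrix(0, 8, 1)
  al[1:2, 1] <- 1
  hm <- haplotype_matrix(al, 5000, rep(c("teosinte", "maize"), each = 4),
                         region_start = 1, region_end = 10000)
  sc <- window_scan(hm, 3000, 100, min_sites = 1)
  covers <- sc$start <= 5000 & 5000 < sc$start + 3000
  expect_equal(sc$n_sites == 1, covers)
})

test_that("short regions give one truncated window with a warning", {
  hm <- haplotype_matrix(rbind(c(0, 1), c(1, 0), c(0, 0), c(1, 1)),
                         c(5, 90), rep(c("teosinte", "maize"), 2),
                         region_end = 100)
  expect_warning(sc <- window_scan(hm, 3000, 100, min_sites = 1), "truncated")
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$end - sc$start, 100)
})

test_that("pooled diversity is invariant to population labels; coordinates stable", {
  set.seed(41)
  al <- matrix(rbinom(20 * 40, 1, 0.2), 20, 40)
  pos <- sort(sample(1:5000, 40))
  hm <- haplotype_matrix(al, pos, rep(c("teosinte", "maize"), each = 10),
                         region_end = 5000)
  hm2 <- hm
  hm2$pop_labels <- sample(hm$pop_labels)
  expect_equal(nucleotide_diversity(hm$alleles, 5000),
               nucleotide_diversity(hm2$alleles, 5000))
  s1 <- window_scan(hm, 1000, 250, 1)
  s2 <- window_scan(hm2, 1000, 250, 1)
  expect_equal(s1[c("start", "end", "n_sites")], s2[c("start", "end", "n_sites")])
})

test_that("Hudson estimator flag works and agrees at fixation", {
  al <- rbind(matrix(1, 5, 3), matrix(0, 5, 3))
  hm <- haplotype_matrix(al, c(10, 20, 30),
                         rep(c("teosinte", "maize"), each = 5),
                         region_end = 3000)
  expect_warning(sw <- window_scan(hm, 3000, 3000, 1), NA)
  sh <- window_scan(hm, 3000, 3000, 1, estimator = "hudson")
  expect_equal(sw$fst, 1)
  expect_equal(sh$fst, 1)
})
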