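test_that("cytosine context calling follows the CG/CHG/CHH rules", {
  expect_equal(call_contexts("ACGT"),
               data.frame(pos = 2L, context = "CG"))
  # CCGG: position 1 is C-C-G = CHG (H = C), position 2 is C-G = CG
  cc <- call_contexts("CCGG")
  expect_equal(cc$context, c("CHG", "CG"))
  # CATC: position 1 CHH; trailing position 4 indeterminate
  cc2 <- call_contexts("CATC")
  expect_equal(cc2$context, c("CHH", "indeterminate"))
  expect_error(call_contexts("ACGN"), "ACGT")
})

test_that("every internal cytosine gets exactly one of the three contexts", {
  set.seed(17)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    cc <- call_contexts(s)
    internal <- cc[cc$pos <= nchar(s) - 2, ]
    expect_true(all(internal$context %in% c("CG", "CHG", "CHH")))
  }
})

test_that("bisulfite summary matches the hand-counted example", {
  # ref ACGTCAT: one CG site (pos 2), one CHH site (pos 5)
  loc <- bisulfite_locus("ACGTCAT", c("ACGTCAT", "ATGTTAT"))
  sm <- bisulfite_summary(loc)
  expect_equal(sm$percent[sm$context == "CG"], 50)
  expect_equal(sm$percent[sm$context == "CHH"], 50)
  expect_equal(sm$n_sites, c(1L, 0L, 1L))
  expect_equal(sm$n_calls, c(2L, 0L, 2L))
})

test_that("non-C/T clone bases at cytosine positions are flagged and excluded", {
  loc <- bisulfite_locus("ACGTCAT", c("ACGTCAT", "AGGTTAT"))
  expect_warning(sm <- bisulfite_summary(loc), "excluded")
  expect_equal(sm$n_calls[sm$context == "CG"], 1L)
  expect_equal(attr(sm, "n_flagged"), 1L)
})

test_that("generated clones hit the trivial endpoints", {
  ref <- balanced_bs_ref(5)
  all0 <- gen_bisulfite_clones(ref, c(CG = 0, CHG = 0, CHH = 0), 4, seed = 1)
  sm0 <- bisulfite_summary(all0)
  expect_true(all(sm0$percent[sm0$n_calls > 0] == 0))
  expect_false(any(grepl("C", substr(all0$clones[1], 1, nchar(ref) - 2))))

  all1 <- gen_bisulfite_clones(ref, c(CG = 1, CHG = 1, CHH = 1), 4, seed = 1)
  sm1 <- bisulfite_summary(all1)
  expect_true(all(sm1$percent == 100))
  # fully methylated clones differ from the reference only at trailing Cs
  expect_equal(substr(all1$clones[1], 1, nchar(ref) - 2),
               substr(ref, 1, nchar(ref) - 2))
})

test_that("conversion failure biases calls upward", {
  ref <- balanced_bs_ref(10)
  noisy <- gen_bisulfite_clones(ref, c(CG = 0, CHG = 0, CHH = 0), 40,
                                conversion_failure = 0.2, seed = 3)
  sm <- bisulfite_summary(noisy)
  expect_equal(sm$percent, rep(20, 3), tolerance = 0.25)
})

test_that("generated percentages fall in exact binomial CIs of the truth", {
  ref <- balanced_bs_ref(20)   # 20 sites per context
  p <- c(CG = 0.8, CHG = 0.5, CHH = 0.05)
  loc <- gen_bisulfite_clones(ref, p, n_clones = 8, seed = 1)
  sm <- bisulfite_summary(loc)
  for (k in seq_len(3)) {
    ci <- binom.test(sm$n_methylated[k], sm$n_calls[k])$conf.int
    expect_gte(p[[sm$context[k]]], ci[1])
    expect_lte(p[[sm$context[k]]], ci[2])
  }
})

test_that("clone order does not affect the summary", {
  ref <- balanced_bs_ref(6)
  loc <- gen_bisulfite_clones(ref, c(CG = .6, CHG = .3, CHH = .1), 8, seed = 5)
  loc_rev <- bisulfite_locus(loc$ref_seq, rev(loc$clones))
  expect_equal(bisulfite_summary(loc)$percent,
               bisulfite_summary(loc_rev)$percent)
})

test_that("McrBC delta-delta-Ct scores match hand computations", {
  mk_ct <- function(d_reg, d_ref) {
    rbind(
      data.frame(region = "R1", genotype = "C7-2", digested = TRUE,
                 replicate = 1:3, ct = 20 + d_reg),
      data.frame(region = "R1", genotype = "C7-2", digested = FALSE,
                 replicate = 1:3, ct = 20),
      data.frame(region = "UBQ2", genotype = "C7-2", digested = TRUE,
                 replicate = 1:3, ct = 18 + d_ref),
      data.frame(region = "UBQ2", genotype = "C7-2", digested = FALSE,
                 replicate = 1:3, ct = 18),
      data.frame(region = "ACT1", genotype = "C7-2", digested = TRUE,
                 replicate = 1:3, ct = 22 + d_ref),
      data.frame(region = "ACT1", genotype = "C7-2", digested = FALSE,
                 replicate = 1:3, ct = 22))
  }
  expect_equal(mcrbc_relative_methylation(mk_ct(0, 0), "R1", "C7-2")$score, 0)
  # region loses 2 cycles, references protected: remaining 2^-2 = 0.25
  r <- mcrbc_relative_methylation(mk_ct(2, 0), "R1", "C7-2")
  expect_equal(r$score, 0.75)
  expect_equal(r$remaining, 0.25)
  # fully digested region: score ~ 0.999
  expect_equal(mcrbc_relative_methylation(mk_ct(10, 0), "R1", "C7-2")$score,
               1 - 2^-10)
  # missing undigested control errors
  ct <- mk_ct(2, 0)
  ct <- ct[!(ct$region == "R1" & !ct$digested), ]
  expect_error(mcrbc_relative_methylation(ct, "R1", "C7-2"), "undigested")
  # negative score clamps to zero with a note
  expect_message(
    r2 <- mcrbc_relative_methylation(mk_ct(-1, 0), "R1", "C7-2"),
    "clamping")
  expect_equal(r2$score, 0)
})

test_that("bottom-strand loci are reverse-complemented before calling", {
  # top strand ACGTCAT; bottom strand read is its reverse complement
  loc <- bisulfite_locus(.revcomp_test("ACGTCAT"),
                         c(.revcomp_test("ACGTCAT"), .revcomp_test("ATGTTAT")),
                         strand = "bottom")
  sm <- bisulfite_summary(loc)
  expect_equal(sm$percent[sm$context == "CG"], 50)
})
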