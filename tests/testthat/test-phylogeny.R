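test_that("complete deletion removes exactly the ambiguous columns", {
  aln <- c(a = "ACDEF", b = "ACDEF", c = "ACDEF")
  expect_equal(complete_deletion(aln), aln)

  gapped <- c(a = "ACDEF", b = "AC-EF", c = "ACDEF")
  expect_equal(unname(complete_deletion(gapped)),
               c("ACEF", "ACEF", "ACEF"))

  set.seed(23)
  m <- matrix(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                     50, replace = TRUE), 5, 10)
  amb_cols <- c(2, 5, 7, 10)
  for (ci in amb_cols) m[sample(5, 1), ci] <- sample(c("-", "X"), 1)
  rownames(m) <- paste0("t", 1:5)
  res <- complete_deletion(m)
  oracle_keep <- apply(m, 2, function(col)
    all(col %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  expect_equal(unname(nchar(res[1])), sum(oracle_keep))
  expect_equal(unname(res[1]), paste(m[1, oracle_keep], collapse = ""))

  all_amb <- c(a = "-X", b = "AC")
  expect_error(complete_deletion(all_amb), "no unambiguous")
})

test_that("Poisson distance matches its closed form and dominates p", {
  expect_equal(poisson_distance("AAAA", "AAAA"), 0)
  expect_equal(poisson_distance(paste(rep("A", 10), collapse = ""),
                                paste(c(rep("A", 9), "C"), collapse = "")),
               -log(0.9))
  set.seed(29)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    x <- paste(sample(aa, 50, TRUE), collapse = "")
    y <- paste(sample(aa, 50, TRUE), collapse = "")
    p <- mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    if (p < 1) expect_gte(poisson_distance(x, y), p)
  }
  expect_error(poisson_distance("AA", "CC"), "saturated")
})

test_that("NJ inverts additive matrices exactly (4-8 taxa, vs ape oracle)", {
  set.seed(37)
  for (n in 4:8) {
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(tr)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    fit <- nj_tree(D)
    # exact additivity: path lengths reproduce the input matrix
    Dfit <- ape::cophenetic.phylo(fit)[rownames(D), colnames(D)]
    expect_equal(Dfit, D, tolerance = 1e-8)
    # topology agrees with the independent NJ implementation
    expect_equal(ape::dist.topo(ape::unroot(fit), ape::unroot(ape::nj(D))),
                 structure(0, names = "PH85"), ignore_attr = TRUE)
  }
})

test_that("3-taxon trees use the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
})

test_that("NJ input validation", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(nj_tree(D), ">= 3")
  D3 <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3)
  expect_error(nj_tree(D3), "NA")
})

test_that("bootstrap supports a planted deep split and B = 1 is binary", {
  aln <- two_clade_alignment(n_per_clade = 4, n_sites = 200, n_fixed = 40)
  tree <- bootstrap_tree(aln, B = 50, collapse_below = 50, seed = 1)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  deep <- max(sup, na.rm = TRUE)
  expect_gte(deep, 95)

  t1 <- bootstrap_tree(aln, B = 1, collapse_below = 0, seed = 2)
  s1 <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("star-like data collapse toward a multifurcation", {
  aln <- star_alignment(n_taxa = 7, n_sites = 150, n_private = 4)
  tree <- bootstrap_tree(aln, B = 100, collapse_below = 50, seed = 3)
  full <- attr(tree, "full_tree")
  expect_lt(tree$Nnode, full$Nnode)
})

test_that("the well-supported split is invariant to taxon order", {
  # weakly supported splits can shift when bootstrap replicates contain
  # exact distance ties, so only the signal-bearing bipartition is compared
  aln <- two_clade_alignment(n_per_clade = 3, n_sites = 150, n_fixed = 30,
                             seed = 77)
  t_a <- bootstrap_tree(aln, B = 30, collapse_below = 0, seed = 5)
  t_b <- bootstrap_tree(rev(aln), B = 30, collapse_below = 0, seed = 5)
  sup_a <- suppressWarnings(as.numeric(t_a$node.label))
  sup_b <- suppressWarnings(as.numeric(t_b$node.label))
  expect_equal(max(sup_a, na.rm = TRUE), max(sup_b, na.rm = TRUE))
  expect_equal(length(sup_a), length(sup_b))
})
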