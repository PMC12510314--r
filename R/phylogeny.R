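# Protein-distance phylogenetics: complete deletion of ambiguous columns,
# Poisson-corrected distances, neighbor-joining with fixed deterministic
# tie-breaks, and site-bootstrap supports with <50% collapse. Trees are
# ape "phylo" objects; newick IO goes through ape.

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# alignment -> character matrix (taxa x columns)
.aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  stopifnot(is.character(aln), !is.null(names(aln)))
  if (length(unique(nchar(aln))) != 1L) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Remove ambiguous alignment columns (complete deletion)
#'
#' Retains exactly the columns where every row carries an unambiguous
#' amino acid (one of the 20 standard letters); columns containing gaps,
#' `X`, or other ambiguity codes in any row are removed for all rows.
#'
#' @param aln named character vector of aligned protein sequences (equal
#'   lengths), or a character matrix taxa x columns.
#' @return named character vector of the filtered alignment.
#' @export
complete_deletion <- function(aln) {
  m <- .aln_matrix(aln)
  keep <- apply(m, 2, function(col) all(col %in% .AA))
  if (!any(keep)) stop("no unambiguous columns survive complete deletion",
                       call. = FALSE)
  m <- m[, keep, drop = FALSE]
  setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

#' Poisson-corrected protein distance
#'
#' With `p` the proportion of differing sites between two equal-length
#' (post-deletion) sequences, the Poisson correction is `d = -ln(1 - p)`,
#' the expected number of substitutions per site. `p = 1` (saturation) is
#' an error.
#'
#' @param seqA,seqB aligned sequences (strings of equal length).
#' @return distance in substitutions per site (>= p).
#' @examples
#' poisson_distance("AAAAAAAAAA", "AAAAAAAAAC")  # -log(0.9)
#' @export
poisson_distance <- function(seqA, seqB) {
  a <- strsplit(seqA, "")[[1]]
  b <- strsplit(seqB, "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length",
                                   call. = FALSE)
  p <- mean(a != b)
  if (p >= 1) stop("saturated pair (p = 1): Poisson distance infinite",
                   call. = FALSE)
  -log(1 - p)
}

#' Poisson distance matrix of an alignment
#'
#' @param aln named character vector (or matrix) of aligned sequences,
#'   assumed already gap-free (see [complete_deletion()]).
#' @return symmetric distance matrix with taxa dimnames.
#' @export
poisson_dist_matrix <- function(aln) {
  m <- .aln_matrix(aln)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- mean(m[i, ] != m[j, ])
      if (p >= 1) stop("saturated pair (p = 1): Poisson distance infinite",
                       call. = FALSE)
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou–Nei neighbor joining on a symmetric distance matrix with the
#' standard Q-criterion. Determinism is fixed: ties in Q are broken by the
#' lowest `(i, j)` index pair, and a negative branch length is clamped to
#' 0 with the excess transferred to the adjacent (sister) branch so the
#' pair sum is preserved. On an additive matrix the generating tree is
#' recovered exactly.
#'
#' @param dist symmetric numeric matrix with zero diagonal, taxa dimnames,
#'   and `n >= 3`; `NA`/`NaN` entries are an error.
#' @return an unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(dist) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (n < 3L) stop("need >= 3 taxa", call. = FALSE)
  if (any(is.na(D))) stop("NA/NaN in distance matrix", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  }
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  frag <- labs
  act <- seq_len(n)
  fmt <- function(x) sprintf("%.12g", x)
  while (length(act) > 3L) {
    m <- length(act)
    sub <- D[act, act, drop = FALSE]
    r <- rowSums(sub)
    best <- NULL
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) {
        q <- (m - 2) * sub[a, b] - r[a] - r[b]
        if (is.null(best) || q < best$q - 1e-12) best <- list(q = q, a = a, b = b)
      }
    }
    a <- best$a; b <- best$b
    dij <- sub[a, b]
    la <- dij / 2 + (r[a] - r[b]) / (2 * (m - 2))
    lb <- dij - la
    if (la < 0) { lb <- lb + la; la <- 0 }
    if (lb < 0) { la <- la + lb; lb <- 0 }
    la <- max(la, 0); lb <- max(lb, 0)
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[act[a]], fmt(la),
                       frag[act[b]], fmt(lb))
    others <- act[-c(a, b)]
    dnew <- pmax((D[act[a], others] + D[act[b], others] - dij) / 2, 0)
    u <- act[a]                      # reuse slot a for the new node
    D[u, others] <- dnew
    D[others, u] <- dnew
    D[u, u] <- 0
    frag[u] <- newfrag
    act <- c(u, others)
  }
  i <- act[1]; j <- act[2]; k <- act[3]
  li <- max((D[i, j] + D[i, k] - D[j, k]) / 2, 0)
  lj <- max((D[i, j] + D[j, k] - D[i, k]) / 2, 0)
  lk <- max((D[i, k] + D[j, k] - D[i, j]) / 2, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[i], fmt(li), frag[j], fmt(lj),
                 frag[k], fmt(lk))
  ape::read.tree(text = nwk)
}

# Canonical bipartition keys of all informative internal edges.
.tree_splits <- function(tree, taxa) {
  n <- length(taxa)
  pp <- ape::prop.part(tree)
  tips <- attr(pp, "labels")
  ntip <- length(tips)
  keys <- character(0)
  nodes <- integer(0)
  for (v in seq_along(pp)) {
    clade <- tips[pp[[v]]]
    size <- length(clade)
    if (size < 2L || size > n - 2L) next
    memb <- taxa %in% clade
    if (memb[1]) memb <- !memb
    keys <- c(keys, paste(as.integer(memb), collapse = ""))
    nodes <- c(nodes, ntip + v)
  }
  list(keys = keys, nodes = nodes)
}

#' Bootstrap-supported neighbor-joining tree
#'
#' Builds the full-data tree ([complete_deletion()] ->
#' [poisson_dist_matrix()] -> [nj_tree()]), then resamples alignment
#' columns with replacement `B` times, rebuilds the tree for each
#' replicate, and scores each internal branch of the full-data tree by the
#' percentage of replicates containing the same bipartition. Supports are
#' mapped onto the full-data tree (not a consensus); branches with support
#' below `collapse_below` are then collapsed into multifurcations.
#'
#' @param aln named character vector of aligned protein sequences.
#' @param B bootstrap replicates (default 1000).
#' @param collapse_below support percentage below which internal branches
#'   collapse (default 50); `0` disables collapsing.
#' @param seed RNG seed.
#' @return an `ape::phylo` tree whose internal `node.label`s are bootstrap
#'   percentages; the uncollapsed tree is attached as attribute
#'   `full_tree`.
#' @export
bootstrap_tree <- function(aln, B = 1000, collapse_below = 50, seed = 1) {
  if (B < 1) stop("`B` must be >= 1", call. = FALSE)
  aln <- complete_deletion(aln)
  m <- .aln_matrix(aln)
  taxa <- sort(rownames(m))
  main <- nj_tree(poisson_dist_matrix(m))
  sp <- .tree_splits(main, taxa)
  counts <- setNames(rep(0L, length(sp$keys)), sp$keys)
  with_seed(seed, {
    for (b in seq_len(B)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      tb <- nj_tree(poisson_dist_matrix(m[, cols, drop = FALSE]))
      kb <- .tree_splits(tb, taxa)$keys
      hit <- sp$keys %in% kb
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- 100 * counts / B
  ntip <- length(main$tip.label)
  labels <- rep("", main$Nnode)
  labels[sp$nodes - ntip] <- as.character(round(support, 1))
  main$node.label <- labels
  full <- main
  if (collapse_below > 0 && any(support < collapse_below)) {
    low_nodes <- sp$nodes[support < collapse_below]
    low_edges <- main$edge[, 2] %in% low_nodes
    main$edge.length[low_edges] <- 0
    main <- ape::di2multi(main, tol = 1e-11)
  }
  attr(main, "full_tree") <- full
  main
}
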