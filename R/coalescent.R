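# Two-population structured coalescent with a domestication bottleneck in
# the domesticated lineage, plus infinite-sites mutation, used as the
# neutral null for the selection scan. Times are in generations backwards
# from the present; sizes are diploid effective sizes, so a pair of
# lineages in a population of size N coalesces at rate 1/(2N) per
# generation.

#' Specify a two-population domestication-bottleneck model
#'
#' Backwards in time the domesticated (maize) lineage has size
#' `N_maize_now` until `t_bottleneck_end`, then `N_maize_bottleneck` until
#' `t_split`, when both lineages merge into an ancestral population of size
#' `N_anc`; the wild (teosinte) lineage has constant size `N_teosinte`
#' until the split. Defaults follow literature-typical maize domestication
#' values: ancestral and teosinte size 150,000; a bottleneck to 5% of the
#' ancestral size lasting 1,000 generations and ending 9,000 generations
#' ago; mutation rate 3e-8 per bp per generation. These are configuration,
#' not estimates made by this package.
#'
#' @param N_anc,N_teosinte,N_maize_bottleneck,N_maize_now diploid effective
#'   sizes.
#' @param t_split,t_bottleneck_end times in generations
#'   (`t_bottleneck_end < t_split`).
#' @param mu per-bp per-generation mutation rate.
#' @param r per-bp recombination rate; only `r = 0` is simulated (windows
#'   are short).
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(N_anc = 150000, N_teosinte = 150000,
                              N_maize_bottleneck = 7500,
                              N_maize_now = 150000,
                              t_split = 10000, t_bottleneck_end = 9000,
                              mu = 3e-8, r = 0) {
  for (nm in c("N_anc", "N_teosinte", "N_maize_bottleneck", "N_maize_now",
               "t_split", "t_bottleneck_end")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  stopifnot_scalar_pos(mu, "mu", strict = FALSE)
  if (t_bottleneck_end >= t_split) {
    stop("`t_bottleneck_end` must be < `t_split`", call. = FALSE)
  }
  if (r != 0) {
    stop("only r = 0 (no recombination) is supported", call. = FALSE)
  }
  structure(
    list(N_anc = N_anc, N_teosinte = N_teosinte,
         N_maize_bottleneck = N_maize_bottleneck, N_maize_now = N_maize_now,
         t_split = t_split, t_bottleneck_end = t_bottleneck_end,
         mu = mu, r = r),
    class = "demographic_model"
  )
}

#' Simulate one neutral window under the bottleneck model
#'
#' Draws a genealogy of `n1` teosinte and `n2` maize haplotypes from the
#' structured coalescent of the two-population history, then drops
#' infinite-sites mutations (Poisson with rate `mu * L` per lineage per
#' generation; distinct integer positions in `1..L`). When one of the
#' sample sizes is 0, a single constant-size population is simulated
#' (teosinte at `N_teosinte`, maize ignoring the split): for such a
#' population the expected per-site diversity is `4 N mu`.
#'
#' @param model a [demographic_model()].
#' @param L window length in bp.
#' @param n1 number of teosinte haplotypes sampled.
#' @param n2 number of maize haplotypes sampled.
#' @param seed RNG seed.
#' @return a [haplotype_matrix()] with labels `teosinte` / `maize` and
#'   `region_start = 1`, `region_end = L`.
#' @export
simulate_coalescent_window <- function(model, L, n1, n2, seed) {
  stopifnot(inherits(model, "demographic_model"))
  stopifnot_scalar_pos(L, "L")
  if (n1 + n2 < 2) stop("need at least 2 sampled haplotypes", call. = FALSE)
  with_seed(seed, {
    tree <- .sim_genealogy(model, n1, n2)
    .drop_mutations(tree, model$mu, L, n1, n2)
  })
}

# Genealogy of n1 + n2 leaves. Returns parent pointers, node times and
# children lists; leaves are nodes 1..n (teosinte first).
.sim_genealogy <- function(model, n1, n2) {
  n <- n1 + n2
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  children <- vector("list", n_nodes)
  next_node <- n + 1L
  # active lineages per population
  act <- list(teosinte = seq_len(n1), maize = if (n2 > 0) n1 + seq_len(n2) else integer(0))
  single_pop <- n1 == 0L || n2 == 0L
  if (single_pop) {
    act <- list(all = seq_len(n))
  }
  t_now <- 0
  pop_size <- function(pop, t) {
    if (single_pop) {
      return(if (n2 == 0L) model$N_teosinte else model$N_maize_now)
    }
    switch(pop,
      teosinte = model$N_teosinte,
      maize = if (t < model$t_bottleneck_end) model$N_maize_now
              else model$N_maize_bottleneck,
      all = model$N_anc)
  }
  boundaries <- if (single_pop) numeric(0) else
    c(model$t_bottleneck_end, model$t_split)
  merged <- single_pop
  repeat {
    k <- vapply(act, length, integer(1))
    if (sum(k) <= 1L) break
    rates <- vapply(names(act), function(p) {
      kp <- length(act[[p]])
      if (kp < 2L) 0 else kp * (kp - 1) / 2 / (2 * pop_size(p, t_now))
    }, numeric(1))
    tot <- sum(rates)
    nxt_b <- boundaries[boundaries > t_now]
    t_event <- if (tot > 0) t_now + rexp(1, tot) else Inf
    if (length(nxt_b) && t_event > nxt_b[1]) {
      t_now <- nxt_b[1]
      if (!merged && t_now >= model$t_split) {
        act <- list(all = unlist(act, use.names = FALSE))
        merged <- TRUE
        boundaries <- numeric(0)
      }
      next
    }
    if (!is.finite(t_event)) {
      stop("internal: no coalescence possible", call. = FALSE)
    }
    t_now <- t_event
    p <- sample(names(act), 1L, prob = rates / tot)
    pair <- sample(act[[p]], 2L)
    u <- next_node; next_node <- next_node + 1L
    node_time[u] <- t_now
    children[[u]] <- pair
    parent[pair] <- u
    act[[p]] <- c(setdiff(act[[p]], pair), u)
  }
  list(parent = parent, node_time = node_time, children = children,
       n_leaves = n, root = which(parent == 0L & seq_len(n_nodes) >= n)[1])
}

# Infinite-sites mutations onto the genealogy -> haplotype_matrix.
.drop_mutations <- function(tree, mu, L, n1, n2) {
  n <- tree$n_leaves
  non_root <- setdiff(seq_along(tree$parent), tree$root)
  non_root <- non_root[tree$parent[non_root] != 0L]
  elen <- tree$node_time[tree$parent[non_root]] - tree$node_time[non_root]
  total <- sum(elen)
  S <- rpois(1L, mu * L * total)
  if (S > L) {
    warning("more mutations than sites; capping at L (infinite-sites saturated)")
    S <- as.integer(L)
  }
  labels <- c(rep("teosinte", n1), rep("maize", n2))
  if (n1 == 0L) labels <- rep("maize", n2)
  if (n2 == 0L) labels <- rep("teosinte", n1)
  if (S == 0L) {
    return(haplotype_matrix(matrix(0L, n, 0L), numeric(0), labels,
                            contig = "sim", region_start = 1, region_end = L))
  }
  pos <- sort(sample.int(as.integer(L), S))
  edge_of_mut <- sample(seq_along(non_root), S, replace = TRUE,
                        prob = elen / total)
  # leaf sets below each node
  below <- vector("list", length(tree$parent))
  for (i in seq_len(n)) below[[i]] <- i
  ord <- order(tree$node_time[seq_along(tree$parent)])
  for (u in ord) {
    if (u > n && !is.null(tree$children[[u]])) {
      below[[u]] <- c(below[[tree$children[[u]][1]]],
                      below[[tree$children[[u]][2]]])
    }
  }
  alleles <- matrix(0L, n, S)
  for (s in seq_len(S)) {
    carriers <- below[[non_root[edge_of_mut[s]]]]
    alleles[carriers, s] <- 1L
  }
  haplotype_matrix(alleles, pos, labels, contig = "sim",
                   region_start = 1, region_end = L)
}
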