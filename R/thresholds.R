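# Significance thresholds for the selection scan: an empirical
# label-permutation null on the observed data, and a neutral coalescent
# bottleneck null. Quantiles use linear interpolation of the empirical CDF
# (type 4), so e.g. the 95% point of 1000 simulations is exactly the 950th
# order statistic.

#' Permutation threshold for the window-FST scan
#'
#' Shuffles the population labels `n_perm` times; for each shuffle the full
#' window scan is recomputed and the maximum window FST recorded. The
#' threshold is the `1 - alpha` empirical quantile of these maxima, i.e. a
#' familywise bound on the scan maximum under exchangeable labels.
#'
#' @param hm a [haplotype_matrix()] (>= 4 haplotypes).
#' @param window_bp,step_bp,min_sites scan parameters (see [window_scan()]).
#' @param n_perm number of label permutations (>= 100).
#' @param alpha tail probability (default 0.05).
#' @param seed RNG seed.
#' @return the FST threshold (numeric scalar), with the permuted maxima as
#'   attribute `max_fst`.
#' @export
permutation_threshold <- function(hm, window_bp = 3000, step_bp = 100,
                                  min_sites = 3, n_perm = 1000, alpha = 0.05,
                                  seed = 1) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  if (nrow(hm$alleles) < 4L) {
    stop("need >= 4 haplotypes to permute labels meaningfully", call. = FALSE)
  }
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  maxima <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      hp <- hm
      hp$pop_labels <- sample(hm$pop_labels)
      sc <- window_scan(hp, window_bp, step_bp, min_sites)
      m <- suppressWarnings(max(sc$fst, na.rm = TRUE))
      if (is.finite(m)) m else NA_real_
    }, numeric(1))
  })
  maxima <- maxima[is.finite(maxima)]
  if (!length(maxima)) stop("no permutation produced a defined window FST",
                            call. = FALSE)
  thr <- empirical_quantile(maxima, 1 - alpha)
  attr(thr, "max_fst") <- maxima
  thr
}

#' Neutral-bottleneck thresholds for window FST and the diversity ratio
#'
#' Simulates `n_sim` independent neutral windows under the
#' domestication-bottleneck model and returns the `1 - alpha` quantiles of
#' the window FST and of the diversity ratio
#' `pi_teosinte / pi_maize`. Windows where `pi_maize = 0` are excluded from
#' the ratio distribution (their count is reported via a message and the
#' `n_ratio_excluded` attribute).
#'
#' @param model a [demographic_model()].
#' @param window_bp simulated window length in bp.
#' @param n_sim number of neutral windows (>= 200).
#' @param n1,n2 teosinte / maize sample sizes (haplotypes).
#' @param alpha tail probability (default 0.05).
#' @param seed RNG seed.
#' @return list with `fst_threshold`, `pi_ratio_threshold`, and the null
#'   distributions `fst`, `pi_ratio`.
#' @export
bottleneck_threshold <- function(model, window_bp = 3000, n_sim = 1000,
                                 n1 = 18, n2 = 40, alpha = 0.05, seed = 1) {
  stopifnot(inherits(model, "demographic_model"))
  if (n_sim < 200) stop("`n_sim` must be >= 200", call. = FALSE)
  fst <- ratio <- rep(NA_real_, n_sim)
  for (i in seq_len(n_sim)) {
    hm <- simulate_coalescent_window(model, window_bp, n1, n2,
                                     seed = substream_seed(seed, i))
    st <- .site_stats(hm$alleles, hm$pop_labels == "teosinte",
                      hm$pop_labels == "maize")
    seg <- st$segregating
    dsum <- sum(st$d[seg])
    if (dsum > 0) fst[i] <- sum(st$a[seg]) / dsum
    pi_t <- sum(st$pi1) / window_bp
    pi_m <- sum(st$pi2) / window_bp
    if (pi_m > 0) ratio[i] <- pi_t / pi_m
  }
  n_excl <- sum(is.na(ratio))
  if (n_excl > 0) {
    message(sprintf("%d window(s) with pi_maize = 0 excluded from the ratio null",
                    n_excl))
  }
  out <- list(
    fst_threshold = empirical_quantile(fst[is.finite(fst)], 1 - alpha),
    pi_ratio_threshold = empirical_quantile(ratio[is.finite(ratio)], 1 - alpha),
    fst = fst, pi_ratio = ratio
  )
  attr(out, "n_ratio_excluded") <- n_excl
  out
}
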