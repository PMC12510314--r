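# Multiple-comparison machinery shared by the binding-kinetics and
# phenotype modules: Monte-Carlo Dunnett many-to-one comparisons and
# Scheffe simultaneous pairwise letters.

#' Monte-Carlo Dunnett critical value
#'
#' Two-sided critical value of the Dunnett many-to-one max-|t| statistic for
#' `k` treatment groups compared against one control, estimated by
#' Monte-Carlo simulation of the underlying multivariate t (group means
#' drawn independently, a shared chi-square error scale, max over the `k`
#' standardized contrasts). With balanced groups this reproduces published
#' Dunnett table values (e.g. k = 2, df = 6, alpha = 0.05 gives ~2.86).
#'
#' @param k number of treatment groups (excluding the control).
#' @param df error degrees of freedom.
#' @param alpha familywise error rate (two-sided; default 0.05).
#' @param n_control,n_treat group sizes (defaults balanced; only the ratio
#'   matters).
#' @param n_draws Monte-Carlo draws (default 1e5).
#' @param seed RNG seed (default 20260501).
#' @return the critical value (numeric scalar).
#' @export
dunnett_critical_value <- function(k, df, alpha = 0.05, n_control = 1,
                                   n_treat = rep(1, k), n_draws = 1e5,
                                   seed = 20260501) {
  stopifnot(k >= 1, df >= 1, length(n_treat) == k)
  maxT <- .dunnett_maxT_draws(k, df, n_control, n_treat, n_draws, seed)
  empirical_quantile(maxT, 1 - alpha)
}

.dunnett_maxT_draws <- function(k, df, n_control, n_treat, n_draws, seed) {
  with_seed(seed, {
    m0 <- rnorm(n_draws, sd = sqrt(1 / n_control))
    s <- sqrt(rchisq(n_draws, df) / df)
    maxT <- rep(0, n_draws)
    for (j in seq_len(k)) {
      mj <- rnorm(n_draws, sd = sqrt(1 / n_treat[j]))
      tj <- abs(mj - m0) / (s * sqrt(1 / n_treat[j] + 1 / n_control))
      maxT <- pmax(maxT, tj)
    }
    maxT
  })
}

#' Dunnett many-to-one comparisons against a control
#'
#' One-way layout: each treatment group is compared with the named control
#' using the pooled error variance; adjusted p-values are tail probabilities
#' of the Monte-Carlo max-|t| Dunnett distribution (see
#' [dunnett_critical_value()]). With a single treatment group the statistic
#' reduces to an ordinary two-sided t test and no adjustment is applied.
#'
#' @param values named list (or a `group`/`y` data frame) of replicate
#'   measurements per group; must include `control`.
#' @param control name of the control group.
#' @param alpha familywise level, used only for the reported critical value.
#' @param n_draws,seed Monte-Carlo settings (see [dunnett_critical_value()]).
#' @return data frame with one row per non-control group: `group`, `diff`,
#'   `t`, `p_adj`, plus attributes `crit` and `df`.
#' @export
dunnett_vs_control <- function(values, control, alpha = 0.05,
                               n_draws = 1e5, seed = 20260501) {
  if (is.data.frame(values)) {
    values <- split(values$y, values$group)
  }
  stopifnot(is.list(values), control %in% names(values))
  ns <- lengths(values)
  if (any(ns < 2L)) stop("every group needs >= 2 replicates", call. = FALSE)
  groups <- setdiff(names(values), control)
  k <- length(groups)
  if (k < 1L) stop("no non-control groups", call. = FALSE)
  means <- vapply(values, mean, numeric(1))
  N <- sum(ns)
  mse <- sum(vapply(values, function(v) sum((v - mean(v))^2), numeric(1))) /
    (N - length(values))
  df <- N - length(values)
  tstat <- (means[groups] - means[control]) /
    sqrt(mse * (1 / ns[groups] + 1 / ns[control]))
  if (k == 1L) {
    p_adj <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
    crit <- qt(1 - alpha / 2, df)
  } else {
    maxT <- .dunnett_maxT_draws(k, df, ns[control], ns[groups], n_draws, seed)
    p_adj <- vapply(abs(tstat), function(t0) mean(maxT >= t0), numeric(1))
    crit <- empirical_quantile(maxT, 1 - alpha)
  }
  out <- data.frame(group = groups, diff = unname(means[groups] - means[control]),
                    t = unname(tstat), p_adj = unname(p_adj),
                    row.names = NULL)
  attr(out, "crit") <- crit
  attr(out, "df") <- df
  out
}

#' Scheffé simultaneous pairwise comparisons with letter groupings
#'
#' One-way ANOVA followed by Scheffé's simultaneous pairwise criterion:
#' groups `i`, `j` differ when
#' `(m_i - m_j)^2 > (g - 1) F(1 - alpha; g - 1, df) * MSE * (1/n_i + 1/n_j)`.
#' Compact letters are assigned from maximal runs of mutually
#' non-significant groups along the mean ordering; groups sharing a letter
#' are not significantly different.
#'
#' @param values named list (or `group`/`y` data frame) of replicate values.
#' @param alpha simultaneous level (default 0.05).
#' @return data frame `group`, `mean`, `n`, `letters` (ordered by mean,
#'   descending), with the ANOVA p-value as attribute `anova_p`.
#' @export
scheffe_groups <- function(values, alpha = 0.05) {
  if (is.data.frame(values)) {
    values <- split(values$y, values$group)
  }
  ns <- lengths(values)
  keep <- ns >= 2L | vapply(values, function(v) var(v) > 0, logical(1))
  if (any(!keep)) {
    warning(sprintf("excluding %d group(s) with n = 1 and no variance",
                    sum(!keep)))
    values <- values[keep]
    ns <- ns[keep]
  }
  g <- length(values)
  stopifnot(g >= 2L)
  means <- vapply(values, mean, numeric(1))
  N <- sum(ns)
  df <- N - g
  mse <- sum(vapply(values, function(v) sum((v - mean(v))^2), numeric(1))) / df
  msb <- sum(ns * (means - sum(ns * means) / N)^2) / (g - 1)
  anova_p <- pf(msb / mse, g - 1, df, lower.tail = FALSE)
  fcrit <- (g - 1) * qf(1 - alpha, g - 1, df)
  differs <- function(i, j) {
    (means[i] - means[j])^2 > fcrit * mse * (1 / ns[i] + 1 / ns[j])
  }
  ord <- order(means, decreasing = TRUE)
  runs <- list()
  for (i in seq_len(g)) {
    j <- i
    while (j < g && !any(vapply(i:j, function(a) differs(ord[a], ord[j + 1L]),
                                logical(1)))) {
      j <- j + 1L
    }
    runs[[length(runs) + 1L]] <- i:j
  }
  # drop runs contained in another run
  keep_run <- vapply(seq_along(runs), function(a) {
    !any(vapply(seq_along(runs), function(b) {
      b != a && all(runs[[a]] %in% runs[[b]])
    }, logical(1)))
  }, logical(1))
  runs <- unique(runs[keep_run])
  letter <- vapply(seq_len(g), function(i) {
    paste0(letters[which(vapply(runs, function(r) i %in% r, logical(1)))],
           collapse = "")
  }, character(1))
  out <- data.frame(group = names(values)[ord], mean = unname(means[ord]),
                    n = unname(ns[ord]), letters = letter, row.names = NULL)
  attr(out, "anova_p") <- anova_p
  out
}

#' Treatment-comparison statistics for a KD table
#'
#' Reproduces the analysis layout applied to a KD time-course table:
#' within each aging stratum and incubation duration, a one-way ANOVA
#' across treatments plus Dunnett comparisons of each enzyme treatment
#' against the no-enzyme control; and within each aging stratum and
#' treatment, Scheffé letters across incubation durations.
#'
#' @param kd_table data frame with columns `treatment`, `aging`,
#'   `incubation_h`, `replicate`, `kd` (one row per replicate estimate; rows
#'   with `NA` kd are dropped).
#' @param control treatment label of the no-enzyme control
#'   (default `"alone"`).
#' @param alpha level for both procedures (default 0.05).
#' @param n_draws,seed Monte-Carlo Dunnett settings.
#' @return list with data frames `anova` (aging, incubation_h, p),
#'   `scheffe` (aging, treatment, incubation_h ordered by mean, letters) and
#'   `dunnett` (aging, incubation_h, group, diff, t, p_adj).
#' @export
compare_treatments <- function(kd_table, control = "alone", alpha = 0.05,
                               n_draws = 1e5, seed = 20260501) {
  need <- c("treatment", "aging", "incubation_h", "replicate", "kd")
  stopifnot(is.data.frame(kd_table), all(need %in% names(kd_table)))
  kd_table <- kd_table[is.finite(kd_table$kd), , drop = FALSE]

  anova_rows <- list(); dunnett_rows <- list(); scheffe_rows <- list()
  for (ag in unique(kd_table$aging)) {
    sub_ag <- kd_table[kd_table$aging == ag, , drop = FALSE]
    for (h in sort(unique(sub_ag$incubation_h))) {
      sub <- sub_ag[sub_ag$incubation_h == h, , drop = FALSE]
      vals <- split(sub$kd, sub$treatment)
      vals <- vals[lengths(vals) >= 2L]
      if (length(vals) >= 2L) {
        sg <- scheffe_groups(vals, alpha)
        anova_rows[[length(anova_rows) + 1L]] <-
          data.frame(aging = ag, incubation_h = h, p = attr(sg, "anova_p"))
        if (control %in% names(vals)) {
          dd <- dunnett_vs_control(vals, control, alpha, n_draws, seed)
          dd <- cbind(aging = ag, incubation_h = h, dd)
          dunnett_rows[[length(dunnett_rows) + 1L]] <- dd
        }
      }
    }
    for (tr in unique(sub_ag$treatment)) {
      sub <- sub_ag[sub_ag$treatment == tr, , drop = FALSE]
      vals <- split(sub$kd, sub$incubation_h)
      vals <- vals[lengths(vals) >= 2L]
      if (length(vals) >= 2L) {
        sg <- scheffe_groups(vals, alpha)
        scheffe_rows[[length(scheffe_rows) + 1L]] <-
          cbind(aging = ag, treatment = tr,
                setNames(sg, c("incubation_h", "mean", "n", "letters")))
      }
    }
  }
  list(anova = do.call(rbind, anova_rows),
       scheffe = do.call(rbind, scheffe_rows),
       dunnett = do.call(rbind, dunnett_rows))
}
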