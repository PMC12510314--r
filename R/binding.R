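# Ligand-depletion binding model and dissociation-constant fitting.
#
# The dose-response ladder titrates the ligand (protein) against a fixed,
# labelled target (poly(A) mRNA, ~89 nM). Because the target is not always
# negligible against the KD ladder, the single-site quadratic depletion
# isotherm is used throughout; it reduces to L/(L+KD) as the target
# concentration goes to 0.

#' Fraction of target bound under ligand depletion
#'
#' Single-site mass-action isotherm accounting for target (and hence ligand)
#' depletion: with total ligand `L`, total target `T` and dissociation
#' constant `kd`,
#' `FB = ((L + T + kd) - sqrt((L + T + kd)^2 - 4 L T)) / (2 T)`.
#' Continuous, increasing in `L`, decreasing in `kd`; for `T = 0` defined by
#' the limit `L / (L + kd)`.
#'
#' @param L_tot total ligand concentration (µM); vectorized.
#' @param T_tot total target concentration (µM).
#' @param kd dissociation constant (µM), > 0.
#' @return fraction bound in `[0, 1]`, same length as `L_tot`.
#' @examples
#' fraction_bound(2.85, T_tot = 0, kd = 2.85)  # half saturation
#' @export
fraction_bound <- function(L_tot, T_tot, kd) {
  stopifnot_scalar_pos(kd, "kd")
  stopifnot_scalar_pos(T_tot, "T_tot", strict = FALSE)
  if (any(L_tot < 0)) stop("`L_tot` must be >= 0", call. = FALSE)
  if (T_tot == 0) {
    return(L_tot / (L_tot + kd))
  }
  s <- L_tot + T_tot + kd
  disc <- pmax(s^2 - 4 * L_tot * T_tot, 0)
  fb <- (s - sqrt(disc)) / (2 * T_tot)
  pmin(pmax(fb, 0), 1)
}

# Residual sum of squares profiled over the linear parameters (unbound
# level and amplitude) at a fixed kd. Returns RSS and the linear fit.
.kd_profile <- function(log10_kd, L, y, T_tot) {
  fb <- fraction_bound(L, T_tot, 10^log10_kd)
  X <- cbind(1, fb)
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), unbound = fit$coefficients[[1]],
       amplitude = fit$coefficients[[2]], resid = fit$residuals)
}

# One-series least-squares fit: multi-start 1D optimization of kd on the
# log10 scale with the two level parameters profiled out.
.fit_kd_single <- function(L, y, T_tot, n_starts = 7L) {
  lo <- log10(min(L) / 10)
  hi <- log10(max(L) * 10)
  starts <- seq(lo, hi, length.out = n_starts)
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::nlminb(s, function(lk) .kd_profile(lk, L, y, T_tot)$rss,
                    lower = lo, upper = hi),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    cand <- list(log10_kd = opt$par, rss = opt$objective,
                 converged = opt$convergence == 0)
    if (is.null(best) || cand$rss < best$rss - 1e-12 ||
        (abs(cand$rss - best$rss) <= 1e-12 && cand$log10_kd < best$log10_kd)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    return(list(converged = FALSE))
  }
  prof <- .kd_profile(best$log10_kd, L, y, T_tot)
  kd <- 10^best$log10_kd
  n <- length(y)
  sigma2 <- prof$rss / max(n - 3, 1)
  # curvature of RSS in kd (not log kd) for a fallback standard error
  h <- kd * 1e-4
  r_p <- .kd_profile(log10(kd + h), L, y, T_tot)$rss
  r_m <- .kd_profile(log10(max(kd - h, 1e-12)), L, y, T_tot)$rss
  d2 <- (r_p - 2 * prof$rss + r_m) / h^2
  se_curv <- if (is.finite(d2) && d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
  list(kd = kd, rss = prof$rss, unbound = prof$unbound,
       amplitude = prof$amplitude, resid_sd = sqrt(sigma2),
       se_curvature = se_curv, converged = best$converged,
       at_bound = best$log10_kd <= lo + 1e-8 || best$log10_kd >= hi - 1e-8)
}

#' Fit a dissociation constant to one binding-series ladder
#'
#' Least-squares fit of `fnorm = unbound + (bound - unbound) * FB(L, T, kd)`
#' (see [fraction_bound()]) over the unflagged wells of a ladder, with the
#' two fluorescence levels profiled out and `kd` optimized on a log scale
#' from a multi-start grid spanning `[min(conc)/10, max(conc) * 10]`.
#'
#' When the series holds 3 or more replicates, each replicate ladder is fit
#' separately: the reported `kd` is the replicate mean and `se` the standard
#' error of that mean (as the source assays report "mean KD +/- SE, n = 3").
#' With fewer replicates, a pooled fit is used and `se` comes from the
#' curvature of the residual sum of squares at the optimum.
#'
#' The estimate is flagged `legitimate = FALSE` (with a `reason`) when the
#' fit fails to converge, when the fitted amplitude is below
#' `min_amplitude_snr` times the residual standard deviation, or when the
#' fitted `kd` falls at the edge of the search range.
#'
#' @param series a data frame with columns `ligand_conc_uM`, `fnorm`, and
#'   optionally `replicate` and `well_flag` (non-empty flags exclude wells),
#'   e.g. one element of [gen_binding_plate()] output or a [qc_series()]
#'   result.
#' @param target_conc_nM total labelled-target concentration in nM
#'   (default 89).
#' @param min_amplitude_snr legitimacy threshold on amplitude / residual SD
#'   (default 3).
#' @return an object of class `kd_estimate`: list with `kd`, `se`,
#'   `bound_level`, `unbound_level`, `n_wells_used`, `legitimate`, `reason`,
#'   and `replicate_kds`.
#' @export
fit_kd <- function(series, target_conc_nM = 89, min_amplitude_snr = 3) {
  stopifnot(is.data.frame(series),
            all(c("ligand_conc_uM", "fnorm") %in% names(series)))
  if (!is.null(series$well_flag)) {
    series <- series[is.na(series$well_flag) | series$well_flag == "", ,
                     drop = FALSE]
  }
  series <- series[is.finite(series$fnorm), , drop = FALSE]
  if (!is.null(attr(series, "usable")) && !attr(series, "usable")) {
    return(.kd_illegitimate("series_unusable", nrow(series)))
  }
  L <- series$ligand_conc_uM
  if (nrow(series) < 5L) {
    return(.kd_illegitimate("too_few_wells", nrow(series)))
  }
  if (max(L) / min(L) < 100) {
    return(.kd_illegitimate("ladder_span_lt_2_decades", nrow(series)))
  }
  T_uM <- target_conc_nM / 1000
  reps <- if (is.null(series$replicate)) rep(1L, nrow(series)) else series$replicate
  rep_ids <- unique(reps)

  if (length(rep_ids) >= 3L) {
    fits <- lapply(rep_ids, function(r) {
      idx <- reps == r
      .fit_kd_single(L[idx], series$fnorm[idx], T_uM)
    })
    ok <- vapply(fits, function(f) isTRUE(f$converged) && !f$at_bound, logical(1))
    if (!any(ok)) return(.kd_illegitimate("no_convergence", nrow(series)))
    kds <- vapply(fits[ok], `[[`, numeric(1), "kd")
    kd <- mean(kds)
    se <- if (length(kds) >= 2) sd(kds) / sqrt(length(kds)) else NA_real_
    pooled <- .fit_kd_single(L, series$fnorm, T_uM)
    est <- list(kd = kd, se = se, bound = pooled$unbound + pooled$amplitude,
                unbound = pooled$unbound, amplitude = pooled$amplitude,
                resid_sd = pooled$resid_sd, replicate_kds = kds,
                converged = TRUE, at_bound = any(!ok))
  } else {
    f <- .fit_kd_single(L, series$fnorm, T_uM)
    if (!isTRUE(f$converged)) return(.kd_illegitimate("no_convergence", nrow(series)))
    est <- list(kd = f$kd, se = f$se_curvature,
                bound = f$unbound + f$amplitude, unbound = f$unbound,
                amplitude = f$amplitude, resid_sd = f$resid_sd,
                replicate_kds = f$kd, converged = TRUE, at_bound = f$at_bound)
  }

  legitimate <- TRUE
  reason <- ""
  if (est$at_bound) {
    legitimate <- FALSE
    reason <- "kd_outside_ladder_range"
  }
  if (legitimate && est$resid_sd > 0 &&
      abs(est$amplitude) < min_amplitude_snr * est$resid_sd) {
    legitimate <- FALSE
    reason <- "amplitude_below_noise"
  }
  structure(
    list(kd = est$kd, se = est$se, bound_level = est$bound,
         unbound_level = est$unbound, n_wells_used = nrow(series),
         legitimate = legitimate, reason = reason,
         replicate_kds = est$replicate_kds),
    class = "kd_estimate"
  )
}

.kd_illegitimate <- function(reason, n_used) {
  structure(
    list(kd = NA_real_, se = NA_real_, bound_level = NA_real_,
         unbound_level = NA_real_, n_wells_used = n_used,
         legitimate = FALSE, reason = reason, replicate_kds = numeric(0)),
    class = "kd_estimate"
  )
}

#' @export
print.kd_estimate <- function(x, ...) {
  if (x$legitimate) {
    cat(sprintf("KD = %.4g uM (SE %.3g), %d wells\n", x$kd, x$se,
                x$n_wells_used))
  } else {
    cat(sprintf("no legitimate KD (%s)\n", x$reason))
  }
  invisible(x)
}

#' Quality-control a binding series
#'
#' Flags wells before fitting, mirroring the screening that binding-assay
#' software applies: `outlier` when the studentized residual from a
#' provisional ladder fit exceeds `outlier_z`, and `inhomogeneous` when the
#' well's initial fluorescence (column `init_fluor`, when present) deviates
#' from the ladder median by more than `homogeneity_tol` as a fraction.
#' Flagged wells are excluded by [fit_kd()]. When more than half of the
#' wells are flagged the whole series is marked unusable.
#'
#' @param series binding-series data frame (see [fit_kd()]); replicates are
#'   QCed independently when a `replicate` column is present.
#' @param homogeneity_tol fractional tolerance on initial fluorescence
#'   (default 0.2).
#' @param outlier_z studentized-residual threshold (default 3).
#' @param target_conc_nM target concentration for the provisional fit.
#' @return `series` with a `well_flag` character column (`""` for clean
#'   wells) and attribute `usable` (FALSE when > 50% flagged).
#' @export
qc_series <- function(series, homogeneity_tol = 0.2, outlier_z = 3,
                      target_conc_nM = 89) {
  stopifnot(is.data.frame(series))
  flags <- character(nrow(series))
  if (!is.null(series$init_fluor)) {
    med <- median(series$init_fluor, na.rm = TRUE)
    bad <- abs(series$init_fluor - med) > homogeneity_tol * abs(med)
    flags[bad] <- "inhomogeneous"
  }
  reps <- if (is.null(series$replicate)) rep(1L, nrow(series)) else series$replicate
  for (r in unique(reps)) {
    idx <- which(reps == r & flags == "")
    if (length(idx) < 5L) next
    f <- .fit_kd_single(series$ligand_conc_uM[idx], series$fnorm[idx],
                        target_conc_nM / 1000)
    if (!isTRUE(f$converged)) next
    fb <- fraction_bound(series$ligand_conc_uM[idx], target_conc_nM / 1000, f$kd)
    res <- series$fnorm[idx] - (f$unbound + f$amplitude * fb)
    # leave-one-out scale so a single gross outlier cannot mask itself
    z <- vapply(seq_along(res), function(i) {
      s <- sd(res[-i])
      if (s == 0) 0 else abs(res[i]) / s
    }, numeric(1))
    flags[idx[z > outlier_z]] <- "outlier"
  }
  series$well_flag <- flags
  attr(series, "usable") <- mean(flags != "") <= 0.5
  series
}

#' Pairwise leave-one-out standard errors of three replicate KDs
#'
#' From exactly three replicate estimates, returns the standard error of
#' each of the three two-replicate subsets `{1,2}`, `{2,3}`, `{1,3}` (the SE
#' of a pair is `|x - y| / 2`). These resampled SEs feed an ANOVA on
#' estimate variability across treatments.
#'
#' @param replicate_kds numeric vector of exactly 3 replicate KD estimates.
#' @return named numeric vector of 3 standard errors.
#' @examples
#' resample_kd_se(c(1, 2, 3))  # 0.5, 0.5, 1.0
#' @export
resample_kd_se <- function(replicate_kds) {
  if (!is.numeric(replicate_kds) || length(replicate_kds) != 3L ||
      any(!is.finite(replicate_kds))) {
    stop("`replicate_kds` must be exactly 3 finite values", call. = FALSE)
  }
  pairs <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))
  out <- vapply(pairs, function(p) {
    sd(replicate_kds[p]) / sqrt(2)
  }, numeric(1))
  names(out) <- c("rep1_2", "rep2_3", "rep1_3")
  out
}
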