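# Germination time-course summaries and tests, amplicon-length haplotype
# calling, and the expression-GWAS Bonferroni threshold.

#' Germination percentage curve (mean ± SE per timepoint)
#'
#' @param trials data frame with columns `genotype`, `treatment`,
#'   `replicate`, `time_h`, `n_germinated` (cumulative), `n_total`.
#' @param genotype,treatment labels selecting one curve; `NULL` keeps all
#'   rows.
#' @return data frame `time_h`, `n_reps`, `mean_pct`, `se_pct`, ordered by
#'   time; SE is over replicate percentages.
#' @export
germination_percent <- function(trials, genotype = NULL, treatment = NULL) {
  need <- c("replicate", "time_h", "n_germinated", "n_total")
  stopifnot(is.data.frame(trials), all(need %in% names(trials)))
  if (!is.null(genotype)) trials <- trials[trials$genotype == genotype, ]
  if (!is.null(treatment)) trials <- trials[trials$treatment == treatment, ]
  if (length(unique(trials$replicate)) < 2L) {
    stop("need >= 2 replicates", call. = FALSE)
  }
  pct <- 100 * trials$n_germinated / trials$n_total
  times <- sort(unique(trials$time_h))
  n_full <- length(unique(trials$replicate))
  out <- do.call(rbind, lapply(times, function(t0) {
    x <- pct[trials$time_h == t0]
    data.frame(time_h = t0, n_reps = length(x), mean_pct = mean(x),
               se_pct = if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_)
  }))
  if (any(out$n_reps < n_full)) {
    warning("some timepoints missing in one or more replicates; reduced n there")
  }
  attr(out, "replicate_pct") <- split(pct, list(trials$time_h))
  out
}

#' Per-timepoint two-sample t tests between two germination curves
#'
#' Welch's two-sided t test at every shared timepoint (equal-variance
#' Student's t behind `var_equal = TRUE`), with significance stars at the
#' usual printed thresholds (`*` < 0.05, `**` < 0.01, `***` < 0.001).
#' When both groups have zero variance and equal means the p-value is 1.
#'
#' @param trialsA,trialsB data frames as in [germination_percent()], one
#'   group each (already filtered to a genotype/treatment).
#' @param var_equal use the pooled-variance t test (default FALSE = Welch).
#' @return data frame `time_h`, `meanA`, `meanB`, `p`, `stars`.
#' @export
timepoint_tests <- function(trialsA, trialsB, var_equal = FALSE) {
  pctof <- function(tr) {
    stopifnot(all(c("replicate", "time_h", "n_germinated", "n_total") %in%
                    names(tr)))
    data.frame(time_h = tr$time_h, pct = 100 * tr$n_germinated / tr$n_total)
  }
  a <- pctof(trialsA); b <- pctof(trialsB)
  times <- intersect(sort(unique(a$time_h)), sort(unique(b$time_h)))
  out <- do.call(rbind, lapply(times, function(t0) {
    xa <- a$pct[a$time_h == t0]; xb <- b$pct[b$time_h == t0]
    if (length(xa) < 2L || length(xb) < 2L) {
      stop("need >= 2 replicates per group at every timepoint", call. = FALSE)
    }
    p <- if (sd(xa) == 0 && sd(xb) == 0) {
      if (mean(xa) == mean(xb)) 1 else 0
    } else {
      t.test(xa, xb, var.equal = var_equal)$p.value
    }
    data.frame(time_h = t0, meanA = mean(xa), meanB = mean(xb), p = p)
  }))
  out$stars <- cut(out$p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out$stars <- as.character(out$stars)
  out
}

#' Call a promoter haplotype from an amplicon length
#'
#' The two promoter haplotypes are distinguished by an insertion: the
#' short reference amplicon (365 bp, C7-2-like) versus the long one
#' (2682 bp, Z58-like, carrying a 2316-bp insertion). An amplicon within
#' `tol` bp of a reference is assigned that haplotype; anything else is
#' `other`.
#'
#' @param amplicon_bp observed amplicon length(s), bp; vectorized.
#' @param short_ref,long_ref reference lengths (defaults 365 and 2682).
#' @param tol matching tolerance in bp (default 50, a gel-resolution
#'   default).
#' @return character vector: `"Hap_C7-2"`, `"Hap_Z58"` or `"other"`.
#' @examples
#' call_haplotype(c(365, 2682, 1500))
#' @export
call_haplotype <- function(amplicon_bp, short_ref = 365, long_ref = 2682,
                           tol = 50) {
  if (any(amplicon_bp <= 0)) stop("`amplicon_bp` must be > 0", call. = FALSE)
  out <- rep("other", length(amplicon_bp))
  out[abs(amplicon_bp - short_ref) <= tol] <- "Hap_C7-2"
  out[abs(amplicon_bp - long_ref) <= tol] <- "Hap_Z58"
  out
}

#' Haplotype frequency summary
#'
#' @param calls character vector of haplotype labels (>= 1).
#' @return data frame `haplotype`, `n`, `percent` (integer percent, as
#'   printed in haplotype-frequency figures); a message is emitted when
#'   rounding makes the percents not sum to 100.
#' @examples
#' haplotype_frequencies(rep(c("Hap_C7-2", "Hap_Z58"), c(221, 80)))
#' @export
haplotype_frequencies <- function(calls) {
  if (!length(calls)) stop("need >= 1 call", call. = FALSE)
  tab <- table(calls)
  out <- data.frame(haplotype = names(tab), n = as.integer(tab),
                    percent = as.integer(round(100 * as.integer(tab) /
                                                 length(calls))),
                    row.names = NULL)
  out <- out[order(-out$n), , drop = FALSE]
  rownames(out) <- NULL
  if (sum(out$percent) != 100) {
    message(sprintf("rounded percents sum to %d (rounding)", sum(out$percent)))
  }
  out
}

#' Bonferroni significance threshold
#'
#' `threshold = familywise_alpha / n_tests`. The default
#' `familywise_alpha = 1` follows the 1/m convention used for
#' expression-GWAS thresholds (e.g. 1/2,965,911 = 3.37e-7); the standard
#' 0.05/m is available by setting `familywise_alpha = 0.05`.
#'
#' @param n_tests number of tests (>= 1).
#' @param familywise_alpha familywise level (default 1.0).
#' @return p-value threshold.
#' @examples
#' signif(bonferroni_threshold(2965911), 3)  # 3.37e-7
#' @export
bonferroni_threshold <- function(n_tests, familywise_alpha = 1.0) {
  if (n_tests < 1) stop("`n_tests` must be >= 1", call. = FALSE)
  familywise_alpha / n_tests
}
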