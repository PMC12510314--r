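# Paired RNA-seq / RNC-seq differential analysis. Translation efficiency
# (TE) is RNC/RNA on the offset-normalized scale; the TE effect is the
# group x assay interaction of a negative-binomial log-linear model with a
# common trended dispersion estimated by method-of-moments.

#' Construct a paired RNA/RNC count container
#'
#' @param counts non-negative integer matrix, genes x samples, with gene
#'   ids as rownames and sample names as colnames.
#' @param sample_meta data frame with one row per column of `counts`:
#'   `sample`, `assay` (`"RNA"` or `"RNC"`), `group` (e.g. `"control"`,
#'   `"mutant"`), `replicate`. Every (assay, group) cell needs >= 2
#'   replicates and RNA/RNC samples must pair by (group, replicate).
#' @return object of class `gene_pair_counts`.
#' @export
gene_pair_counts <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), !is.null(rownames(counts)))
  need <- c("sample", "assay", "group", "replicate")
  stopifnot(is.data.frame(sample_meta), all(need %in% names(sample_meta)),
            nrow(sample_meta) == ncol(counts))
  if (!all(sample_meta$assay %in% c("RNA", "RNC"))) {
    stop("`assay` must be RNA or RNC", call. = FALSE)
  }
  cell <- interaction(sample_meta$assay, sample_meta$group, drop = TRUE)
  if (any(table(cell) < 2L)) {
    stop("every (assay, group) cell needs >= 2 replicates", call. = FALSE)
  }
  key <- function(a) {
    with(sample_meta[sample_meta$assay == a, ],
         paste(group, replicate, sep = "/"))
  }
  unpaired <- c(setdiff(key("RNA"), key("RNC")), setdiff(key("RNC"), key("RNA")))
  if (length(unpaired)) {
    stop("unpaired replicates (group/replicate): ",
         paste(unique(unpaired), collapse = ", "), call. = FALSE)
  }
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "gene_pair_counts")
}

# Median-of-ratios size factors: robust to composition bias (a block of
# strongly shifted genes must not drag the offsets of unchanged genes).
.size_factors <- function(counts) {
  lgm <- rowMeans(log(counts))
  ok <- is.finite(lgm)
  if (!any(ok)) return(colSums(counts) / mean(colSums(counts)))
  sf <- apply(counts[ok, , drop = FALSE], 2, function(cnt) {
    exp(median(log(cnt) - lgm[ok]))
  })
  sf / exp(mean(log(sf)))
}

# Method-of-moments per-gene dispersion, smoothed against mean expression
# (lowess on the log scale) to give a common trended dispersion.
.dispersion_trend <- function(counts, cell, lib) {
  y <- sweep(counts, 2, lib / mean(lib), "/")
  cells <- levels(cell)
  num <- den <- rep(0, nrow(counts))
  for (cl in cells) {
    idx <- which(cell == cl)
    m <- rowMeans(y[, idx, drop = FALSE])
    v <- apply(y[, idx, drop = FALSE], 1, var)
    num <- num + (v - m)
    den <- den + m^2
  }
  phi_raw <- pmax(num / pmax(den, 1e-8), 0)
  mu <- rowMeans(y)
  ok <- mu > 0
  lo <- lowess(log(mu[ok]), phi_raw[ok], f = 0.5)
  phi_fit <- approx(lo$x, lo$y, xout = log(pmax(mu, min(mu[ok]))),
                    rule = 2)$y
  pmax(phi_fit, 1e-3)
}

#' Paired RNA/RNC differential test
#'
#' Per gene, fits negative-binomial log-linear models with library-size
#' offsets and a common trended method-of-moments dispersion:
#' * **RNA effect**: the group coefficient in a model on the RNA samples
#'   alone, tested by likelihood ratio against the intercept model;
#' * **TE effect**: the group x assay interaction in a model on all
#'   samples (`count ~ group * assay + offset(log(lib))`), tested by
#'   likelihood ratio against the additive model.
#'
#' Genes with all-zero counts are excluded (their number is messaged).
#' p-values are BH-adjusted within the two families separately, matching
#' the two volcano-plot families (transcriptome, translation efficiency).
#'
#' @param gp a [gene_pair_counts()].
#' @param fdr FDR level used downstream by [classify_genes()]
#'   (stored as attribute; default 0.05).
#' @param ref_group reference (control) group level; default `"control"`
#'   when present, else the first sorted level.
#' @return data frame of class `te_result`: `gene_id`, `log2fc_rna`,
#'   `log2fc_te`, `p_rna`, `p_te`, `q_rna`, `q_te`.
#' @export
te_test <- function(gp, fdr = 0.05, ref_group = NULL) {
  stopifnot(inherits(gp, "gene_pair_counts"))
  counts <- gp$counts
  meta <- gp$sample_meta
  if (any(colSums(counts) <= 0)) {
    stop("library sizes must be > 0", call. = FALSE)
  }

  nz <- rowSums(counts) > 0
  if (any(!nz)) {
    message(sprintf("excluding %d all-zero gene(s)", sum(!nz)))
    counts <- counts[nz, , drop = FALSE]
  }
  lib <- .size_factors(counts) * mean(colSums(counts))
  groups <- sort(unique(meta$group))
  if (length(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  if (is.null(ref_group)) {
    ref_group <- if ("control" %in% groups) "control" else groups[1]
  }
  grp <- factor(meta$group, levels = c(ref_group, setdiff(groups, ref_group)))
  assay <- factor(meta$assay, levels = c("RNA", "RNC"))
  cell <- interaction(assay, grp, drop = TRUE)
  phi <- .dispersion_trend(counts, cell, lib)

  rna_idx <- which(assay == "RNA")
  grp_rna <- droplevels(grp[rna_idx])
  off_all <- log(lib)
  off_rna <- off_all[rna_idx]
  X_full <- model.matrix(~ grp * assay)
  X_add <- model.matrix(~ grp + assay)
  X_rna <- model.matrix(~ grp_rna)
  n_genes <- nrow(counts)
  log2fc_rna <- log2fc_te <- p_rna <- p_te <- rep(NA_real_, n_genes)

  for (g in seq_len(n_genes)) {
    y <- counts[g, ]
    fam <- MASS::negative.binomial(theta = 1 / phi[g])
    fit_full <- tryCatch(
      glm.fit(X_full, y, offset = off_all, family = fam),
      error = function(e) NULL)
    fit_add <- tryCatch(
      glm.fit(X_add, y, offset = off_all, family = fam),
      error = function(e) NULL)
    if (!is.null(fit_full) && !is.null(fit_add)) {
      lrt <- fit_add$deviance - fit_full$deviance
      p_te[g] <- pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
      log2fc_te[g] <- fit_full$coefficients[[4]] / log(2)
    }
    yr <- y[rna_idx]
    fit_r1 <- tryCatch(
      glm.fit(X_rna, yr, offset = off_rna, family = fam),
      error = function(e) NULL)
    fit_r0 <- tryCatch(
      glm.fit(matrix(1, length(yr)), yr, offset = off_rna, family = fam),
      error = function(e) NULL)
    if (!is.null(fit_r1) && !is.null(fit_r0)) {
      lrt <- fit_r0$deviance - fit_r1$deviance
      p_rna[g] <- pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
      log2fc_rna[g] <- fit_r1$coefficients[[2]] / log(2)
    }
  }
  out <- data.frame(
    gene_id = rownames(counts),
    log2fc_rna = log2fc_rna, log2fc_te = log2fc_te,
    p_rna = p_rna, p_te = p_te,
    q_rna = p.adjust(p_rna, "BH"), q_te = p.adjust(p_te, "BH"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "fdr") <- fdr
  class(out) <- c("te_result", class(out))
  out
}

#' Five-category classification of paired RNA/TE calls
#'
#' Assigns each gene one of:
#' * `Transcription` — significant in RNA only (`q_rna < fdr`, `q_te >= fdr`);
#' * `Translation` — significant in TE only;
#' * `Homodirection` — significant in both with equal fold-change signs;
#' * `Opposite` — significant in both with opposite signs;
#' * `Unchanged` — significant in neither.
#'
#' Genes with a missing q-value are labelled `Unclassifiable` and excluded
#' from the summary counts.
#'
#' @param results a [te_test()] result (or any data frame with `q_rna`,
#'   `q_te`, `log2fc_rna`, `log2fc_te`).
#' @param fdr significance level (default: the `fdr` attribute of
#'   `results`, else 0.05).
#' @return `results` with a `category` column; the per-category /
#'   per-direction count table is attached as attribute `summary` (see
#'   [category_summary()]).
#' @export
classify_genes <- function(results, fdr = NULL) {
  stopifnot(all(c("q_rna", "q_te", "log2fc_rna", "log2fc_te") %in%
                  names(results)))
  if (is.null(fdr)) fdr <- attr(results, "fdr") %||% 0.05
  sig_r <- results$q_rna < fdr
  sig_t <- results$q_te < fdr
  same <- sign(results$log2fc_rna) == sign(results$log2fc_te)
  cat <- rep("Unchanged", nrow(results))
  cat[which(sig_r & !sig_t)] <- "Transcription"
  cat[which(!sig_r & sig_t)] <- "Translation"
  cat[which(sig_r & sig_t & same)] <- "Homodirection"
  cat[which(sig_r & sig_t & !same)] <- "Opposite"
  cat[which(is.na(sig_r) | is.na(sig_t))] <- "Unclassifiable"
  results$category <- cat
  attr(results, "summary") <- category_summary(results)
  results
}

#' Category count summary
#'
#' @param results a classified [classify_genes()] result.
#' @return data frame `category`, `n`, `n_up`, `n_down` (direction from the
#'   relevant fold change: TE for `Translation`, RNA otherwise).
#' @export
category_summary <- function(results) {
  cats <- c("Transcription", "Translation", "Homodirection", "Opposite",
            "Unchanged")
  res <- results[results$category %in% cats, , drop = FALSE]
  dir_fc <- ifelse(res$category == "Translation", res$log2fc_te,
                   res$log2fc_rna)
  data.frame(
    category = cats,
    n = vapply(cats, function(cc) sum(res$category == cc), integer(1)),
    n_up = vapply(cats, function(cc)
      sum(res$category == cc & dir_fc > 0), integer(1)),
    n_down = vapply(cats, function(cc)
      sum(res$category == cc & dir_fc < 0), integer(1)),
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
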