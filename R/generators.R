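# Synthetic-data generators. Each takes one global integer seed and splits
# it into fixed-offset per-replicate substreams, so identical calls are
# byte-identical and replicates differ only by their noise draws. The
# defaults encode the study conditions each analysis stage assumes
# (12-well 2-fold ladders with 3 replicates, 89 nM target; 3 x 50-seed
# germination replicates; >= 8 bisulfite clones).

#' Generate a serial-dilution binding plate
#'
#' Noise-free fluorescence follows the ligand-depletion isotherm:
#' `fnorm = unbound_level + (bound_level - unbound_level) *
#' fraction_bound(ligand, target, true_kd)`, with i.i.d. Gaussian noise
#' added per well. Replicates share the ladder and differ only by the
#' noise draw.
#'
#' @param true_kd generating dissociation constant (µM), > 0.
#' @param bound_level,unbound_level fluorescence plateaus (a.u.); defaults
#'   900 / 800 give the ~100-unit amplitude typical of normalized
#'   fluorescence ladders.
#' @param noise_sd Gaussian noise SD (a.u.); default 1% of the amplitude.
#' @param plan a [plan_serial_dilution()] (>= 4 wells); the first reagent
#'   is the ligand.
#' @param target_conc_nM labelled-target concentration (nM), > 0.
#' @param n_reps number of replicate ladders (default 3).
#' @param seed RNG seed.
#' @return data frame with columns `well`, `ligand_conc_uM`, `fnorm`,
#'   `replicate`.
#' @export
gen_binding_plate <- function(true_kd, bound_level = 900, unbound_level = 800,
                              noise_sd = 0.01 * abs(bound_level - unbound_level),
                              plan = plan_serial_dilution(c(ligand = 30.46)),
                              target_conc_nM = 89, n_reps = 3, seed = 1) {
  stopifnot_scalar_pos(true_kd, "true_kd")
  stopifnot_scalar_pos(target_conc_nM, "target_conc_nM")
  stopifnot_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  stopifnot(inherits(plan, "dilution_plan"))
  if (plan$n_wells < 4L) stop("plan needs >= 4 wells", call. = FALSE)
  L <- plan$conc_uM[, 1L]
  mu <- unbound_level + (bound_level - unbound_level) *
    fraction_bound(L, target_conc_nM / 1000, true_kd)
  out <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    noise <- with_seed(substream_seed(seed, r),
                       rnorm(length(L), 0, noise_sd))
    data.frame(well = seq_along(L), ligand_conc_uM = unname(L),
               fnorm = unname(mu) + noise, replicate = r)
  }))
  rownames(out) <- NULL
  out
}

#' Generate paired RNA/RNC counts with planted effects
#'
#' Negative-binomial counts for a two-group (control vs mutant), two-assay
#' (RNA vs RNC) design. Per gene, the RNA mutant mean shifts by
#' `rna_log2fc` and the RNC mutant mean by `rna_log2fc + te_log2fc`, so
#' `te_log2fc` is the planted translation-efficiency effect. Genes absent
#' from `planted` are Unchanged (both fold changes 0).
#'
#' @param n_genes total number of genes.
#' @param n_reps_per_group replicates per (assay, group) cell (default 4).
#' @param planted `NULL`, or a data frame `gene` (integer index),
#'   `category`, `rna_log2fc`, `te_log2fc`; categories must be consistent
#'   with their fold changes (e.g. `Translation` needs `te_log2fc != 0`
#'   and `rna_log2fc = 0`), otherwise an error.
#' @param dispersion common NB dispersion (> 0; variance
#'   `mu + dispersion * mu^2`).
#' @param lib_sizes library sizes, recycled over the `4 *
#'   n_reps_per_group` samples (default 1e6).
#' @param mean_range log-uniform range of baseline gene means per million
#'   (default `c(20, 500)`).
#' @param seed RNG seed.
#' @return list with `gp` (a [gene_pair_counts()]) and `truth` (per-gene
#'   `gene_id`, `category`, `rna_log2fc`, `te_log2fc`).
#' @export
gen_rna_rnc_counts <- function(n_genes, n_reps_per_group = 4, planted = NULL,
                               dispersion = 0.1, lib_sizes = 1e6,
                               mean_range = c(20, 500), seed = 1) {
  stopifnot_scalar_pos(dispersion, "dispersion")
  rna_fc <- te_fc <- rep(0, n_genes)
  category <- rep("Unchanged", n_genes)
  if (!is.null(planted)) {
    stopifnot(all(c("gene", "category", "rna_log2fc", "te_log2fc") %in%
                    names(planted)))
    ok_cat <- c("Transcription", "Translation", "Homodirection", "Opposite",
                "Unchanged")
    if (!all(planted$category %in% ok_cat)) {
      stop("unknown category in `planted`", call. = FALSE)
    }
    consistent <- with(planted, ifelse(
      category == "Unchanged", rna_log2fc == 0 & te_log2fc == 0,
      ifelse(category == "Transcription", rna_log2fc != 0 & te_log2fc == 0,
      ifelse(category == "Translation", rna_log2fc == 0 & te_log2fc != 0,
      ifelse(category == "Homodirection",
             rna_log2fc != 0 & te_log2fc != 0 &
               sign(rna_log2fc) == sign(te_log2fc),
             rna_log2fc != 0 & te_log2fc != 0 &
               sign(rna_log2fc) != sign(te_log2fc))))))
    if (!all(consistent)) {
      stop("inconsistent planted table: fold changes do not match categories for gene(s) ",
           paste(head(planted$gene[!consistent], 5), collapse = ", "),
           call. = FALSE)
    }
    rna_fc[planted$gene] <- planted$rna_log2fc
    te_fc[planted$gene] <- planted$te_log2fc
    category[planted$gene] <- planted$category
  }
  n_samp <- 4L * n_reps_per_group
  lib <- rep_len(lib_sizes, n_samp)
  meta <- data.frame(
    sample = paste0(rep(c("RNA", "RNC"), each = 2L * n_reps_per_group),
                    "_", rep(rep(c("control", "mutant"),
                                 each = n_reps_per_group), 2L),
                    "_", rep(seq_len(n_reps_per_group), 4L)),
    assay = rep(c("RNA", "RNC"), each = 2L * n_reps_per_group),
    group = rep(rep(c("control", "mutant"), each = n_reps_per_group), 2L),
    replicate = rep(seq_len(n_reps_per_group), 4L)
  )
  counts <- with_seed(seed, {
    base_cpm <- exp(runif(n_genes, log(mean_range[1]), log(mean_range[2])))
    mu_mat <- vapply(seq_len(n_samp), function(j) {
      fc <- if (meta$group[j] == "mutant") {
        if (meta$assay[j] == "RNA") rna_fc else rna_fc + te_fc
      } else 0
      base_cpm * 2^fc * lib[j] / 1e6
    }, numeric(n_genes))
    matrix(rnbinom(n_genes * n_samp, mu = mu_mat, size = 1 / dispersion),
           n_genes, n_samp)
  })
  rownames(counts) <- sprintf("gene%05d", seq_len(n_genes))
  colnames(counts) <- meta$sample
  list(gp = gene_pair_counts(counts, meta),
       truth = data.frame(gene_id = rownames(counts), category = category,
                          rna_log2fc = rna_fc, te_log2fc = te_fc))
}

#' Generate bisulfite-converted clone sequences
#'
#' Each clone copies the reference with every cytosine independently kept
#' as `C` with probability `p + (1 - p) * conversion_failure` (where `p`
#' is the per-context methylation probability — incomplete conversion
#' biases methylation upward) and converted to `T` otherwise; non-C bases
#' are copied verbatim. Cytosines with indeterminate context (trailing,
#' <2 downstream bases) have `p = 0`.
#'
#' @param ref_seq uppercase ACGT reference amplicon.
#' @param p_meth named probabilities `c(CG = , CHG = , CHH = )`.
#' @param n_clones number of clones (default 8).
#' @param conversion_failure probability an unmethylated C escapes
#'   conversion (default 0).
#' @param seed RNG seed.
#' @return a [bisulfite_locus()].
#' @export
gen_bisulfite_clones <- function(ref_seq, p_meth, n_clones = 8,
                                 conversion_failure = 0, seed = 1) {
  stopifnot(all(c("CG", "CHG", "CHH") %in% names(p_meth)),
            all(p_meth >= 0 & p_meth <= 1),
            conversion_failure >= 0, conversion_failure <= 1)
  ctx <- call_contexts(ref_seq)   # errors on non-ACGT input
  bases <- strsplit(ref_seq, "")[[1]]
  p_keep <- numeric(nrow(ctx))
  det <- ctx$context != "indeterminate"
  p_site <- ifelse(det, p_meth[ctx$context], 0)
  p_keep <- p_site + (1 - p_site) * conversion_failure
  clones <- vapply(seq_len(n_clones), function(r) {
    keep <- with_seed(substream_seed(seed, r),
                      runif(nrow(ctx)) < p_keep)
    cl <- bases
    cl[ctx$pos[!keep]] <- "T"
    paste(cl, collapse = "")
  }, character(1))
  bisulfite_locus(ref_seq, clones, region_id = "synthetic")
}

#' Generate germination time-courses
#'
#' Seeds germinate at latent times drawn from a logistic law: a seed
#' eventually germinates with probability `max_pct / 100`, and its
#' germination time has CDF `1 / (1 + exp(-slope * (t - t50)))`. Counting
#' seeds with time `<= t` makes cumulative counts monotone by
#' construction and binomial around the logistic curve at every timepoint.
#'
#' @param genotypes character vector of genotype labels.
#' @param timepoints strictly increasing assay times (hours).
#' @param n_reps replicates per genotype (default 3).
#' @param seeds_per_rep seeds per replicate (default 50).
#' @param logistic_params named list `genotype -> c(t50, slope, max_pct)`
#'   (`t50` hours, `slope` per hour, `max_pct` in [0, 100]).
#' @param treatment treatment label stored in the output (default `"AA"`).
#' @param seed RNG seed.
#' @return data frame `genotype`, `treatment`, `replicate`, `time_h`,
#'   `n_germinated` (cumulative), `n_total`.
#' @export
gen_germination <- function(genotypes, timepoints, n_reps = 3,
                            seeds_per_rep = 50, logistic_params,
                            treatment = "AA", seed = 1) {
  if (length(timepoints) > 1 && any(diff(timepoints) <= 0)) {
    stop("`timepoints` must be strictly increasing", call. = FALSE)
  }
  stopifnot_scalar_pos(seeds_per_rep, "seeds_per_rep")
  stopifnot(all(genotypes %in% names(logistic_params)))
  out <- list()
  for (gi in seq_along(genotypes)) {
    gp <- logistic_params[[genotypes[gi]]]
    t50 <- gp[[1]]; slope <- gp[[2]]; max_pct <- gp[[3]]
    if (max_pct < 0 || max_pct > 100) {
      stop("`max_pct` must be in [0, 100]", call. = FALSE)
    }
    for (r in seq_len(n_reps)) {
      times <- with_seed(substream_seed(seed, (gi - 1L) * n_reps + r), {
        germinates <- runif(seeds_per_rep) < max_pct / 100
        u <- runif(seeds_per_rep)
        # logistic quantile; infinite slope collapses to a step at t50
        tg <- if (is.finite(slope)) t50 + log(u / (1 - u)) / slope
              else rep(t50, seeds_per_rep)
        ifelse(germinates, tg, Inf)
      })
      cnt <- vapply(timepoints, function(t0) sum(times <= t0), integer(1))
      out[[length(out) + 1L]] <- data.frame(
        genotype = genotypes[gi], treatment = treatment, replicate = r,
        time_h = timepoints, n_germinated = cnt, n_total = seeds_per_rep)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
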