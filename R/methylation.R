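# Locus-specific methylation: McrBC-qPCR relative scores (delta-delta-Ct)
# and bisulfite clone-sequencing CG/CHG/CHH context calling. Clones are
# assumed gap-free, pre-aligned, and reading the converted top strand
# (reverse-complement the reference first for bottom-strand amplicons).

#' Cytosine context labels for a reference sequence
#'
#' Classifies every cytosine of the (top-strand) reference by its two
#' downstream bases: `CG` when followed by G; `CHG` for C-H-G and `CHH`
#' for C-H-H with H in {A, C, T}. Cytosines lacking 1–2 downstream bases,
#' or followed by a non-ACGT base, are labelled `indeterminate` and
#' excluded from summaries.
#'
#' @param ref_seq uppercase ACGT string.
#' @return data frame `pos`, `context` with one row per cytosine.
#' @examples
#' call_contexts("CCGG")  # CHG then CG
#' @export
call_contexts <- function(ref_seq) {
  stopifnot(is.character(ref_seq), length(ref_seq) == 1L)
  bases <- strsplit(ref_seq, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("`ref_seq` must contain only uppercase ACGT", call. = FALSE)
  }
  cpos <- which(bases == "C")
  if (!length(cpos)) {
    return(data.frame(pos = integer(0), context = character(0)))
  }
  n <- length(bases)
  ctx <- vapply(cpos, function(i) {
    if (i + 1L > n) return("indeterminate")
    b1 <- bases[i + 1L]
    if (b1 == "G") return("CG")
    if (i + 2L > n) return("indeterminate")
    b2 <- bases[i + 2L]
    if (b2 == "G") "CHG" else "CHH"
  }, character(1))
  data.frame(pos = cpos, context = ctx)
}

#' Construct a bisulfite locus
#'
#' @param ref_seq unconverted reference amplicon (uppercase ACGT).
#' @param clones character vector of >= 1 bisulfite-converted clone
#'   sequences, each the same length as `ref_seq`.
#' @param region_id label for the amplicon (default `"locus"`).
#' @param strand `"top"` (default) or `"bottom"`; bottom-strand amplicons
#'   are handled by reverse-complementing the reference (and clones) before
#'   calling.
#' @return object of class `bisulfite_locus`.
#' @export
bisulfite_locus <- function(ref_seq, clones, region_id = "locus",
                            strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  stopifnot(is.character(ref_seq), length(ref_seq) == 1L,
            is.character(clones), length(clones) >= 1L)
  if (any(nchar(clones) != nchar(ref_seq))) {
    stop("all clones must have the same length as the reference", call. = FALSE)
  }
  if (strand == "bottom") {
    ref_seq <- .revcomp(ref_seq)
    clones <- vapply(clones, .revcomp, character(1), USE.NAMES = FALSE)
  }
  structure(list(region_id = region_id, ref_seq = ref_seq, clones = clones,
                 strand = strand),
            class = "bisulfite_locus")
}

.revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

#' Per-context methylation summary of a bisulfite locus
#'
#' At every reference cytosine with a determinate context, a clone base of
#' `C` is a methylated call and `T` an unmethylated call (bisulfite
#' converts unmethylated C to T). Any other clone base at a cytosine
#' position is flagged and excluded. Calls are aggregated per context into
#' percentages.
#'
#' @param locus a [bisulfite_locus()].
#' @return data frame of class `methylation_summary` with one row per
#'   context (`CG`, `CHG`, `CHH`): `n_sites`, `n_calls`, `n_methylated`,
#'   `percent`; the number of flagged (non-C/T) calls is attribute
#'   `n_flagged`.
#' @export
bisulfite_summary <- function(locus) {
  stopifnot(inherits(locus, "bisulfite_locus"))
  ctx <- call_contexts(locus$ref_seq)
  ctx <- ctx[ctx$context != "indeterminate", , drop = FALSE]
  contexts <- c("CG", "CHG", "CHH")
  out <- data.frame(context = contexts, n_sites = 0L, n_calls = 0L,
                    n_methylated = 0L, percent = NA_real_)
  n_flagged <- 0L
  clone_mat <- do.call(rbind, strsplit(locus$clones, ""))
  for (k in seq_along(contexts)) {
    pos <- ctx$pos[ctx$context == contexts[k]]
    out$n_sites[k] <- length(pos)
    if (!length(pos)) next
    calls <- clone_mat[, pos, drop = FALSE]
    meth <- calls == "C"
    unmeth <- calls == "T"
    bad <- !(meth | unmeth)
    n_flagged <- n_flagged + sum(bad)
    out$n_calls[k] <- sum(!bad)
    out$n_methylated[k] <- sum(meth)
    out$percent[k] <- if (out$n_calls[k] > 0)
      100 * out$n_methylated[k] / out$n_calls[k] else NA_real_
  }
  if (n_flagged > 0) {
    warning(sprintf("%d clone call(s) other than C/T at cytosine positions excluded",
                    n_flagged))
  }
  attr(out, "n_flagged") <- n_flagged
  class(out) <- c("methylation_summary", class(out))
  out
}

#' McrBC-qPCR relative methylation score
#'
#' McrBC cuts methylated DNA, so qPCR after digestion loses template in
#' proportion to methylation. The remaining fraction is `2^(-ddCt)` with
#' `ddCt = (Ct_dig - Ct_undig)_region - (Ct_dig - Ct_undig)_reference`,
#' the reference delta-Ct being the mean over the reference genes; the
#' methylation score is `1 - remaining`, clamped to `[0, 1]`. The SE is
#' propagated from the replicate spread of the four delta-Ct cells.
#'
#' @param ct data frame with columns `region`, `genotype`, `digested`
#'   (logical), `replicate`, `ct`; reference genes are the rows whose
#'   `region` is in `reference_regions`.
#' @param region target region label (e.g. `"R1"`).
#' @param genotype genotype/haplotype label.
#' @param reference_regions labels of the reference genes
#'   (default `c("UBQ2", "ACT1")`).
#' @return list `score`, `se`, `remaining`, `ddct`.
#' @export
mcrbc_relative_methylation <- function(ct, region, genotype,
                                       reference_regions = c("UBQ2", "ACT1")) {
  need <- c("region", "genotype", "digested", "replicate", "ct")
  stopifnot(is.data.frame(ct), all(need %in% names(ct)))
  ct <- ct[ct$genotype == genotype, , drop = FALSE]
  grab <- function(reg, dig) {
    x <- ct$ct[ct$region == reg & ct$digested == dig]
    if (!length(x)) {
      stop(sprintf("missing %s Ct values for region %s",
                   if (dig) "digested" else "undigested control", reg),
           call. = FALSE)
    }
    x
  }
  dct <- function(reg) {
    d <- grab(reg, TRUE); u <- grab(reg, FALSE)
    list(mean = mean(d) - mean(u),
         var = var(d) / length(d) + var(u) / length(u))
  }
  reg <- dct(region)
  refs <- lapply(reference_regions, dct)
  ref_mean <- mean(vapply(refs, `[[`, numeric(1), "mean"))
  ref_var <- sum(vapply(refs, `[[`, numeric(1), "var")) / length(refs)^2
  ddct <- reg$mean - ref_mean
  remaining <- 2^(-ddct)
  score <- 1 - remaining
  if (score < 0) {
    message(sprintf("score %.3f < 0 before clamping (unmethylated with noise)",
                    score))
  }
  # delta-method: var(score) = (ln 2 * remaining)^2 * var(ddct)
  se <- abs(log(2) * remaining) * sqrt(reg$var + ref_var)
  list(score = min(max(score, 0), 1), se = se, remaining = remaining,
       ddct = ddct)
}
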