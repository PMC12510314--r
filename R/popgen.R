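# Windowed FST / nucleotide-diversity selection scan between two
# populations (wild vs domesticated) on haploid biallelic calls.

#' Construct a haplotype matrix
#'
#' Container for phased/haploid biallelic genotypes: a haplotypes x sites
#' matrix of 0/1/NA calls with physical positions and a two-group
#' population label per haplotype.
#'
#' @param alleles integer/numeric matrix, haplotypes x sites, entries 0, 1
#'   or `NA` (missing). Zero columns are allowed.
#' @param positions strictly increasing 1-based physical positions, one per
#'   site.
#' @param pop_labels character vector, one label per haplotype; exactly two
#'   distinct labels (e.g. `"teosinte"`, `"maize"`) unless `n_pops = 1`.
#' @param contig contig name.
#' @param region_start,region_end 1-based bounds of the surveyed region
#'   (default 1 to `max(positions)`); windows are anchored at
#'   `region_start`.
#' @return object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(alleles, positions, pop_labels, contig = "chr",
                             region_start = 1L,
                             region_end = NULL) {
  alleles <- as.matrix(alleles)
  if (ncol(alleles) != length(positions)) {
    stop("ncol(alleles) must equal length(positions)", call. = FALSE)
  }
  if (nrow(alleles) != length(pop_labels)) {
    stop("nrow(alleles) must equal length(pop_labels)", call. = FALSE)
  }
  if (length(positions) > 1 && any(diff(positions) <= 0)) {
    stop("`positions` must be strictly increasing", call. = FALSE)
  }
  vals <- alleles[!is.na(alleles)]
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop("`alleles` entries must be 0, 1 or NA", call. = FALSE)
  }
  if (is.null(region_end)) {
    region_end <- if (length(positions)) max(positions) else region_start
  }
  structure(
    list(alleles = alleles, positions = unname(as.numeric(positions)),
         pop_labels = unname(as.character(pop_labels)),
         contig = unname(as.character(contig))[1],
         region_start = as.numeric(region_start),
         region_end = as.numeric(region_end)),
    class = "haplotype_matrix"
  )
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes x %d sites on %s [%g, %g]\n",
              nrow(x$alleles), ncol(x$alleles), x$contig, x$region_start,
              x$region_end))
  print(table(x$pop_labels))
  invisible(x)
}

#' Weir–Cockerham variance components for one biallelic haploid site
#'
#' Haploid specialization of the Weir & Cockerham (1984) moment estimator:
#' with per-population alternate-allele frequencies `p_i`, sample sizes
#' `n_i` and `r = 2` populations,
#' `MSP = sum n_i (p_i - pbar)^2 / (r - 1)`,
#' `MSG = sum n_i p_i (1 - p_i) / sum (n_i - 1)`,
#' `n_c = (sum n_i - sum n_i^2 / sum n_i) / (r - 1)`; the between-population
#' component is `a = (MSP - MSG) / n_c` and the site FST is
#' `a / (a + MSG)`. Windowed FST is the ratio of sums of the two
#' components. A site monomorphic in both populations returns `(0, 0)`.
#'
#' @param n1,n2 length-2 allele counts `(ref, alt)` in each population;
#'   each population needs >= 2 non-missing alleles.
#' @return named numeric `c(a = ..., d = ...)` with `d` the denominator
#'   component `a + b` (between + within).
#' @examples
#' comp <- site_fst(c(6, 4), c(9, 1))
#' comp[["a"]] / comp[["d"]]
#' @export
site_fst <- function(n1, n2) {
  stopifnot(length(n1) == 2L, length(n2) == 2L)
  s1 <- sum(n1); s2 <- sum(n2)
  if (s1 < 2 || s2 < 2) stop("each population needs >= 2 alleles", call. = FALSE)
  comp <- .wc_components(n1[2], s1, n2[2], s2)
  c(a = comp$a, d = comp$d)
}

# Vectorized Weir-Cockerham haploid components over sites.
# ac*: alternate allele counts; an*: total non-missing alleles.
.wc_components <- function(ac1, an1, ac2, an2) {
  p1 <- ac1 / an1
  p2 <- ac2 / an2
  nsum <- an1 + an2
  nc <- nsum - (an1^2 + an2^2) / nsum        # r - 1 = 1
  pbar <- (ac1 + ac2) / nsum
  msp <- an1 * (p1 - pbar)^2 + an2 * (p2 - pbar)^2
  msg <- (an1 * p1 * (1 - p1) + an2 * p2 * (1 - p2)) / (an1 + an2 - 2)
  a <- (msp - msg) / nc
  d <- a + msg
  mono <- (ac1 + ac2 == 0) | (ac1 + ac2 == nsum)
  a[mono] <- 0
  d[mono] <- 0
  list(a = a, d = d)
}

# Hudson (1992) estimator components, for sensitivity checks.
.hudson_components <- function(ac1, an1, ac2, an2) {
  p1 <- ac1 / an1
  p2 <- ac2 / an2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (an1 - 1) - p2 * (1 - p2) / (an2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mono <- (ac1 + ac2 == 0) | (ac1 + ac2 == an1 + an2)
  num[mono] <- 0
  den[mono] <- 0
  list(a = num, d = den)
}

#' Per-site nucleotide diversity of a haplotype set
#'
#' `theta_pi = sum_sites 2 p q n / (n - 1) / span`, with `n` the per-site
#' count of non-missing alleles (pairwise complete) and `span` the surveyed
#' length in bp. Equals the mean pairwise difference per bp.
#'
#' @param alleles 0/1/NA matrix (haplotypes x sites) for one population,
#'   >= 2 haplotypes.
#' @param span_bp surveyed span in bp.
#' @return per-site diversity (numeric scalar, >= 0).
#' @export
nucleotide_diversity <- function(alleles, span_bp) {
  alleles <- as.matrix(alleles)
  stopifnot(nrow(alleles) >= 2L)
  stopifnot_scalar_pos(span_bp, "span_bp")
  if (ncol(alleles) == 0L) return(0)
  n <- colSums(!is.na(alleles))
  ac <- colSums(alleles, na.rm = TRUE)
  ok <- n >= 2
  if (!any(ok)) {
    warning("all sites missing; diversity reported as 0")
    return(0)
  }
  p <- ac[ok] / n[ok]
  sum(2 * p * (1 - p) * n[ok] / (n[ok] - 1)) / span_bp
}

#' Sliding-window FST and diversity scan
#'
#' Tiles the surveyed region with windows of `window_bp` advanced by
#' `step_bp` (anchored at `region_start`; windows are `[start, start +
#' window_bp)` half-open internally, reported with inclusive `start` and
#' exclusive `end`). Per window: the ratio-of-sums Weir–Cockerham FST over
#' the segregating sites it contains, per-population nucleotide diversity,
#' and their ratio `pi_pop1 / pi_pop2`. Windows with fewer than `min_sites`
#' segregating sites carry `NA` statistics but keep their coordinates.
#'
#' @param hm a [haplotype_matrix()] with two population labels.
#' @param window_bp window length in bp (default 3000).
#' @param step_bp step in bp (default 100); must be <= `window_bp`.
#' @param min_sites minimum segregating sites for defined statistics
#'   (default 3).
#' @param estimator `"wc"` (Weir–Cockerham, default) or `"hudson"`.
#' @param pop1 label treated as population 1 (default: first label sorted
#'   as in `sort(unique(pop_labels))`).
#' @return data frame with columns `contig`, `start`, `end`, `n_sites`,
#'   `fst`, `pi_pop1`, `pi_pop2`, `pi_ratio`.
#' @export
window_scan <- function(hm, window_bp = 3000, step_bp = 100, min_sites = 3,
                        estimator = c("wc", "hudson"), pop1 = NULL) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  estimator <- match.arg(estimator)
  if (step_bp > window_bp) stop("`step_bp` must be <= `window_bp`", call. = FALSE)
  labs <- sort(unique(hm$pop_labels))
  if (length(labs) != 2L) stop("exactly two population labels required", call. = FALSE)
  if (is.null(pop1)) pop1 <- labs[1]
  pop2 <- setdiff(labs, pop1)
  i1 <- hm$pop_labels == pop1
  i2 <- hm$pop_labels == pop2

  span_total <- hm$region_end - hm$region_start + 1
  truncated <- span_total < window_bp
  if (truncated) {
    warning("region shorter than one window; returning a single truncated window")
    starts <- hm$region_start
    wlen <- span_total
  } else {
    starts <- seq(hm$region_start, hm$region_end - window_bp + 1, by = step_bp)
    wlen <- window_bp
  }

  st <- .site_stats(hm$alleles, i1, i2, estimator)
  pos <- hm$positions

  out <- data.frame(
    contig = hm$contig, start = starts, end = starts + wlen,
    n_sites = NA_integer_, fst = NA_real_, pi_pop1 = NA_real_,
    pi_pop2 = NA_real_, pi_ratio = NA_real_
  )
  for (w in seq_along(starts)) {
    inw <- which(pos >= starts[w] & pos < starts[w] + wlen)
    use <- inw[st$usable[inw]]
    seg <- use[st$segregating[use]]
    out$n_sites[w] <- length(seg)
    out$pi_pop1[w] <- sum(st$pi1[use]) / wlen
    out$pi_pop2[w] <- sum(st$pi2[use]) / wlen
    if (length(seg) >= min_sites) {
      dsum <- sum(st$d[seg])
      if (dsum > 0) out$fst[w] <- sum(st$a[seg]) / dsum
      if (out$pi_pop2[w] > 0) out$pi_ratio[w] <- out$pi_pop1[w] / out$pi_pop2[w]
    } else {
      out$pi_ratio[w] <- NA_real_
    }
  }
  out
}

# Per-site statistics shared by the scan and the permutation null.
.site_stats <- function(alleles, i1, i2, estimator = "wc") {
  m1 <- alleles[i1, , drop = FALSE]
  m2 <- alleles[i2, , drop = FALSE]
  an1 <- colSums(!is.na(m1)); ac1 <- colSums(m1, na.rm = TRUE)
  an2 <- colSums(!is.na(m2)); ac2 <- colSums(m2, na.rm = TRUE)
  usable <- an1 >= 2 & an2 >= 2
  a <- d <- pi1 <- pi2 <- numeric(length(an1))
  if (any(usable)) {
    comp <- if (estimator == "hudson") {
      .hudson_components(ac1[usable], an1[usable], ac2[usable], an2[usable])
    } else {
      .wc_components(ac1[usable], an1[usable], ac2[usable], an2[usable])
    }
    a[usable] <- comp$a
    d[usable] <- comp$d
    p1 <- ac1[usable] / an1[usable]
    p2 <- ac2[usable] / an2[usable]
    pi1[usable] <- 2 * p1 * (1 - p1) * an1[usable] / (an1[usable] - 1)
    pi2[usable] <- 2 * p2 * (1 - p2) * an2[usable] / (an2[usable] - 1)
  }
  segregating <- usable & (ac1 + ac2 > 0) & (ac1 + ac2 < an1 + an2)
  list(a = a, d = d, pi1 = pi1, pi2 = pi2, usable = usable,
       segregating = segregating)
}
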