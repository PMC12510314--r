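#' Plan a serial-dilution binding plate
#'
#' Computes the final per-well concentration of every co-reagent in a
#' fold-wise serial dilution followed by a constant-volume target addition.
#' With the default equal-volume addition (`mix_fraction = 0.5`, e.g. 10 µL
#' of diluted reaction plus 10 µL of labelled target), well `k` holds
#' `stock * mix_fraction / fold^(k-1)`.
#'
#' @param stocks named numeric vector of reaction stock concentrations in µM
#'   (e.g. `c(ligand = 30.46, enzyme = 4.66, cofactor = 270)`).
#' @param n_wells number of wells in the ladder (default 12).
#' @param fold dilution factor between consecutive wells (default 2; must be
#'   > 1).
#' @param mix_fraction fraction of the final well volume contributed by the
#'   dilution series after target addition (default 0.5).
#' @return an object of class `dilution_plan`: a list with `conc_uM` (matrix
#'   of final concentrations, wells x reagents), `n_wells`, `fold`,
#'   `mix_fraction`, and `stock_conc`.
#' @examples
#' plan <- plan_serial_dilution(c(AtPABP2 = 30.46, AdoMet = 270))
#' signif(plan$conc_uM[1, "AtPABP2"], 3)       # 15.2 uM in well 1
#' signif(plan$conc_uM[12, "AdoMet"] * 1000, 3) # 65.9 nM in well 12
#' @export
plan_serial_dilution <- function(stocks, n_wells = 12L, fold = 2,
                                 mix_fraction = 0.5) {
  if (!is.numeric(stocks) || length(stocks) < 1L || any(!is.finite(stocks)) ||
      any(stocks <= 0)) {
    stop("`stocks` must be positive finite concentrations (uM)", call. = FALSE)
  }
  if (!is.numeric(n_wells) || length(n_wells) != 1L || n_wells < 2L) {
    stop("`n_wells` must be >= 2", call. = FALSE)
  }
  stopifnot_scalar_pos(fold, "fold")
  if (fold <= 1) stop("`fold` must be > 1", call. = FALSE)
  if (mix_fraction <= 0 || mix_fraction > 1) {
    stop("`mix_fraction` must be in (0, 1]", call. = FALSE)
  }
  n_wells <- as.integer(n_wells)
  if (is.null(names(stocks))) {
    names(stocks) <- paste0("reagent", seq_along(stocks))
  }
  conc <- outer(mix_fraction / fold^(seq_len(n_wells) - 1), stocks)
  dimnames(conc) <- list(well = seq_len(n_wells), reagent = names(stocks))
  structure(
    list(conc_uM = conc, n_wells = n_wells, fold = fold,
         mix_fraction = mix_fraction, stock_conc = stocks),
    class = "dilution_plan"
  )
}

#' @export
print.dilution_plan <- function(x, ...) {
  cat(sprintf("Serial-dilution plan: %d wells, %g-fold, mix fraction %g\n",
              x$n_wells, x$fold, x$mix_fraction))
  print(signif(x$conc_uM, 3))
  invisible(x)
}

#' Final well concentration for one reagent
#'
#' @param plan a [plan_serial_dilution()] result.
#' @param reagent reagent name or column index.
#' @param well well number (1-based).
#' @param unit `"uM"` or `"nM"`.
#' @return concentration in the requested unit (numeric scalar).
#' @export
well_concentration <- function(plan, reagent = 1L, well = 1L, unit = c("uM", "nM")) {
  stopifnot(inherits(plan, "dilution_plan"))
  unit <- match.arg(unit)
  x <- plan$conc_uM[well, reagent]
  if (unit == "nM") x <- x * 1000
  unname(x)
}
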