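#' Multiplicity of infection from a dilution of a titered stock
#'
#' Computes the MOI (plaque-forming units applied per cell) obtained when a
#' viral stock of known titer is diluted and a fixed inoculum volume is
#' applied to a well containing a known number of cells:
#' \deqn{MOI = \frac{titer / dilution \times volume}{cells}}
#'
#' With the default-style inputs of a 3e6 PFU/ml stock diluted 1:10, a
#' 0.05 ml inoculum and 3e4 cells per well, the MOI is 0.5.
#'
#' @param stock_titer Stock titer in PFU per ml. Must be positive.
#' @param dilution_factor Dimensionless dilution (10 means 1:10). Must be
#'   positive; values below 1 would concentrate the stock and are refused.
#' @param inoculum_volume Volume applied per well, in ml. Must be positive.
#' @param cells_per_well Number of cells in the well. Must be positive.
#' @return MOI in PFU per cell (double scalar).
#' @seealso [infection_probability()] for the dose-response this feeds.
#' @examples
#' moi_from_dilution(3e6, 10, 0.05, 3e4) # 0.5
#' @export
moi_from_dilution <- function(stock_titer, dilution_factor, inoculum_volume,
                              cells_per_well) {
  for (p in c("stock_titer", "dilution_factor", "inoculum_volume",
              "cells_per_well")) {
    v <- get(p)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_domain(p, "must be a single positive finite number")
    }
  }
  if (dilution_factor < 1) {
    stop_domain("dilution_factor", "must be >= 1 (a dilution, not a concentration)")
  }
  (stock_titer / dilution_factor) * inoculum_volume / cells_per_well
}

#' Single-hit Poisson infection probability
#'
#' Under the single-hit model, infectious particles land on cells as a
#' Poisson process with rate equal to the MOI, so the probability that a
#' cell receives at least one particle is \eqn{p = 1 - e^{-MOI}}. The curve
#' is 0 at MOI 0, strictly increasing, and saturates at 1 - the monotone
#' dose dependence seen when a virus stock is titrated over a dilution
#' series.
#'
#' @param moi Multiplicity of infection (PFU per cell), non-negative.
#'   Vectorized.
#' @return Infection probability in \[0, 1\].
#' @examples
#' infection_probability(0.5) # 1 - exp(-0.5) ~ 0.3935
#' @export
infection_probability <- function(moi) {
  if (!is.numeric(moi) || any(!is.finite(moi)) || any(moi < 0)) {
    stop_domain("moi", "must be finite and >= 0")
  }
  -expm1(-moi)
}

#' Dose model for a dilution series
#'
#' Convenience constructor bundling the stock/dilution arithmetic with the
#' single-hit infection probability, so a dilution series maps directly to
#' expected infection fractions.
#'
#' @inheritParams moi_from_dilution
#' @return A list of class `dose_model` with elements `stock_titer`,
#'   `dilution_factor`, `inoculum_volume`, `cells_per_well`, `moi` and
#'   `infect_prob`.
#' @examples
#' dose_model(3e6, 25, 0.05, 3e4)$moi # 0.2
#' @export
dose_model <- function(stock_titer = 3e6, dilution_factor = 10,
                       inoculum_volume = 0.05, cells_per_well = 3e4) {
  moi <- moi_from_dilution(stock_titer, dilution_factor, inoculum_volume,
                           cells_per_well)
  structure(list(
    stock_titer = stock_titer,
    dilution_factor = dilution_factor,
    inoculum_volume = inoculum_volume,
    cells_per_well = cells_per_well,
    moi = moi,
    infect_prob = infection_probability(moi)
  ), class = "dose_model")
}

#' @export
print.dose_model <- function(x, ...) {
  cat(sprintf(
    "<dose_model> titer %.3g PFU/ml, 1:%g dilution, %.3g ml onto %.3g cells\n  MOI = %.4g PFU/cell, infection probability = %.4g\n",
    x$stock_titer, x$dilution_factor, x$inoculum_volume, x$cells_per_well,
    x$moi, x$infect_prob))
  invisible(x)
}
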