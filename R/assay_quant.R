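#' A qPCR measurement (target and reference Ct)
#'
#' One sample's threshold cycles for the target transcript and the
#' internal reference gene (e.g. Gapdh). Technical replicates are
#' averaged on the Ct scale before any fold computation.
#'
#' @param sample_id Sample label.
#' @param ct_target Threshold cycle(s) of the target; replicates allowed.
#' @param ct_reference Threshold cycle(s) of the reference gene.
#' @param condition Optional condition label.
#' @param calibrator Logical; is this the calibrator sample (e.g. the
#'   irrelevant-shRNA control set to relative expression 1)?
#' @param ct_range Valid Ct range; values outside error out (default
#'   5-40 cycles).
#' @return A list of class `qpcr_measure` with replicate-averaged
#'   `ct_target`, `ct_reference`.
#' @export
qpcr_measure <- function(sample_id, ct_target, ct_reference,
                         condition = NA_character_, calibrator = FALSE,
                         ct_range = c(5, 40)) {
  for (p in c("ct_target", "ct_reference")) {
    v <- get(p)
    if (length(v) == 0 || any(!is.finite(v)))
      stop_domain(p, "must be present and finite")
    if (any(v < ct_range[1] | v > ct_range[2]))
      stop_domain(p, sprintf("outside the valid Ct range [%g, %g]",
                             ct_range[1], ct_range[2]))
  }
  structure(list(sample_id = sample_id,
                 ct_target = mean(ct_target),
                 ct_reference = mean(ct_reference),
                 condition = condition, calibrator = calibrator),
            class = "qpcr_measure")
}

#' Relative expression by the 2^-ddCt method
#'
#' Normalizes the target Ct to the reference gene within each sample
#' (\eqn{\Delta Ct = Ct_{target} - Ct_{ref}}), then to the calibrator
#' sample (\eqn{\Delta\Delta Ct = \Delta Ct_{sample} - \Delta
#' Ct_{calibrator}}), and reports \eqn{2^{-\Delta\Delta Ct}}. The
#' calibrator's own relative expression is exactly 1. Amplification
#' efficiency is taken as perfect doubling per cycle. Adding a constant
#' to both Ct values of a sample (a plate shift) cancels exactly.
#'
#' @param sample,calibrator [qpcr_measure()] objects.
#' @return List of class `expression_result`: `relative_expression`
#'   (> 0; calibrator maps to 1) and `knockdown_fraction`
#'   (1 - relative_expression; 0.6 means 60% reduction in mRNA).
#' @examples
#' s <- qpcr_measure("kd", 25, 20)
#' c <- qpcr_measure("ctrl", 24, 20, calibrator = TRUE)
#' relative_expression(s, c)$relative_expression # 0.5
#' @export
relative_expression <- function(sample, calibrator) {
  stopifnot(inherits(sample, "qpcr_measure"),
            inherits(calibrator, "qpcr_measure"))
  ddct <- (sample$ct_target - sample$ct_reference) -
    (calibrator$ct_target - calibrator$ct_reference)
  rel <- 2^(-ddct)
  structure(list(relative_expression = rel, knockdown_fraction = 1 - rel,
                 ddct = ddct),
            class = "expression_result")
}

#' Rank correlation between knockdown depth and infection phenotype
#'
#' Tests the gene-dosage expectation that hairpins achieving deeper
#' knockdown of an antiviral gene produce proportionally higher infection
#' efficiency. Spearman's rank correlation is used because the claim is
#' about ordering, not linearity, and is invariant under any strictly
#' monotone transform of either axis.
#'
#' @param knockdown Numeric vector of knockdown fractions.
#' @param efficiency Numeric vector of matching infection efficiencies.
#' @param cutoff Coefficient at or above which the relationship is
#'   flagged monotone (default 0.8).
#' @return List: `rho` (Spearman coefficient), `monotone` (logical),
#'   `n`.
#' @export
knockdown_phenotype_correlation <- function(knockdown, efficiency,
                                            cutoff = 0.8) {
  if (length(knockdown) != length(efficiency))
    stop("knockdown and efficiency lengths differ", call. = FALSE)
  if (length(knockdown) < 3)
    stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(knockdown) == 0 || stats::sd(efficiency) == 0)
    stop("correlation undefined: an input is constant", call. = FALSE)
  rho <- stats::cor(knockdown, efficiency, method = "spearman")
  list(rho = rho, monotone = rho >= cutoff, n = length(knockdown))
}

#' Viability-normalized reporter activity
#'
#' Luciferase reporter readouts are confounded by differences in cell
#' number, so luminescence is first divided by a viability readout
#' (resazurin-type absorbance), then expressed as fold over the untreated
#' reference pair (which maps exactly to 1):
#' \deqn{activity = \frac{lum / via}{lum_{ref} / via_{ref}}}
#'
#' @param luminescence Sample luminescence (arbitrary units).
#' @param viability Sample viability absorbance; must be > 0.
#' @param reference_luminescence,reference_viability The untreated
#'   reference pair; reference viability must be > 0.
#' @return Normalized fold activity (dimensionless).
#' @export
reporter_activity <- function(luminescence, viability,
                              reference_luminescence, reference_viability) {
  if (any(viability <= 0)) stop_domain("viability", "must be > 0")
  if (any(reference_viability <= 0))
    stop_domain("reference_viability", "must be > 0")
  (luminescence / viability) /
    (reference_luminescence / reference_viability)
}
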