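#' Hit-calling parameters
#'
#' Thresholds for the screen's statistics. The defaults encode the
#' standard arrayed-screen rules: an shRNA is a hit at Z >= 3 (inclusive),
#' a gene is a positive regulator when 2 or more of its distinct hairpins
#' are hits, and a well is flagged cytotoxic when its cell count falls
#' strictly below half the median cell count of its plate's
#' negative-control wells.
#'
#' @param z_threshold Z-score hit threshold (inclusive). Must be > 0.
#' @param min_hits Minimum distinct scoring hairpins per positive gene.
#' @param sd_estimator `"sample"` (n-1 denominator, the default) or
#'   `"population"` (n) for the null standard deviation.
#' @param cytotoxicity_fraction Fraction of the plate negative-control
#'   median cell count below which (strictly) a well is cytotoxic.
#' @return A list of class `hit_params`.
#' @export
hit_params <- function(z_threshold = 3, min_hits = 2L,
                       sd_estimator = c("sample", "population"),
                       cytotoxicity_fraction = 0.5) {
  sd_estimator <- match.arg(sd_estimator)
  if (z_threshold <= 0) stop_domain("z_threshold", "must be > 0")
  if (min_hits < 1) stop_domain("min_hits", "must be >= 1")
  structure(list(z_threshold = z_threshold, min_hits = as.integer(min_hits),
                 sd_estimator = sd_estimator,
                 cytotoxicity_fraction = cytotoxicity_fraction),
            class = "hit_params")
}

null_sd <- function(x, estimator) {
  if (estimator == "sample") stats::sd(x)
  else sqrt(mean((x - mean(x))^2))
}

check_wells <- function(wells, need = c("plate_id", "well_id", "role",
                                        "efficiency")) {
  stopifnot(is.data.frame(wells))
  missing <- setdiff(need, names(wells))
  if (length(missing))
    stop("wells table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(wells$role), c("neg_control", "pos_control", "test"))
  if (length(bad))
    stop("invalid role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(wells$valid)) wells$valid <- !is.na(wells$efficiency)
  wells
}

#' Range-normalize one plate between its control medians
#'
#' Rescales every well of a single plate so that the median efficiency of
#' its negative-control (irrelevant shRNA) wells maps exactly to 0 and the
#' median of its positive-control wells maps exactly to 1:
#' \deqn{normalized = \frac{eff - median_{neg}}{median_{pos} - median_{neg}}}
#' Values are deliberately not clipped: test wells may fall below 0 or
#' above 1, and clipping would truncate the Z-score tails downstream.
#' The per-plate affine rescaling removes additive and multiplicative
#' plate offsets.
#'
#' Plates with fewer than `min_controls` valid wells of either control
#' role, or whose positive median does not exceed the negative median,
#' are flagged `failed_controls` and all their wells invalidated.
#'
#' @param wells Data frame of one plate's wells with columns `plate_id`,
#'   `well_id`, `role` (neg_control / pos_control / test), `efficiency`
#'   (fraction in \[0, 1\]; NA allowed for invalid wells) and optionally
#'   `valid`.
#' @param min_controls Minimum valid control wells per role (default 2).
#' @return The data frame with columns `normalized`, `valid` and
#'   `plate_qc` added/updated.
#' @export
range_normalize_plate <- function(wells, min_controls = 2L) {
  wells <- check_wells(wells)
  if (length(unique(wells$plate_id)) != 1L)
    stop("range_normalize_plate expects a single plate; see normalize_screen()",
         call. = FALSE)
  neg <- wells$efficiency[wells$role == "neg_control" & wells$valid]
  pos <- wells$efficiency[wells$role == "pos_control" & wells$valid]
  wells$normalized <- NA_real_
  wells$plate_qc <- ""
  if (length(neg) < min_controls || length(pos) < min_controls ||
      median(pos) <= median(neg)) {
    wells$plate_qc <- "failed_controls"
    wells$valid <- FALSE
    return(wells)
  }
  m0 <- median(neg)
  m1 <- median(pos)
  wells$normalized <- (wells$efficiency - m0) / (m1 - m0)
  wells
}

#' Range-normalize every plate of a screen
#'
#' Applies [range_normalize_plate()] plate by plate and re-assembles the
#' screen in the original row order.
#'
#' @inheritParams range_normalize_plate
#' @return The full wells data frame with `normalized`, `valid`,
#'   `plate_qc` columns.
#' @export
normalize_screen <- function(wells, min_controls = 2L) {
  wells <- check_wells(wells)
  wells$.row <- seq_len(nrow(wells))
  out <- do.call(rbind, lapply(split(wells, wells$plate_id),
                               range_normalize_plate,
                               min_controls = min_controls))
  out <- out[order(out$.row), , drop = FALSE]
  out$.row <- NULL
  rownames(out) <- NULL
  out
}

#' Pool normalized wells and compute Z scores against the control null
#'
#' After per-plate normalization, all plates are pooled and each well's Z
#' score is computed from the distribution of the pooled valid
#' negative-control wells: \eqn{z = (normalized - \bar{x}_{null}) /
#' s_{null}}. The null wells therefore self-standardize to mean 0 and
#' (under the chosen estimator) sd 1 exactly.
#'
#' @param wells Normalized wells data frame (from [normalize_screen()]).
#' @param params A [hit_params()] object (chooses the sd estimator).
#' @param min_null Minimum pooled valid negative-control wells (default 3).
#' @return The data frame with a `z` column (NA for invalid wells).
#' @export
pool_and_zscore <- function(wells, params = hit_params(), min_null = 3L) {
  if (is.null(wells$normalized))
    stop("wells are not normalized; run normalize_screen() first",
         call. = FALSE)
  null <- wells$normalized[wells$role == "neg_control" & wells$valid]
  if (length(null) < min_null)
    stop(sprintf("need >= %d pooled valid negative-control wells, have %d",
                 min_null, length(null)), call. = FALSE)
  s <- null_sd(null, params$sd_estimator)
  if (s == 0)
    stop("degenerate null: pooled negative controls have zero spread",
         call. = FALSE)
  wells$z <- ifelse(wells$valid, (wells$normalized - mean(null)) / s, NA_real_)
  wells
}

#' Flag cytotoxic, non-expressed and invalid wells for exclusion
#'
#' A hairpin that kills cells confounds the infection readout, and a
#' hairpin against a gene the cell line does not express cannot inform on
#' it; both are excluded from hit calling. Cytotoxicity is operationalized
#' from the imaging cell counts: a well is cytotoxic when its cell count
#' is strictly below `cytotoxicity_fraction` times the median cell count
#' of its plate's negative-control wells (a count exactly at the threshold
#' is kept). Expression status comes from an external annotation table;
#' when absent, the expression filter is skipped with a message.
#'
#' Exclusion reasons are assigned with priority invalid_well > cytotoxic >
#' not_expressed.
#'
#' @param wells Wells data frame with `cell_count` (and `gene_id` if an
#'   expression table is supplied).
#' @param expression_table Optional data frame (`gene_id`, `expressed`
#'   logical).
#' @param params A [hit_params()] object.
#' @return The data frame with logical `excluded` and character
#'   `exclusion_reason` (`none`, `invalid_well`, `cytotoxic`,
#'   `not_expressed`) columns.
#' @export
flag_exclusions <- function(wells, expression_table = NULL,
                            params = hit_params()) {
  wells <- check_wells(wells)
  if (is.null(wells$cell_count))
    stop("wells table lacks cell_count; cytotoxicity cannot be assessed",
         call. = FALSE)
  reason <- rep("none", nrow(wells))

  if (!is.null(expression_table)) {
    stopifnot(all(c("gene_id", "expressed") %in% names(expression_table)))
    notexp <- expression_table$gene_id[!expression_table$expressed]
    reason[wells$role == "test" & wells$gene_id %in% notexp] <- "not_expressed"
  } else {
    message("no expression table supplied; expression filter skipped")
  }

  for (pid in unique(wells$plate_id)) {
    onplate <- wells$plate_id == pid
    negct <- wells$cell_count[onplate & wells$role == "neg_control" &
                                wells$valid]
    if (length(negct) == 0) next
    cut <- params$cytotoxicity_fraction * median(negct)
    tox <- onplate & wells$cell_count < cut   # strict: at-threshold is kept
    reason[tox] <- "cytotoxic"
  }
  reason[!wells$valid] <- "invalid_well"
  wells$excluded <- reason != "none"
  wells$exclusion_reason <- reason
  wells
}

#' Call per-shRNA hits
#'
#' An shRNA scores as a hit when it is not excluded and its Z score is at
#' or above the threshold (inclusive boundary: z exactly equal to the
#' threshold is a hit).
#'
#' @param scores Wells/scores data frame with `z` and (optionally)
#'   `excluded` columns.
#' @param params A [hit_params()] object.
#' @return The data frame with a logical `hit` column.
#' @export
call_shrna_hits <- function(scores, params = hit_params()) {
  if (is.null(scores$z))
    stop("no z column; run pool_and_zscore() first", call. = FALSE)
  excluded <- scores$excluded %||% rep(FALSE, nrow(scores))
  scores$hit <- !excluded & !is.na(scores$z) & scores$z >= params$z_threshold
  scores
}

#' Call gene-level positive regulators
#'
#' A gene scores as a positive regulator of the antiviral response when at
#' least `min_hits` distinct hairpins targeting it are hits (default 2) -
#' the redundancy requirement that guards against single-hairpin
#' off-target effects. Only test wells contribute; control wells carry no
#' gene.
#'
#' @param scores Data frame with `role`, `gene_id`, `shrna_id`, `hit`.
#' @param params A [hit_params()] object.
#' @return Data frame (`gene_id`, `n_shrnas_tested`, `n_hits`,
#'   `positive`), one row per gene, sorted by `gene_id`.
#' @export
call_gene_hits <- function(scores, params = hit_params()) {
  if (is.null(scores$hit))
    stop("no hit column; run call_shrna_hits() first", call. = FALSE)
  tw <- scores[scores$role == "test", , drop = FALSE]
  genes <- sort(unique(tw$gene_id))
  out <- do.call(rbind, lapply(genes, function(g) {
    sub <- tw[tw$gene_id == g, , drop = FALSE]
    n_hits <- length(unique(sub$shrna_id[sub$hit]))
    data.frame(gene_id = g,
               n_shrnas_tested = length(unique(sub$shrna_id)),
               n_hits = n_hits,
               positive = n_hits >= params$min_hits)
  }))
  out %||% data.frame(gene_id = character(), n_shrnas_tested = integer(),
                      n_hits = integer(), positive = logical())
}

#' Ranked table of normalized scores
#'
#' Orders all wells by ascending normalized value (stable; ties broken by
#' shRNA id) - the layout of the classic ranked range-normalization plot
#' in which negative controls cluster near 0, positive controls near 1,
#' and hits occupy the upper tail beyond the Z threshold.
#'
#' @param scores Data frame with `normalized` (plus `shrna_id`, `role`,
#'   `z`, `hit` if present).
#' @return The rows ordered by normalized value with a `rank` column
#'   prepended.
#' @export
rank_normalized_table <- function(scores) {
  if (is.null(scores$normalized))
    stop("no normalized column; run normalize_screen() first", call. = FALSE)
  tie <- scores$shrna_id %||% rep("", nrow(scores))
  ord <- order(scores$normalized, tie, method = "radix")
  out <- scores[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Fold change between two infection efficiencies
#'
#' Reports the ratio as a "fold reduction" (reference / treated; e.g. a
#' drop from 20% to 5% under interferon priming is a 4-fold reduction) or
#' a "fold increase" (treated / reference; e.g. knocking down an
#' interferon receptor raising infectivity from 4% to 14% is a 3.5-fold
#' increase).
#'
#' @param reference_eff,treated_eff Efficiencies (fractions), >= 0.
#' @param direction `"reduction"` (reference / treated) or `"increase"`
#'   (treated / reference).
#' @return The fold change; `Inf` with a warning when the denominator is
#'   zero.
#' @export
fold_change <- function(reference_eff, treated_eff,
                        direction = c("reduction", "increase")) {
  direction <- match.arg(direction)
  if (reference_eff < 0 || treated_eff < 0)
    stop_domain("efficiency", "must be >= 0")
  den <- if (direction == "reduction") treated_eff else reference_eff
  num <- if (direction == "reduction") reference_eff else treated_eff
  if (den == 0) {
    warning("zero denominator efficiency; fold change is infinite")
    return(Inf)
  }
  num / den
}

#' Run the full scoring stage on a wells table
#'
#' Normalize per plate, flag exclusions, Z-score against the pooled
#' negative-control null, call shRNA hits and gene-level positives.
#'
#' @param wells Wells data frame (see [normalize_screen()]; needs
#'   `cell_count` for the cytotoxicity filter, plus `shrna_id`/`gene_id`
#'   on test wells).
#' @param params A [hit_params()] object.
#' @param expression_table Optional gene expression annotation (see
#'   [flag_exclusions()]).
#' @return List of class `screen_scores`: `scores` (per-well data frame
#'   with normalized, z, excluded, hit), `gene_calls`, `ranked`.
#' @export
score_screen <- function(wells, params = hit_params(),
                         expression_table = NULL) {
  scores <- normalize_screen(wells)
  if (!is.null(wells$cell_count)) {
    scores <- suppressMessages(
      flag_exclusions(scores, expression_table, params))
  }
  scores <- pool_and_zscore(scores, params)
  scores <- call_shrna_hits(scores, params)
  structure(list(scores = scores,
                 gene_calls = call_gene_hits(scores, params),
                 ranked = rank_normalized_table(scores)),
            class = "screen_scores")
}
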