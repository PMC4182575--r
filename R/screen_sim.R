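#' Design of a simulated arrayed shRNA screen
#'
#' Describes a full multi-plate 96-well screen: an shRNA library of
#' `n_genes` genes covered by `n_shrnas` hairpins (hairpins are spread as
#' evenly as possible, so the default 827 hairpins over 161 genes gives
#' five per gene with the remainder genes carrying six), in-plate
#' negative (irrelevant shRNA) and positive controls on every plate, a
#' baseline infection efficiency in the interferon-primed regime,
#' multiplicative planted effects for a chosen set of positive-regulator
#' genes, lognormal plate-to-plate offsets, and additive Gaussian well
#' noise.
#'
#' The planted effect is expressed as a fold increase over baseline. Its
#' default is calibrated so that an effective hairpin sits
#' `planted_shift_sds` (default 5) approximate null standard deviations
#' above the null on the normalized scale: with well noise sd
#' \eqn{\sigma} and baseline \eqn{b}, the fold is \eqn{1 +
#' planted\_shift\_sds \cdot \sigma / b}.
#'
#' @param n_genes Number of genes in the library.
#' @param n_shrnas Total hairpins across all genes.
#' @param wells_per_plate Plate capacity (default 96).
#' @param n_neg_controls,n_pos_controls Control wells per plate.
#' @param baseline Baseline infection efficiency (fraction) of a
#'   neutral well under interferon priming; default 0.075, the middle of
#'   the 5-10% working band the screen is titrated into.
#' @param pos_effect Fold increase of the positive-control wells over
#'   baseline (default 3.5, the effect of knocking down an interferon
#'   receptor).
#' @param plate_offset_sd sdlog of the lognormal multiplicative
#'   plate offset (0 disables plate effects).
#' @param well_noise_sd Additive Gaussian noise sd on the efficiency
#'   scale.
#' @param n_positive_genes Number of genes planted as true positive
#'   regulators.
#' @param effective_shrnas Number of hairpins per positive gene that carry
#'   the planted effect (the rest stay at effect 1, mimicking hairpins
#'   with poor knockdown).
#' @param planted_shift_sds Planted effect size in approximate null
#'   standard deviations (see Details); ignored when `planted_fold` is
#'   given.
#' @param planted_fold Explicit fold increase for effective hairpins of
#'   positive genes; overrides `planted_shift_sds`.
#' @param cytotoxic_rate Per-well Bernoulli probability that a test
#'   hairpin is cytotoxic (cell count collapses).
#' @param cytotoxic_cell_fraction Cell count of a cytotoxic well as a
#'   fraction of the normal mean.
#' @param cells_mean,cells_sd Normal cell-count distribution of healthy
#'   wells.
#' @return A list of class `screen_design`.
#' @export
screen_design <- function(n_genes = 161L,
                          n_shrnas = 827L,
                          wells_per_plate = 96L,
                          n_neg_controls = 6L,
                          n_pos_controls = 6L,
                          baseline = 0.075,
                          pos_effect = 3.5,
                          plate_offset_sd = 0.1,
                          well_noise_sd = 0.015,
                          n_positive_genes = 14L,
                          effective_shrnas = 3L,
                          planted_shift_sds = 5,
                          planted_fold = NULL,
                          cytotoxic_rate = 0,
                          cytotoxic_cell_fraction = 0.1,
                          cells_mean = 2000,
                          cells_sd = 150) {
  if (n_shrnas < n_genes)
    stop_domain("n_shrnas", "must be >= n_genes (every gene needs a hairpin)")
  if (n_neg_controls < 1 || n_pos_controls < 1)
    stop_domain("controls", "every plate needs negative and positive controls")
  if (wells_per_plate <= n_neg_controls + n_pos_controls)
    stop_domain("wells_per_plate", "no room for test wells after controls")
  if (baseline <= 0 || baseline >= 1)
    stop_domain("baseline", "must be a fraction in (0, 1)")
  if (pos_effect <= 1) stop_domain("pos_effect", "must exceed 1")
  if (n_positive_genes > n_genes)
    stop_domain("n_positive_genes", "cannot exceed n_genes")
  planted_fold <- planted_fold %||%
    (1 + planted_shift_sds * well_noise_sd / baseline)
  structure(list(n_genes = as.integer(n_genes),
                 n_shrnas = as.integer(n_shrnas),
                 wells_per_plate = as.integer(wells_per_plate),
                 n_neg_controls = as.integer(n_neg_controls),
                 n_pos_controls = as.integer(n_pos_controls),
                 baseline = baseline, pos_effect = pos_effect,
                 plate_offset_sd = plate_offset_sd,
                 well_noise_sd = well_noise_sd,
                 n_positive_genes = as.integer(n_positive_genes),
                 effective_shrnas = as.integer(effective_shrnas),
                 planted_fold = planted_fold,
                 cytotoxic_rate = cytotoxic_rate,
                 cytotoxic_cell_fraction = cytotoxic_cell_fraction,
                 cells_mean = cells_mean, cells_sd = cells_sd),
            class = "screen_design")
}

# Deterministic library layout: gene/shRNA ids, hairpins per gene as even
# as possible (first `extra` genes get one more), wells filled row-major
# with controls in the first columns of every plate.
screen_layout <- function(design) {
  per_gene <- rep(design$n_shrnas %/% design$n_genes, design$n_genes)
  extra <- design$n_shrnas %% design$n_genes
  if (extra > 0) per_gene[seq_len(extra)] <- per_gene[seq_len(extra)] + 1L
  gene_ids <- sprintf("gene%03d", seq_len(design$n_genes))
  shrnas <- data.frame(
    shrna_id = unlist(lapply(seq_len(design$n_genes), function(g) {
      sprintf("%s_sh%d", gene_ids[g], seq_len(per_gene[g]))
    })),
    gene_id = rep(gene_ids, per_gene)
  )

  test_per_plate <- design$wells_per_plate - design$n_neg_controls -
    design$n_pos_controls
  n_plates <- ceiling(design$n_shrnas / test_per_plate)

  well_ids <- as.vector(t(outer(LETTERS[1:8],
                                sprintf("%02d", 1:12), paste0)))
  rows <- NULL
  k <- 0L
  for (p in seq_len(n_plates)) {
    pid <- sprintf("plate%02d", p)
    n_test <- min(test_per_plate, design$n_shrnas - k)
    roles <- c(rep("neg_control", design$n_neg_controls),
               rep("pos_control", design$n_pos_controls),
               rep("test", n_test))
    sh <- c(rep("", design$n_neg_controls + design$n_pos_controls),
            shrnas$shrna_id[k + seq_len(n_test)])
    gn <- c(rep("", design$n_neg_controls + design$n_pos_controls),
            shrnas$gene_id[k + seq_len(n_test)])
    rows <- rbind(rows, data.frame(plate_id = pid,
                                   well_id = well_ids[seq_along(roles)],
                                   role = roles, shrna_id = sh, gene_id = gn))
    k <- k + n_test
  }
  list(map = rows, shrnas = shrnas, gene_ids = gene_ids, n_plates = n_plates)
}

#' Simulate a whole arrayed screen at the well level
#'
#' Fast, imageless simulation: each well's measured infection efficiency
#' is \deqn{clamp_{[0,1]}(baseline \times effect \times plateOffset +
#' \epsilon), \quad \epsilon \sim N(0, \sigma_{well})} where effect is 1
#' for negative controls and neutral hairpins, `pos_effect` for positive
#' controls, and `planted_fold` for the effective hairpins of planted
#' positive genes. Plate offsets are lognormal. Ground truth (which genes
#' are positive, which hairpins carry the effect, which wells are
#' cytotoxic) is drawn from a sub-seed separate from the measurement
#' noise, so re-simulating with different noise leaves the truth
#' unchanged.
#'
#' @param design A [screen_design()].
#' @param seed Integer seed.
#' @return List of class `screen_sim`: `wells` (data frame plate_id,
#'   well_id, role, shrna_id, gene_id, efficiency, cell_count, valid) and
#'   `truth` (list: `shrna_effects` data frame with per-hairpin fold,
#'   `gene_status` data frame with logical `positive`, `cytotoxic`
#'   logical per well row).
#' @export
simulate_screen <- function(design = screen_design(), seed = 1L) {
  stopifnot(inherits(design, "screen_design"))
  lay <- screen_layout(design)
  wells <- lay$map

  truth <- with_seed_if(derive_seed(seed, 11L), {
    pos_genes <- sample(lay$gene_ids, design$n_positive_genes)
    eff <- rep(1, nrow(lay$shrnas))
    for (g in pos_genes) {
      idx <- which(lay$shrnas$gene_id == g)
      take <- idx[seq_len(min(design$effective_shrnas, length(idx)))]
      eff[take] <- design$planted_fold
    }
    cytotoxic <- wells$role == "test" &
      runif(nrow(wells)) < design$cytotoxic_rate
    list(shrna_effects = data.frame(lay$shrnas, effect = eff),
         gene_status = data.frame(gene_id = lay$gene_ids,
                                  positive = lay$gene_ids %in% pos_genes),
         cytotoxic = cytotoxic)
  })

  effect <- rep(1, nrow(wells))
  effect[wells$role == "pos_control"] <- design$pos_effect
  ti <- match(wells$shrna_id, truth$shrna_effects$shrna_id)
  effect[!is.na(ti)] <- truth$shrna_effects$effect[ti[!is.na(ti)]]

  wells <- with_seed_if(derive_seed(seed, 12L), {
    plates <- unique(wells$plate_id)
    offs <- exp(rnorm(length(plates), 0, design$plate_offset_sd))
    off <- offs[match(wells$plate_id, plates)]
    eff <- clamp01(design$baseline * effect * off +
                     rnorm(nrow(wells), 0, design$well_noise_sd))
    cells <- round(rnorm(nrow(wells), design$cells_mean, design$cells_sd))
    cells[truth$cytotoxic] <-
      round(rnorm(sum(truth$cytotoxic),
                  design$cells_mean * design$cytotoxic_cell_fraction,
                  design$cells_sd * design$cytotoxic_cell_fraction))
    cells <- pmax(cells, 0L)
    wells$efficiency <- eff
    wells$cell_count <- as.integer(cells)
    wells$valid <- TRUE
    wells
  })

  structure(list(wells = wells, truth = truth, design = design, seed = seed),
            class = "screen_sim")
}

#' Compare gene-level calls with simulation ground truth
#'
#' @param gene_calls Data frame from [call_gene_hits()].
#' @param truth A `screen_sim` truth list (or its `gene_status` data
#'   frame).
#' @return List: `sensitivity` (recovered true positives / planted
#'   positives), `specificity` (true negatives called negative / true
#'   negatives), `confusion` (per-gene data frame with `called` and
#'   `truth` columns).
#' @export
evaluate_recovery <- function(gene_calls, truth) {
  status <- if (is.data.frame(truth)) truth else truth$gene_status
  stopifnot(all(c("gene_id", "positive") %in% names(status)))
  common <- intersect(gene_calls$gene_id, status$gene_id)
  if (length(common) == 0)
    stop("gene calls and truth share no genes", call. = FALSE)
  called <- gene_calls$positive[match(common, gene_calls$gene_id)]
  istrue <- status$positive[match(common, status$gene_id)]
  tp <- sum(called & istrue); fn <- sum(!called & istrue)
  tn <- sum(!called & !istrue); fp <- sum(called & !istrue)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       confusion = data.frame(gene_id = common, called = called,
                              truth = istrue))
}

#' Power and false-positive rate over a grid of effect sizes
#'
#' Replicates simulated screens at each planted fold in `effect_grid`,
#' runs the full scoring pipeline, and reports mean gene-level
#' sensitivity and the shRNA-level false positive rate (hits among
#' hairpins with true effect 1).
#'
#' @param design A [screen_design()] template; its `planted_fold` is
#'   overridden by the grid.
#' @param effect_grid Numeric vector of fold increases (1 = null).
#' @param n_replicates Screens per grid point.
#' @param seed Integer master seed.
#' @param params A [hit_params()] object.
#' @return Data frame (effect, sensitivity, shrna_fpr, n_replicates).
#' @export
power_curve <- function(design = screen_design(), effect_grid,
                        n_replicates = 10L, seed = 1L,
                        params = hit_params()) {
  if (length(effect_grid) == 0) stop_domain("effect_grid", "must be non-empty")
  out <- NULL
  for (i in seq_along(effect_grid)) {
    f <- effect_grid[i]
    d <- design
    d$planted_fold <- f
    sens <- fpr <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      sim <- simulate_screen(d, seed = derive_seed(seed, i, r))
      res <- score_screen(sim$wells, params)
      rec <- evaluate_recovery(res$gene_calls, sim$truth)
      sens[r] <- rec$sensitivity
      nulls <- sim$truth$shrna_effects$shrna_id[
        sim$truth$shrna_effects$effect == 1]
      sc <- res$scores
      nw <- sc[sc$role == "test" & sc$shrna_id %in% nulls, , drop = FALSE]
      fpr[r] <- mean(nw$hit)
    }
    out <- rbind(out, data.frame(effect = f, sensitivity = mean(sens),
                                 shrna_fpr = mean(fpr),
                                 n_replicates = n_replicates))
  }
  out
}
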