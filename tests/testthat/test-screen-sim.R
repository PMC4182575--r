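test_that("the default library layout matches the screen's composition", {
  d <- screen_design()
  lay <- hcscreen:::screen_layout(d)
  expect_identical(nrow(lay$shrnas), 827L)
  expect_identical(length(unique(lay$shrnas$gene_id)), 161L)
  per_gene <- table(lay$shrnas$gene_id)
  expect_true(all(per_gene %in% c(5L, 6L)))   # average ~5 hairpins per gene
  sim <- simulate_screen(d, seed = 1)
  expect_identical(sum(sim$wells$role == "test"), 827L)
  expect_identical(anyDuplicated(sim$wells$shrna_id[sim$wells$role == "test"]),
                   0L)
  # controls on every plate
  per_plate <- table(sim$wells$plate_id, sim$wells$role)
  expect_true(all(per_plate[, "neg_control"] == d$n_neg_controls))
  expect_true(all(per_plate[, "pos_control"] == d$n_pos_controls))
})

test_that("a noiseless screen is exactly the design's means", {
  d <- screen_design(n_genes = 10, n_shrnas = 50, n_positive_genes = 0,
                     plate_offset_sd = 0, well_noise_sd = 0)
  sim <- simulate_screen(d, seed = 3)
  expect_true(all(sim$wells$efficiency[sim$wells$role != "pos_control"] ==
                    d$baseline))
  expect_equal(unique(sim$wells$efficiency[sim$wells$role == "pos_control"]),
               3.5 * d$baseline)
})

test_that("simulation is seed-deterministic with truth/noise separation", {
  d <- screen_design(n_genes = 20, n_shrnas = 100, n_positive_genes = 4)
  a <- simulate_screen(d, seed = 9)
  b <- simulate_screen(d, seed = 9)
  expect_identical(a$wells, b$wells)
  expect_identical(a$truth, b$truth)
  # different noise level, same seed: measurements change, truth does not
  d2 <- d; d2$well_noise_sd <- d$well_noise_sd * 3
  c <- simulate_screen(d2, seed = 9)
  expect_identical(a$truth$shrna_effects, c$truth$shrna_effects)
  expect_identical(a$truth$gene_status, c$truth$gene_status)
  expect_false(identical(a$wells$efficiency, c$wells$efficiency))
  expect_true(all(c$wells$efficiency >= 0 & c$wells$efficiency <= 1))
})

test_that("zero-noise screens feed through scoring to exact truth recovery", {
  d <- screen_design(n_genes = 30, n_shrnas = 150, n_positive_genes = 5,
                     plate_offset_sd = 0, well_noise_sd = 0,
                     planted_fold = 2)
  sim <- simulate_screen(d, seed = 11)
  # zero spread in the null is degenerate by design; add a whisper of
  # noise to the controls only, keeping test wells exact
  wells <- sim$wells
  negs <- wells$role == "neg_control"
  wells$efficiency[negs] <- wells$efficiency[negs] +
    withr::with_seed(1, rnorm(sum(negs), 0, 1e-6))
  res <- score_screen(wells)
  rec <- evaluate_recovery(res$gene_calls, sim$truth)
  expect_equal(rec$sensitivity, 1.0)
  expect_equal(rec$specificity, 1.0)
})

test_that("recovery evaluation handles the trivial and error cases", {
  truth <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      positive = c(TRUE, TRUE, FALSE, FALSE))
  perfect <- data.frame(gene_id = truth$gene_id, positive = truth$positive)
  r <- evaluate_recovery(perfect, truth)
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$specificity, 1.0)
  none <- data.frame(gene_id = truth$gene_id, positive = FALSE)
  r0 <- evaluate_recovery(none, truth)
  expect_equal(r0$sensitivity, 0.0)
  expect_equal(r0$specificity, 1.0)
  other <- data.frame(gene_id = c("x1", "x2"), positive = TRUE)
  expect_error(evaluate_recovery(other, truth), "share no genes")
})

test_that("power rises with effect size while the FPR stays at the null tail", {
  d <- screen_design(n_genes = 40, n_shrnas = 200, n_positive_genes = 6,
                     effective_shrnas = 3)
  pc <- power_curve(d, effect_grid = c(1, 1.5, 2.5), n_replicates = 4,
                    seed = 7)
  expect_identical(nrow(pc), 3L)
  expect_lte(pc$sensitivity[1], 0.05)            # null effect: nothing found
  expect_gte(pc$sensitivity[3], pc$sensitivity[1])
  expect_gte(pc$sensitivity[3], 0.9)             # strong effect: recovered
  # the false-positive rate is a property of the null machinery, not of
  # the planted effect: small everywhere, and not rising with effect size
  expect_true(all(pc$shrna_fpr < 0.05))
  expect_lt(abs(pc$shrna_fpr[3] - pc$shrna_fpr[1]), 0.05)
})
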