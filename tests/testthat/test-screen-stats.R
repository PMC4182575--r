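test_that("range normalization maps control medians to 0 and 1 exactly", {
  plate <- manual_plate(neg = c(0.01, 0.02, 0.03), pos = c(0.06, 0.08, 0.10),
                        test = c(0.02, 0.08, 0.05, 0.11))
  norm <- range_normalize_plate(plate)
  expect_equal(norm$normalized[norm$efficiency == 0.02 &
                                 norm$role == "test"], 0.0)
  expect_equal(norm$normalized[norm$efficiency == 0.08 &
                                 norm$role == "test"], 1.0)
  expect_equal(median(norm$normalized[norm$role == "neg_control"]), 0.0)
  expect_equal(median(norm$normalized[norm$role == "pos_control"]), 1.0)
  # hand arithmetic: (0.05 - 0.02) / (0.08 - 0.02) and the unclipped case
  expect_equal(norm$normalized[norm$efficiency == 0.05], 0.5)
  expect_equal(norm$normalized[norm$efficiency == 0.11], 1.5)
})

test_that("normalization is invariant to per-plate affine transforms", {
  plate <- manual_plate(neg = c(0.02, 0.03, 0.04), pos = c(0.10, 0.12, 0.14),
                        test = seq(0.01, 0.15, length.out = 10))
  a <- range_normalize_plate(plate)
  plate$efficiency <- 0.9 * plate$efficiency + 0.004   # gain + offset
  b <- range_normalize_plate(plate)
  expect_equal(a$normalized, b$normalized, tolerance = 1e-12)
})

test_that("plates with failed or insufficient controls are invalidated", {
  rev <- manual_plate(neg = c(0.10, 0.11), pos = c(0.02, 0.03),
                      test = c(0.05, 0.06))
  out <- range_normalize_plate(rev)
  expect_true(all(out$plate_qc == "failed_controls"))
  expect_false(any(out$valid))
  few <- manual_plate(neg = 0.02, pos = c(0.08, 0.09), test = 0.05)
  expect_false(any(range_normalize_plate(few)$valid))
})

test_that("Z scores are computed against the pooled negative-control null", {
  # null {-0.1, 0, 0.1} has sample sd 0.1, so a value of 0.3 scores z = 3
  wells <- manual_plate(neg = c(0.02, 0.03, 0.04), pos = c(0.12, 0.13, 0.14),
                        test = c(0.05, 0.06))
  wells$normalized <- c(-0.1, 0, 0.1, 1, 1, 1, 0.3, 0)
  z <- pool_and_zscore(wells)
  expect_equal(z$z[z$role == "test"][1], 3.0)
  expect_equal(z$z[z$role == "test"][2], 0.0)
  # self-standardization: null z has mean 0 and sample sd exactly 1
  nz <- z$z[z$role == "neg_control"]
  expect_equal(mean(nz), 0)
  expect_equal(sd(nz), 1)
  # population estimator differs by sqrt((n-1)/n)
  zp <- pool_and_zscore(wells, hit_params(sd_estimator = "population"))
  expect_equal(zp$z[zp$role == "test"][1], 3 / sqrt(2 / 3))
})

test_that("degenerate or missing nulls error", {
  wells <- manual_plate(neg = c(0.02, 0.02, 0.02), pos = c(0.12, 0.13, 0.14),
                        test = 0.05)
  wells$normalized <- c(0, 0, 0, 1, 1, 1, 0.5)
  expect_error(pool_and_zscore(wells), "degenerate")
  expect_error(pool_and_zscore(wells[wells$role != "neg_control", ]),
               "negative-control")
})

test_that("adding a per-plate offset leaves pooled Z scores unchanged", {
  d <- screen_design(n_genes = 30, n_shrnas = 150, n_positive_genes = 3,
                     plate_offset_sd = 0)
  sim <- simulate_screen(d, seed = 5)
  base <- pool_and_zscore(normalize_screen(sim$wells))
  shifted <- sim$wells
  for (p in unique(shifted$plate_id)) {
    shifted$efficiency[shifted$plate_id == p] <-
      shifted$efficiency[shifted$plate_id == p] +
      0.01 * match(p, unique(shifted$plate_id))
  }
  out <- pool_and_zscore(normalize_screen(shifted))
  expect_equal(out$z, base$z, tolerance = 1e-9)
})

test_that("cytotoxicity exclusion uses a strict per-plate cell-count threshold", {
  plate <- manual_plate(neg = c(0.02, 0.03, 0.04), pos = c(0.12, 0.13, 0.14),
                        test = c(0.05, 0.06, 0.07))
  plate$cell_count <- c(2000L, 2000L, 2000L, 2000L, 2000L, 2000L,
                        0L, 1000L, 999L)  # threshold = 0.5 * 2000 = 1000
  out <- suppressMessages(flag_exclusions(plate))
  tw <- out[out$role == "test", ]
  expect_identical(tw$exclusion_reason, c("cytotoxic", "none", "cytotoxic"))
  expect_identical(tw$excluded, c(TRUE, FALSE, TRUE))
})

test_that("expression and validity exclusions are applied with priority", {
  plate <- manual_plate(neg = c(0.02, 0.03), pos = c(0.12, 0.13),
                        test = c(0.05, 0.06, NA))
  plate$valid <- !is.na(plate$efficiency)
  expr <- data.frame(gene_id = c("g01", "g02", "g03"),
                     expressed = c(FALSE, TRUE, TRUE))
  out <- flag_exclusions(plate, expr)
  tw <- out[out$role == "test", ]
  expect_identical(tw$exclusion_reason,
                   c("not_expressed", "none", "invalid_well"))
  expect_message(flag_exclusions(plate), "expression filter skipped")
})

test_that("planted cytotoxic wells are flagged without false flags", {
  d <- screen_design(n_genes = 40, n_shrnas = 200, n_positive_genes = 0,
                     cytotoxic_rate = 0.05)
  sim <- simulate_screen(d, seed = 17)
  out <- suppressMessages(flag_exclusions(sim$wells))
  expect_identical(out$exclusion_reason == "cytotoxic", sim$truth$cytotoxic)
})

test_that("shRNA hit calls use an inclusive Z threshold and honor exclusions", {
  sc <- data.frame(role = "test", shrna_id = c("a", "b", "c"),
                   gene_id = "g", z = c(3.0, 2.999, 5.0),
                   excluded = c(FALSE, FALSE, TRUE))
  out <- call_shrna_hits(sc)
  expect_identical(out$hit, c(TRUE, FALSE, FALSE))
})

test_that("gene calls require two or more distinct scoring hairpins", {
  sc <- data.frame(
    role = "test",
    gene_id = c(rep("gA", 3), rep("gB", 5)),
    shrna_id = c("a1", "a2", "a3", "b1", "b2", "b3", "b4", "b5"),
    z = c(3.2, 3.0, 0.1, 5.0, 1.0, 1.0, 1.0, 1.0),
    excluded = FALSE)
  calls <- call_gene_hits(call_shrna_hits(sc))
  expect_identical(calls$positive[calls$gene_id == "gA"], TRUE)   # 2 hits
  expect_identical(calls$n_hits[calls$gene_id == "gA"], 2L)
  expect_identical(calls$positive[calls$gene_id == "gB"], FALSE)  # 1 hit
  expect_identical(calls$n_shrnas_tested[calls$gene_id == "gB"], 5L)
  # a duplicated hit hairpin counts once
  dup <- rbind(sc, sc[1, ])
  calls2 <- call_gene_hits(call_shrna_hits(dup))
  expect_identical(calls2$n_hits[calls2$gene_id == "gA"], 2L)
})

test_that("ranked table sorts ascending with stable lexicographic ties", {
  sc <- data.frame(role = "test", shrna_id = c("z", "a", "m"),
                   gene_id = "g", normalized = c(0.2, -0.1, 1.4))
  rk <- rank_normalized_table(sc)
  expect_identical(rk$rank, 1:3)
  expect_identical(rk$normalized, c(-0.1, 0.2, 1.4))
  ties <- data.frame(role = "test", shrna_id = c("b", "a", "c"),
                     gene_id = "g", normalized = 0.5)
  expect_identical(rank_normalized_table(ties)$shrna_id, c("a", "b", "c"))
})

test_that("fold changes report reduction and increase conventions", {
  expect_equal(fold_change(0.20, 0.05, "reduction"), 4.0)
  expect_equal(fold_change(0.05, 0.05), 1.0)
  expect_equal(fold_change(0.04, 0.14, "increase"), 3.5)
  expect_warning(out <- fold_change(0.2, 0, "reduction"), "zero denominator")
  expect_identical(out, Inf)
})
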