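test_that("field generation is a pure function of (params, seed)", {
  p <- small_field_params()
  a <- generate_field(p, 0.4, seed = 11)
  b <- generate_field(p, 0.4, seed = 11)
  expect_identical(a$image$hoechst, b$image$hoechst)
  expect_identical(a$image$gfp, b$image$gfp)
  expect_identical(a$truth, b$truth)
  d <- generate_field(p, 0.4, seed = 12)
  expect_false(identical(a$truth$cells, d$truth$cells))
})

test_that("empty fields are background-only with empty truth", {
  f <- generate_field(image_gen_params(n_cells = 0), 0, seed = 1)
  expect_identical(f$truth$n_cells, 0L)
  expect_identical(nrow(f$truth$cells), 0L)
  # only background + read noise remains
  expect_lt(diff(range(f$image$hoechst)), 0.12)
  expect_equal(mean(f$image$gfp), 0.05, tolerance = 0.005)
})

test_that("infection flags honor the per-cell probability", {
  f <- generate_field(small_field_params(n_cells = 30), 1, seed = 3,
                      render = FALSE)
  expect_identical(f$truth$n_infected, 30L)
  f0 <- generate_field(small_field_params(n_cells = 30), 0, seed = 3,
                       render = FALSE)
  expect_identical(f0$truth$n_infected, 0L)
})

test_that("infected fraction is binomial across seeds", {
  p <- image_gen_params(field_dim = c(512L, 512L), n_cells = 500L)
  fr <- vapply(1:100, function(s) {
    tr <- generate_field(p, 0.3, seed = s, render = FALSE)$truth
    tr$n_infected / tr$n_cells
  }, numeric(1))
  se <- sqrt(0.3 * 0.7 / 500 / 100)
  expect_lt(abs(mean(fr) - 0.3), 3 * se)
})

test_that("infected counts pass a binomial goodness-of-fit check", {
  n <- 20L; prob <- 0.4
  p <- small_field_params(n_cells = n)
  counts <- vapply(1:250, function(s) {
    generate_field(p, prob, seed = s, render = FALSE)$truth$n_infected
  }, integer(1))
  # bin the binomial support so every expected count is >= 5
  probs <- dbinom(0:n, n, prob)
  breaks <- c(-Inf, 5, 6, 7, 8, 9, 10, Inf)
  exp_p <- vapply(seq_len(length(breaks) - 1), function(i) {
    sum(probs[(0:n) > breaks[i] & (0:n) <= breaks[i + 1]])
  }, numeric(1))
  obs <- table(cut(counts, breaks))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = exp_p))
  expect_gt(gof$p.value, 0.01)
})

test_that("placement respects separation, margins and feasibility", {
  p <- small_field_params(n_cells = 30, min_separation = 20)
  tr <- generate_field(p, 0, seed = 5, render = FALSE)$truth$cells
  d <- as.matrix(dist(tr[, c("row", "col")]))
  diag(d) <- Inf
  expect_gte(min(d), 20)
  expect_true(all(tr$row >= p$border_margin &
                    tr$row <= p$field_dim[1] - p$border_margin))
  # an impossible request errors instead of spinning
  expect_error(
    generate_field(image_gen_params(field_dim = c(64L, 64L), n_cells = 200),
                   0, seed = 1, render = FALSE),
    "could not place")
})

test_that("noise parameters change pixels but never the truth", {
  quiet <- small_field_params(noise_sd = 0.005)
  loud <- small_field_params(noise_sd = 0.05)
  a <- generate_field(quiet, 0.5, seed = 9)
  b <- generate_field(loud, 0.5, seed = 9)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$image$hoechst, b$image$hoechst))
  # shot noise likewise only touches pixels
  c <- generate_field(small_field_params(shot_noise = TRUE), 0.5, seed = 9)
  expect_identical(a$truth, c$truth)
})

test_that("well fields are reproducible and independent", {
  p <- small_field_params(n_cells = 15)
  w1 <- generate_well_fields(p, 0.3, n_fields = 6, seed = 21, render = FALSE)
  w2 <- generate_well_fields(p, 0.3, n_fields = 6, seed = 21, render = FALSE)
  expect_length(w1, 6)
  expect_identical(lapply(w1, `[[`, "truth"), lapply(w2, `[[`, "truth"))
  # fields differ from one another (independent sub-seeds)
  truths <- lapply(w1, function(f) f$truth$cells)
  expect_gt(length(unique(lapply(truths, `[[`, "row"))), 1)
  expect_error(generate_well_fields(p, 0.3, n_fields = 0, seed = 1),
               "n_fields")
  # the first field of a well is the field of the derived sub-seed
  expect_length(generate_well_fields(p, 0.3, n_fields = 1, seed = 21,
                                     render = FALSE), 1)
})

test_that("fields round-trip through 16-bit TIFF and a truth CSV", {
  dir <- withr::local_tempdir()
  p <- small_field_params(n_cells = 10)
  flds <- generate_well_fields(p, 0.5, n_fields = 2, seed = 4)
  files <- write_field_images(flds, dir, plate_id = "plate01",
                              well_id = "B07")
  expect_identical(nrow(files), 4L)  # 2 fields x 2 channels
  expect_true(all(file.exists(files$path)))
  back <- EBImage::imageData(EBImage::readImage(files$path[1]))
  expect_equal(dim(back), dim(flds[[1]]$image$hoechst))
  expect_lt(max(abs(back - pmin(flds[[1]]$image$hoechst, 1))), 1e-4)
  truth <- read.csv(file.path(dir, "plate01_B07_truth.csv"))
  expect_identical(nrow(truth), 20L)
  expect_identical(sort(unique(truth$field)), c(1L, 2L))
})
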