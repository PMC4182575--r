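#' Parameters for the synthetic two-channel field generator
#'
#' Describes how a microscopic field of Hoechst-stained nuclei with a GFP
#' infection reporter is rendered. Intensities are in arbitrary linear
#' units on a roughly \[0, 1\] scale (images are written to disk as 16-bit
#' TIFF). Nuclei are radially decaying (truncated-Gaussian) disks placed
#' with a hard minimum center separation; an optional "touching" mode
#' additionally places sub-separation pairs to exercise declumping.
#'
#' @param field_dim Integer vector (rows, cols) of the field, in pixels.
#' @param n_cells Number of nuclei to place (before touching pairs).
#' @param poisson_cells If `TRUE`, the realized cell number is drawn as
#'   Poisson with mean `n_cells`.
#' @param radius_range Nucleus radius range (min, max) in pixels; each
#'   nucleus draws its radius uniformly in this range.
#' @param min_separation Minimum pairwise center separation in pixels.
#' @param border_margin Centers are kept at least this far from every
#'   border, so ground-truth nuclei are never border-truncated (matching
#'   the segmenter's default exclusion of border-touching objects).
#' @param nuclear_intensity,nuclear_sd Mean and per-cell sd of the peak
#'   Hoechst amplitude.
#' @param gfp_intensity,gfp_sd Mean and per-cell sd of the peak GFP
#'   amplitude of infected cells.
#' @param background Constant background level added to both channels.
#' @param noise_sd Standard deviation of additive Gaussian read noise.
#' @param shot_noise If `TRUE`, apply Poisson shot noise (at
#'   `shot_noise_scale` photons per intensity unit) before read noise.
#' @param shot_noise_scale Photons per intensity unit for shot noise.
#' @param touching_pairs Number of extra nucleus pairs placed closer than
#'   `min_separation` (centers one mean radius apart) so that their masks
#'   merge unless declumping is enabled.
#' @return A list of class `image_gen_params`.
#' @export
image_gen_params <- function(field_dim = c(256L, 256L),
                             n_cells = 60L,
                             poisson_cells = FALSE,
                             radius_range = c(4, 6),
                             min_separation = 16,
                             border_margin = NULL,
                             nuclear_intensity = 0.6,
                             nuclear_sd = 0.05,
                             gfp_intensity = 0.5,
                             gfp_sd = 0.05,
                             background = 0.05,
                             noise_sd = 0.01,
                             shot_noise = FALSE,
                             shot_noise_scale = 1000,
                             touching_pairs = 0L) {
  if (length(field_dim) != 2L || any(field_dim < 8))
    stop_domain("field_dim", "must be two pixel sizes >= 8")
  if (length(radius_range) != 2L || any(radius_range <= 0) ||
      radius_range[1] > radius_range[2])
    stop_domain("radius_range", "must be positive (min, max) with min <= max")
  if (any(c(nuclear_sd, gfp_sd, noise_sd) < 0))
    stop_domain("sd", "all standard deviations must be >= 0")
  if (min_separation <= 0) stop_domain("min_separation", "must be > 0")
  if (n_cells < 0) stop_domain("n_cells", "must be >= 0")
  border_margin <- border_margin %||% (max(radius_range) + 2)
  p <- list(field_dim = as.integer(field_dim), n_cells = n_cells,
            poisson_cells = poisson_cells, radius_range = radius_range,
            min_separation = min_separation, border_margin = border_margin,
            nuclear_intensity = nuclear_intensity, nuclear_sd = nuclear_sd,
            gfp_intensity = gfp_intensity, gfp_sd = gfp_sd,
            background = background, noise_sd = noise_sd,
            shot_noise = shot_noise, shot_noise_scale = shot_noise_scale,
            touching_pairs = as.integer(touching_pairs))
  class(p) <- "image_gen_params"
  p
}

# Rejection-sample n centers with pairwise distance >= min_sep, inside the
# margin. Errors after a bounded number of tries so infeasible requests
# fail loudly instead of spinning.
place_centers <- function(n, dims, margin, min_sep, max_tries = 400L * max(n, 1L)) {
  lo <- margin
  hi_r <- dims[1] - margin
  hi_c <- dims[2] - margin
  if (n > 0 && (hi_r <= lo || hi_c <= lo))
    stop("field too small for the requested border margin", call. = FALSE)
  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L; tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf(
        "could not place %d centers at separation %.1f px in a %dx%d field (placed %d)",
        n, min_sep, dims[1], dims[2], placed), call. = FALSE)
    r <- runif(1, lo, hi_r); c <- runif(1, lo, hi_c)
    if (placed == 0L ||
        min((rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c)^2) >=
          min_sep^2) {
      placed <- placed + 1L
      rows[placed] <- r; cols[placed] <- c
    }
  }
  cbind(row = rows, col = cols)
}

# Add a truncated-Gaussian disk (sigma = radius / 2, support d <= radius)
# of peak `amp` centered at (r0, c0) into matrix `img` (1-based indices).
# Overlaps combine by max, not sum: nuclei are distinct objects, and max
# combination preserves the intensity saddle between sub-separation pairs
# that distance-transform declumping relies on. At the default minimum
# separation footprints never overlap, so max and sum coincide there.
add_blob <- function(img, r0, c0, radius, amp) {
  d <- dim(img)
  rr <- max(1L, floor(r0 - radius)):min(d[1], ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(d[2], ceiling(c0 + radius))
  dist2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  sigma <- radius / 2
  blob <- amp * exp(-dist2 / (2 * sigma^2))
  blob[dist2 > radius^2] <- 0
  img[rr, cc] <- pmax(img[rr, cc], blob)
  img
}

#' Generate one synthetic two-channel field with ground truth
#'
#' Emulates a microscopic field of a monolayer infected with a
#' GFP-expressing virus: the Hoechst channel shows every nucleus, and each
#' cell is independently infected with probability `infect_prob` (the
#' single-hit Poisson dose model of [infection_probability()]); infected
#' cells carry elevated GFP over their nuclear footprint. Both channels
#' receive constant background plus Gaussian read noise (and optional
#' Poisson shot noise).
#'
#' Ground truth (placements, radii, infected flags) is drawn from a
#' sub-seed distinct from the one used for pixel noise, so changing noise
#' parameters changes pixels but never the truth, and identical
#' (params, seed) pairs reproduce the field bit-for-bit.
#'
#' @param params An [image_gen_params()] object.
#' @param infect_prob Per-cell infection probability in \[0, 1\].
#' @param seed Integer seed; the field is a pure function of
#'   (params, infect_prob, seed).
#' @param render If `FALSE`, skip pixel rendering and return `NULL`
#'   channels with the full truth (fast path for statistical checks on the
#'   truth distribution).
#' @return A list of class `synthetic_field` with elements `image` (class
#'   `field_image`: matrices `hoechst` and `gfp`, row-major, origin
#'   top-left) and `truth` (class `field_truth`: data frame `cells` with
#'   columns cell, row, col, radius, infected; counts `n_cells`,
#'   `n_infected`).
#' @examples
#' f <- generate_field(image_gen_params(n_cells = 10), infect_prob = 0.5, seed = 1)
#' f$truth$n_cells
#' @export
generate_field <- function(params = image_gen_params(), infect_prob, seed,
                           render = TRUE) {
  stopifnot(inherits(params, "image_gen_params"))
  if (!is.numeric(infect_prob) || length(infect_prob) != 1L ||
      infect_prob < 0 || infect_prob > 1)
    stop_domain("infect_prob", "must be a probability in [0, 1]")

  truth <- with_seed_if(derive_seed(seed, 1L), {
    n <- params$n_cells
    if (params$poisson_cells) n <- rpois(1, n)
    centers <- place_centers(n, params$field_dim, params$border_margin,
                             params$min_separation)
    if (params$touching_pairs > 0L) {
      # Touching pairs use an enlarged fixed radius (1.6x the max) with
      # centers 1.2 radii apart: their masks merge into one object, yet
      # the distance-transform saddle stays deep enough (> the watershed
      # tolerance at any orientation on the pixel grid) to declump.
      pr <- 1.6 * max(params$radius_range)
      gap <- 1.2 * pr
      clearance <- gap + 2 * pr
      mp <- params$border_margin + gap + pr
      d <- params$field_dim
      if (d[1] - mp <= mp || d[2] - mp <= mp)
        stop("field too small for touching pairs", call. = FALSE)
      anchors <- NULL
      tries <- 0L
      while (is.null(anchors) || nrow(anchors) < params$touching_pairs) {
        tries <- tries + 1L
        if (tries > 400L * params$touching_pairs)
          stop("could not place touching pairs at the required clearance",
               call. = FALSE)
        cand <- c(runif(1, mp, d[1] - mp), runif(1, mp, d[2] - mp))
        others <- rbind(centers, anchors)
        if (nrow(others) == 0 ||
            min((others[, 1] - cand[1])^2 + (others[, 2] - cand[2])^2) >=
              clearance^2) {
          anchors <- rbind(anchors, cand)
        }
      }
      extra <- NULL
      for (i in seq_len(params$touching_pairs)) {
        theta <- runif(1, 0, 2 * pi)
        extra <- rbind(extra,
                       anchors[i, , drop = FALSE],
                       anchors[i, ] + gap * c(cos(theta), sin(theta)))
      }
      colnames(extra) <- c("row", "col")
      centers <- rbind(centers, extra)
      n <- nrow(centers)
    }
    radius <- runif(n, params$radius_range[1], params$radius_range[2])
    if (params$touching_pairs > 0L) {
      radius[n - seq_len(2L * params$touching_pairs) + 1L] <-
        1.6 * max(params$radius_range)
    }
    infected <- runif(n) < infect_prob
    amp_nuc <- pmax(0.05, rnorm(n, params$nuclear_intensity, params$nuclear_sd))
    amp_gfp <- pmax(0.05, rnorm(n, params$gfp_intensity, params$gfp_sd))
    cells <- data.frame(cell = seq_len(n),
                        row = centers[, "row"], col = centers[, "col"],
                        radius = radius, infected = infected)
    list(cells = cells, amp_nuc = amp_nuc, amp_gfp = amp_gfp)
  })

  cells <- truth$cells
  field_truth <- structure(list(cells = cells,
                                n_cells = nrow(cells),
                                n_infected = sum(cells$infected)),
                           class = "field_truth")

  image <- NULL
  if (render) {
    d <- params$field_dim
    hoechst <- matrix(params$background, d[1], d[2])
    gfp <- matrix(params$background, d[1], d[2])
    for (i in seq_len(nrow(cells))) {
      hoechst <- add_blob(hoechst, cells$row[i], cells$col[i],
                          cells$radius[i], truth$amp_nuc[i])
      if (cells$infected[i]) {
        gfp <- add_blob(gfp, cells$row[i], cells$col[i],
                        cells$radius[i], truth$amp_gfp[i])
      }
    }
    npx <- length(hoechst)
    noisy <- with_seed_if(derive_seed(seed, 2L), {
      if (params$shot_noise) {
        s <- params$shot_noise_scale
        hoechst <- matrix(rpois(npx, hoechst * s) / s, d[1], d[2])
        gfp <- matrix(rpois(npx, gfp * s) / s, d[1], d[2])
      }
      if (params$noise_sd > 0) {
        hoechst <- hoechst + matrix(rnorm(npx, 0, params$noise_sd), d[1], d[2])
        gfp <- gfp + matrix(rnorm(npx, 0, params$noise_sd), d[1], d[2])
      }
      list(hoechst = pmax(hoechst, 0), gfp = pmax(gfp, 0))
    })
    image <- structure(noisy, class = "field_image")
  }

  structure(list(image = image, truth = field_truth),
            class = "synthetic_field")
}

#' Generate all fields of one well
#'
#' A well is imaged as `n_fields` independent microscopic fields (six in
#' the canonical automated-microscope protocol). Each field uses a
#' deterministic per-field sub-seed derived from `seed`, so any field is
#' regenerable in isolation and the whole well is reproducible.
#'
#' @inheritParams generate_field
#' @param n_fields Number of fields per well (default 6).
#' @return List of `n_fields` objects as returned by [generate_field()].
#' @export
generate_well_fields <- function(params = image_gen_params(), infect_prob,
                                 n_fields = 6L, seed, render = TRUE) {
  if (n_fields < 1) stop_domain("n_fields", "must be >= 1")
  lapply(seq_len(n_fields), function(k) {
    generate_field(params, infect_prob, seed = derive_seed(seed, 100L + k),
                   render = render)
  })
}

#' Write a well's fields to disk as 16-bit TIFFs plus a truth table
#'
#' Each channel of each field is written as a single-channel 16-bit
#' grayscale TIFF named `<plate>_<well>_f<field>_<channel>.tif`
#' (intensities clipped to \[0, 1\] then scaled to the 16-bit range), and
#' the ground truth of all fields is appended to one CSV with columns
#' plate, well, field, cell, row, col, radius, infected.
#'
#' @param fields List of `synthetic_field` objects (from
#'   [generate_well_fields()]).
#' @param dir Output directory (created if needed).
#' @param plate_id,well_id Identifiers used in file names and truth rows.
#' @return Invisibly, a data frame listing the files written.
#' @export
write_field_images <- function(fields, dir, plate_id = "P1", well_id = "A01") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- NULL
  truth_rows <- NULL
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (is.null(f$image))
      stop("fields were generated with render = FALSE; no pixels to write",
           call. = FALSE)
    for (ch in c("hoechst", "gfp")) {
      path <- file.path(dir, sprintf("%s_%s_f%d_%s.tif",
                                     plate_id, well_id, k, ch))
      EBImage::writeImage(EBImage::Image(clamp01(f$image[[ch]])), path,
                          type = "tiff", bits.per.sample = 16L)
      written <- rbind(written,
                       data.frame(plate = plate_id, well = well_id,
                                  field = k, channel = ch, path = path))
    }
    tr <- f$truth$cells
    if (nrow(tr) > 0) {
      truth_rows <- rbind(truth_rows,
                          cbind(plate = plate_id, well = well_id, field = k, tr))
    }
  }
  truth_path <- file.path(dir, sprintf("%s_%s_truth.csv", plate_id, well_id))
  write.csv(truth_rows %||%
              data.frame(plate = character(), well = character(),
                         field = integer(), cell = integer(), row = numeric(),
                         col = numeric(), radius = numeric(),
                         infected = logical()),
            truth_path, row.names = FALSE)
  invisible(written)
}
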