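#' Segmentation and classification parameters
#'
#' Settings for the nuclei-counting pipeline: threshold on the Hoechst
#' channel, hole filling, optional distance-transform watershed
#' declumping, size and border filters, and the adaptive GFP-positivity
#' rule. The recipe is the canonical nuclei stack used by high-content
#' pipelines; every knob is surfaced here because published screens rarely
#' disclose their exact settings.
#'
#' GFP positivity is per-field adaptive: a nucleus is positive when its
#' mean GFP over the (dilated) nuclear footprint exceeds the field
#' background mean by more than `gfp_k` background standard deviations,
#' where background is every pixel outside all dilated footprints. If a
#' field has no background pixels the rule falls back to the fixed
#' `gfp_fixed_threshold`.
#'
#' @param threshold_method `"otsu"` (data-adaptive, computed over the
#'   image's observed intensity range, hence invariant to affine
#'   rescaling) or `"fixed"`.
#' @param fixed_threshold Absolute Hoechst threshold used when
#'   `threshold_method = "fixed"`.
#' @param min_area,max_area Object area bounds in pixels squared.
#' @param declump Split touching nuclei by watershed on the distance
#'   transform.
#' @param watershed_tolerance,watershed_ext Watershed parameters
#'   (see [EBImage::watershed()]); the tolerance is the minimum object
#'   depth, the ext the neighborhood radius for peak detection.
#' @param exclude_border Drop objects touching the field border.
#' @param contrast_z Minimum foreground-background separation, in units of
#'   the whole-image standard deviation, for the field to count as
#'   containing nuclei at all; below it the field is reported empty with a
#'   `low_contrast` flag (guards against thresholding pure noise).
#' @param gfp_dilation GFP measurement dilation radius in pixels (0 = bare
#'   nuclear mask).
#' @param gfp_k Positivity threshold in background standard deviations.
#' @param gfp_fixed_threshold Fallback absolute GFP threshold when no
#'   background pixels exist.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(threshold_method = c("otsu", "fixed"),
                       fixed_threshold = 0.3,
                       min_area = 10,
                       max_area = 400,
                       declump = TRUE,
                       watershed_tolerance = 1,
                       watershed_ext = 1,
                       exclude_border = TRUE,
                       contrast_z = 2,
                       gfp_dilation = 1L,
                       gfp_k = 5,
                       gfp_fixed_threshold = 0.15) {
  threshold_method <- match.arg(threshold_method)
  if (min_area >= max_area) stop_domain("min_area", "must be < max_area")
  if (gfp_k <= 0) stop_domain("gfp_k", "must be > 0")
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area = min_area, max_area = max_area,
                 declump = declump,
                 watershed_tolerance = watershed_tolerance,
                 watershed_ext = watershed_ext,
                 exclude_border = exclude_border,
                 contrast_z = contrast_z,
                 gfp_dilation = as.integer(gfp_dilation),
                 gfp_k = gfp_k,
                 gfp_fixed_threshold = gfp_fixed_threshold),
            class = "seg_params")
}

empty_nuclei <- function() {
  data.frame(label = integer(), row = numeric(), col = numeric(),
             area = numeric())
}

#' Segment nuclei from the Hoechst channel
#'
#' Threshold (Otsu over the observed range, or fixed), fill holes,
#' optionally declump touching nuclei by watershed on the distance
#' transform, then remove objects outside the configured area range and
#' (by default) objects touching the border. The total cell count of a
#' field is the number of segmented nuclei.
#'
#' A constant image returns zero nuclei with a `flat_image` flag rather
#' than erroring; a field whose foreground separates from background by
#' less than `contrast_z` whole-image standard deviations (e.g. pure
#' noise) returns zero nuclei with a `low_contrast` flag.
#'
#' @param hoechst Numeric matrix of nuclear-stain intensities (row, col),
#'   origin top-left.
#' @param params A [seg_params()] object.
#' @return List of class `nuclei_seg`: `mask` (integer label matrix,
#'   labels consecutive from 1), `nuclei` (data frame label, row, col,
#'   area; centroids 1-based), `qc_flags` (character vector).
#' @export
segment_nuclei <- function(hoechst, params = seg_params()) {
  stopifnot(is.matrix(hoechst), length(hoechst) > 0)
  if (any(!is.finite(hoechst)))
    stop_domain("hoechst", "intensities must be finite")
  qc <- character()
  zero <- function(flags) {
    structure(list(mask = matrix(0L, nrow(hoechst), ncol(hoechst)),
                   nuclei = empty_nuclei(), qc_flags = flags),
              class = "nuclei_seg")
  }
  rng <- range(hoechst)
  if (diff(rng) == 0) return(zero("flat_image"))

  thr <- if (params$threshold_method == "otsu") {
    as.numeric(EBImage::otsu(EBImage::Image(hoechst), range = rng))
  } else {
    params$fixed_threshold
  }
  mask <- hoechst > thr
  if (!any(mask) || all(mask)) return(zero("low_contrast"))

  # Noise guard: Otsu always returns a threshold, even on a blank field.
  # Require real foreground/background separation before believing it.
  sep <- (mean(hoechst[mask]) - mean(hoechst[!mask])) / stats::sd(hoechst)
  if (is.na(sep) || sep < params$contrast_z) return(zero("low_contrast"))

  mimg <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- if (params$declump) {
    EBImage::watershed(EBImage::distmap(mimg),
                       tolerance = params$watershed_tolerance,
                       ext = params$watershed_ext)
  } else {
    EBImage::bwlabel(mimg)
  }
  lab <- matrix(as.integer(EBImage::imageData(lab)),
                nrow(hoechst), ncol(hoechst))

  if (max(lab) == 0L) return(zero(qc))
  areas <- tabulate(lab, nbins = max(lab))
  drop <- which(areas < params$min_area | areas > params$max_area)
  if (params$exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, setdiff(border, 0L))
  }
  keep <- setdiff(which(areas > 0), drop)
  if (length(keep) == 0L) return(zero(qc))

  relabel <- integer(max(lab))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0L] <- relabel[lab[lab > 0L]]

  idx <- which(lab > 0L)
  lv <- lab[idx]
  ri <- (idx - 1L) %% nrow(lab) + 1L
  ci <- (idx - 1L) %/% nrow(lab) + 1L
  nuclei <- data.frame(
    label = seq_along(keep),
    row = as.numeric(tapply(ri, lv, mean)),
    col = as.numeric(tapply(ci, lv, mean)),
    area = as.numeric(tabulate(lv, nbins = length(keep)))
  )
  structure(list(mask = lab, nuclei = nuclei, qc_flags = qc),
            class = "nuclei_seg")
}

#' Classify segmented nuclei as GFP-positive or -negative
#'
#' For each nucleus, mean GFP intensity is measured over its mask dilated
#' by `gfp_dilation` pixels; the field background is every pixel outside
#' all dilated masks. A nucleus is GFP-positive (infected) when its mean
#' exceeds background mean + `gfp_k` x background sd. With a fully
#' confluent mask (no background pixels) the threshold falls back to
#' `gfp_fixed_threshold` and a `no_background` flag is set.
#'
#' @param seg A `nuclei_seg` object from [segment_nuclei()].
#' @param gfp Numeric matrix of GFP intensities, same dimensions as the
#'   segmented Hoechst channel.
#' @param params A [seg_params()] object.
#' @return `seg` with `nuclei` gaining columns `mean_gfp` and
#'   `gfp_positive`, plus `gfp_threshold` and possibly updated `qc_flags`.
#' @export
classify_infected <- function(seg, gfp, params = seg_params()) {
  stopifnot(inherits(seg, "nuclei_seg"), is.matrix(gfp))
  if (!all(dim(gfp) == dim(seg$mask)))
    stop("gfp and segmentation mask dimensions differ", call. = FALSE)
  nuc <- seg$nuclei
  if (nrow(nuc) == 0L) {
    seg$nuclei <- cbind(nuc, mean_gfp = numeric(0), gfp_positive = logical(0))
    return(seg)
  }
  lab <- seg$mask
  if (params$gfp_dilation > 0L) {
    brush <- EBImage::makeBrush(2L * params$gfp_dilation + 1L, shape = "disc")
    # Greyscale dilation propagates the (positive) labels outward; where
    # dilated footprints would collide the larger label wins, which is
    # immaterial at the generator's default center separation.
    lab <- matrix(as.integer(EBImage::imageData(
      EBImage::dilate(EBImage::Image(lab), brush))), nrow(lab), ncol(lab))
  }
  bg <- gfp[lab == 0L]
  if (length(bg) == 0L) {
    thr <- params$gfp_fixed_threshold
    seg$qc_flags <- union(seg$qc_flags, "no_background")
  } else {
    thr <- mean(bg) + params$gfp_k * stats::sd(bg)
  }
  idx <- which(lab > 0L)
  mean_gfp <- as.numeric(tapply(gfp[idx], lab[idx], mean))
  present <- sort(unique(lab[idx]))
  mg <- rep(NA_real_, nrow(nuc))
  mg[match(present, nuc$label)] <- mean_gfp
  nuc$mean_gfp <- mg
  nuc$gfp_positive <- !is.na(mg) & mg > thr
  seg$nuclei <- nuc
  seg$gfp_threshold <- thr
  seg
}

#' Analyze one field: segment, classify, and summarize
#'
#' Convenience wrapper running [segment_nuclei()] and
#' [classify_infected()] and packaging the per-field result.
#'
#' @param image A `field_image` (list with `hoechst` and `gfp` matrices)
#'   or any list with those elements.
#' @param params A [seg_params()] object.
#' @return A `field_result` list: `n_cells`, `n_gfp_positive`,
#'   `efficiency` (NA with an `empty_field` flag when no cells), `nuclei`
#'   data frame, `qc_flags`.
#' @export
analyze_field <- function(image, params = seg_params()) {
  seg <- segment_nuclei(image$hoechst, params)
  seg <- classify_infected(seg, image$gfp, params)
  field_result(n_cells = nrow(seg$nuclei),
               n_gfp_positive = sum(seg$nuclei$gfp_positive),
               nuclei = seg$nuclei, qc_flags = seg$qc_flags)
}

#' Construct a per-field result
#'
#' @param n_cells,n_gfp_positive Counts of segmented nuclei and of
#'   GFP-positive nuclei.
#' @param nuclei Optional per-nucleus data frame.
#' @param qc_flags Character vector of QC flags.
#' @return A `field_result` list with `efficiency = n_gfp_positive /
#'   n_cells` (NA plus an `empty_field` flag when `n_cells` is 0).
#' @export
field_result <- function(n_cells, n_gfp_positive, nuclei = NULL,
                         qc_flags = character()) {
  if (n_gfp_positive > n_cells)
    stop("n_gfp_positive exceeds n_cells", call. = FALSE)
  if (n_cells > 0) {
    eff <- n_gfp_positive / n_cells
  } else {
    eff <- NA_real_
    qc_flags <- union(qc_flags, "empty_field")
  }
  structure(list(n_cells = n_cells, n_gfp_positive = n_gfp_positive,
                 efficiency = eff, nuclei = nuclei, qc_flags = qc_flags),
            class = "field_result")
}

#' Per-field infection efficiency
#'
#' The fraction of segmented cells that are GFP-positive.
#'
#' @param field A `field_result`.
#' @return Efficiency in \[0, 1\].
#' @export
field_efficiency <- function(field) {
  stopifnot(inherits(field, "field_result"))
  if (field$n_cells == 0)
    stop("efficiency undefined for an empty field (qc: empty_field)",
         call. = FALSE)
  field$efficiency
}

#' Aggregate a well's fields into one infection efficiency
#'
#' The well efficiency is the unweighted mean of per-field efficiencies
#' over fields with at least one cell - the convention of averaging the
#' per-image percentages rather than pooling counts. The pooled-count
#' estimator (total positives / total cells) is also returned for
#' comparison; the two differ when field cell densities are unequal.
#'
#' @param fields List of `field_result` objects (one well).
#' @param min_valid_fields Minimum number of non-empty fields before a
#'   `few_fields` flag is raised (default 3).
#' @return List of class `well_result`: `efficiency` (mean of field
#'   percentages), `pooled_efficiency`, `cell_count` (total over all
#'   fields), `n_valid_fields`, `valid` (FALSE when no field had cells),
#'   `qc_flags`.
#' @export
well_efficiency <- function(fields, min_valid_fields = 3L) {
  stopifnot(length(fields) >= 1)
  effs <- vapply(fields, function(f) f$efficiency, numeric(1))
  ncells <- vapply(fields, function(f) as.numeric(f$n_cells), numeric(1))
  npos <- vapply(fields, function(f) as.numeric(f$n_gfp_positive), numeric(1))
  ok <- !is.na(effs)
  qc <- unique(unlist(lapply(fields, function(f) f$qc_flags)))
  if (sum(ok) < min_valid_fields) qc <- union(qc, "few_fields")
  valid <- any(ok)
  structure(list(
    efficiency = if (valid) mean(effs[ok]) else NA_real_,
    pooled_efficiency = if (valid) sum(npos[ok]) / sum(ncells[ok]) else NA_real_,
    cell_count = sum(ncells),
    n_valid_fields = sum(ok),
    valid = valid,
    qc_flags = qc
  ), class = "well_result")
}

#' Match segmented nuclei against generator ground truth
#'
#' Greedy nearest-neighbor matching within `max_dist` pixels; each truth
#' cell is claimed by at most one segmented nucleus. Used to benchmark
#' segmentation recall/precision on synthetic fields.
#'
#' @param nuclei Data frame with `row`, `col` (from [segment_nuclei()]).
#' @param truth A `field_truth` (from [generate_field()]).
#' @param max_dist Maximum centroid distance in pixels for a match.
#' @return List: `n_matched`, `recall`, `precision`, `mean_dist`.
#' @export
match_truth <- function(nuclei, truth, max_dist = 2) {
  tc <- truth$cells
  if (nrow(tc) == 0 || nrow(nuclei) == 0) {
    return(list(n_matched = 0L,
                recall = if (nrow(tc) == 0) NA_real_ else 0,
                precision = if (nrow(nuclei) == 0) NA_real_ else 0,
                mean_dist = NA_real_))
  }
  d <- outer(nuclei$row, tc$row, "-")^2 + outer(nuclei$col, tc$col, "-")^2
  d <- sqrt(d)
  matched_t <- logical(nrow(tc))
  matched_n <- logical(nrow(nuclei))
  dists <- numeric(0)
  repeat {
    m <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
    if (d[m] > max_dist) break
    dists <- c(dists, d[m])
    matched_n[m[1]] <- TRUE
    matched_t[m[2]] <- TRUE
    d[m[1], ] <- Inf
    d[, m[2]] <- Inf
    if (all(is.infinite(d))) break
  }
  list(n_matched = sum(matched_t),
       recall = sum(matched_t) / nrow(tc),
       precision = sum(matched_n) / nrow(nuclei),
       mean_dist = if (length(dists)) mean(dists) else NA_real_)
}
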