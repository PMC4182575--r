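WELL_ID_PATTERN <- "^[A-P][0-9]{2}$"
PLATE_MAP_COLS <- c("plate_id", "well_id", "role", "shrna_id", "gene_id")
WELL_TABLE_COLS <- c(PLATE_MAP_COLS, "efficiency", "cell_count")

read_screen_csv <- function(path, required, lax = FALSE, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, colClasses = NA, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s %s lacks required column(s): %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(df), required)
  if (length(extra) && !lax)
    stop(sprintf("%s %s has unknown column(s): %s (use lax = TRUE to keep)",
                 what, path, paste(extra, collapse = ", ")), call. = FALSE)
  df[required]
}

validate_plate_map <- function(map, path = "<plate map>") {
  line <- seq_len(nrow(map)) + 1L  # +1 for the header
  probs <- character()
  key <- paste(map$plate_id, map$well_id)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup & duplicated(key)))
    probs <- c(probs, sprintf("duplicate (plate_id, well_id) at line(s) %s",
                              paste(line[duplicated(key)], collapse = ", ")))
  badw <- !grepl(WELL_ID_PATTERN, map$well_id)
  if (any(badw))
    probs <- c(probs, sprintf("malformed well_id at line(s) %s",
                              paste(line[badw], collapse = ", ")))
  badr <- !map$role %in% c("neg_control", "pos_control", "test")
  if (any(badr))
    probs <- c(probs, sprintf("invalid role at line(s) %s",
                              paste(line[badr], collapse = ", ")))
  noid <- map$role == "test" &
    (is.na(map$shrna_id) | map$shrna_id == "" |
       is.na(map$gene_id) | map$gene_id == "")
  if (any(noid))
    probs <- c(probs, sprintf("test well without shrna_id/gene_id at line(s) %s",
                              paste(line[noid], collapse = ", ")))
  if (length(probs))
    stop(sprintf("invalid plate map %s:\n  %s", path,
                 paste(probs, collapse = "\n  ")), call. = FALSE)
  invisible(map)
}

#' Read and validate a plate map CSV
#'
#' A plate map assigns each well of each plate a role (negative control,
#' positive control, or test) and, for test wells, the hairpin and gene
#' identity. Columns: plate_id, well_id (letter + two-digit column, e.g.
#' "B07"), role, shrna_id, gene_id. Duplicate (plate, well) pairs,
#' malformed well ids, invalid roles, and test wells missing identities
#' are rejected with the offending line numbers.
#'
#' @param path CSV path.
#' @param lax Keep unknown columns instead of erroring.
#' @return A validated data frame of class `plate_map`.
#' @export
read_plate_map <- function(path, lax = FALSE) {
  map <- read_screen_csv(path, PLATE_MAP_COLS, lax = lax, what = "plate map")
  for (col in c("shrna_id", "gene_id")) map[[col]][is.na(map[[col]])] <- ""
  validate_plate_map(map, path)
  class(map) <- c("plate_map", "data.frame")
  map
}

#' Write a plate map CSV
#'
#' @param map Plate map data frame (validated before writing).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_plate_map <- function(map, path) {
  validate_plate_map(map[PLATE_MAP_COLS])
  write.csv(map[PLATE_MAP_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-well measurement table CSV
#'
#' Columns: plate_id, well_id, role, shrna_id, gene_id, efficiency
#' (fraction in \[0, 1\] or empty for invalid wells), cell_count.
#'
#' @inheritParams read_plate_map
#' @return Data frame with a `valid` column (`TRUE` where efficiency is
#'   present).
#' @export
read_well_table <- function(path, lax = FALSE) {
  df <- read_screen_csv(path, WELL_TABLE_COLS, lax = lax,
                        what = "well table")
  for (col in c("shrna_id", "gene_id")) df[[col]][is.na(df[[col]])] <- ""
  if (any(df$efficiency < 0 | df$efficiency > 1, na.rm = TRUE))
    stop("efficiencies must be fractions in [0, 1]", call. = FALSE)
  df$valid <- !is.na(df$efficiency)
  df
}

#' Write a per-well measurement table CSV
#'
#' @param wells Wells data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_well_table <- function(wells, path) {
  write.csv(wells[WELL_TABLE_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' The configuration nests sections `design` (arguments to
#' [screen_design()]), `seg` ([seg_params()]), `hit` ([hit_params()]) and
#' `seed`. Unknown argument names inside a section are rejected.
#'
#' @param path YAML (or JSON, a YAML subset) file.
#' @return List of class `run_config` with instantiated parameter
#'   objects and `seed`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(section, fn, fname) {
    args <- raw[[section]] %||% list()
    unknown <- setdiff(names(args), names(formals(fn)))
    if (length(unknown))
      stop(sprintf("config section `%s` has unknown field(s): %s",
                   section, paste(unknown, collapse = ", ")), call. = FALSE)
    do.call(fn, args)
  }
  structure(list(design = build("design", screen_design),
                 seg = build("seg", seg_params),
                 hit = build("hit", hit_params),
                 seed = as.integer(raw$seed %||% 1L)),
            class = "run_config")
}

config_hash <- function(config) {
  rlang::hash(lapply(unclass(config), unclass))
}

#' Run the screening pipeline end to end
#'
#' Executes the stages of an arrayed screen in order - obtain per-well
#' efficiencies (simulated at the well level, measured from simulated
#' images, or read from a CSV), range-normalize each plate, pool and
#' Z-score against the negative-control null, flag exclusions, call
#' shRNA and gene hits - and writes the four artifact tables plus a run
#' log into `out_dir`: `wells.csv`, `scores.csv`, `gene_calls.csv`,
#' `ranked.csv`, `run_log.txt`. Every output is stamped with the config
#' hash and seed, and a rerun with the same config and seed is
#' bit-identical.
#'
#' @param config A `run_config` (from [read_run_config()]) or a list with
#'   elements `design`, `hit`, `seed`.
#' @param out_dir Output directory (created if needed).
#' @param wells Optional pre-computed wells data frame or CSV path; when
#'   supplied the simulation stage is skipped.
#' @param mode `"wells"` (well-level simulation) or `"images"` (render
#'   fields for every well, segment them, and measure efficiencies; far
#'   slower, intended for small designs).
#' @param n_fields Fields per well in image mode.
#' @param image_params [image_gen_params()] for image mode.
#' @param expression_table Optional expression annotation (see
#'   [flag_exclusions()]).
#' @return Invisibly, a list with `scores`, `gene_calls`, `ranked`,
#'   `wells`, `truth` (NULL when wells were supplied), and `files`.
#' @export
run_pipeline <- function(config, out_dir, wells = NULL,
                         mode = c("wells", "images"), n_fields = 6L,
                         image_params = image_gen_params(),
                         expression_table = NULL) {
  mode <- match.arg(mode)
  stopifnot(!is.null(config$design), !is.null(config$hit))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_lines <- c(sprintf("hcscreen pipeline run"),
                 sprintf("config_hash: %s", config_hash(config)),
                 sprintf("seed: %d", config$seed))
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %s: %.2fs", name,
                                       as.numeric(Sys.time() - ts,
                                                  units = "secs")))
    res
  }

  truth <- NULL
  if (is.character(wells)) wells <- read_well_table(wells)
  if (is.null(wells)) {
    if (mode == "wells") {
      sim <- stage("simulate_wells",
                   simulate_screen(config$design, seed = config$seed))
      wells <- sim$wells
      truth <- sim$truth
    } else {
      sim <- stage("simulate_wells",
                   simulate_screen(config$design, seed = config$seed))
      truth <- sim$truth
      wells <- stage("simulate_and_segment_images", {
        w <- sim$wells
        for (i in seq_len(nrow(w))) {
          flds <- generate_well_fields(image_params, clamp01(w$efficiency[i]),
                                       n_fields = n_fields,
                                       seed = derive_seed(config$seed, 500L, i))
          res <- lapply(flds, function(f)
            analyze_field(f$image, config$seg %||% seg_params()))
          wr <- well_efficiency(res)
          w$efficiency[i] <- wr$efficiency
          w$cell_count[i] <- wr$cell_count
          w$valid[i] <- wr$valid
        }
        w
      })
    }
  }

  result <- stage("score",
                  score_screen(wells, config$hit, expression_table))

  files <- c(wells = file.path(out_dir, "wells.csv"),
             scores = file.path(out_dir, "scores.csv"),
             gene_calls = file.path(out_dir, "gene_calls.csv"),
             ranked = file.path(out_dir, "ranked.csv"),
             log = file.path(out_dir, "run_log.txt"))
  stamp <- sprintf("# config_hash=%s seed=%d", config_hash(config),
                   config$seed)
  write_stamped <- function(df, path) {
    con <- file(path, "w")
    writeLines(stamp, con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }
  stage("write_artifacts", {
    write_stamped(wells[intersect(WELL_TABLE_COLS, names(wells))],
                  files[["wells"]])
    write_stamped(result$scores, files[["scores"]])
    write_stamped(result$gene_calls, files[["gene_calls"]])
    write_stamped(result$ranked, files[["ranked"]])
  })
  log_lines <- c(log_lines, sprintf("total: %.2fs",
                                    as.numeric(Sys.time() - t0,
                                               units = "secs")))
  writeLines(log_lines, files[["log"]])
  invisible(list(scores = result$scores, gene_calls = result$gene_calls,
                 ranked = result$ranked, wells = wells, truth = truth,
                 files = files))
}

#' Read a stamped pipeline CSV back
#'
#' Pipeline artifacts begin with a `# config_hash=... seed=...` comment
#' line; this reads one back as a data frame.
#'
#' @param path CSV path written by [run_pipeline()].
#' @return Data frame.
#' @export
read_stamped_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
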