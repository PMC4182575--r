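# Compact fixtures used across tests: smaller fields and a one-plate
# screen keep the suite fast while exercising the same code paths as the
# full-size defaults.

small_field_params <- function(...) {
  args <- utils::modifyList(list(field_dim = c(192L, 192L), n_cells = 40L),
                            list(...))
  do.call(image_gen_params, args)
}

# 96-well single-plate design: 6 + 6 controls and 84 test hairpins.
one_plate_design <- function(...) {
  screen_design(n_genes = 20L, n_shrnas = 84L, n_positive_genes = 0L, ...)
}

# Hand-built plate for normalization arithmetic: controls at stated
# efficiencies plus explicit test wells.
manual_plate <- function(neg, pos, test, plate_id = "p1") {
  eff <- c(neg, pos, test)
  data.frame(
    plate_id = plate_id,
    well_id = sprintf("%s%02d", rep(LETTERS[1:8], each = 12),
                      1:12)[seq_along(eff)],
    role = c(rep("neg_control", length(neg)),
             rep("pos_control", length(pos)),
             rep("test", length(test))),
    shrna_id = c(rep("", length(neg) + length(pos)),
                 sprintf("sh%02d", seq_along(test))),
    gene_id = c(rep("", length(neg) + length(pos)),
                sprintf("g%02d", seq_along(test))),
    efficiency = eff,
    cell_count = 2000L,
    valid = TRUE
  )
}
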