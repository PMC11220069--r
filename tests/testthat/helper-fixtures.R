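# Fixture helpers: records are built in code, never stored.

# Minimal record list for direct calls to total_cell_calcite()
make_record <- function(record_id = "r1", cl = NA, cn = NA, visible = NA,
                        d = NA, h = NA, cw = NA, spine = NA, n_xc = 0,
                        xc_len = NA, n_app = NA, app_present = NA,
                        loose = 0, partial = FALSE, layers = 1) {
  list(record_id = record_id, coccolith_length_um = cl,
       total_coccolith_count = cn, visible_coccolith_count = visible,
       coccosphere_short_axis_um = d, coccosphere_long_axis_um = h,
       coccolith_width_um = cw, process_height_um = spine,
       n_exothecal = n_xc, exothecal_length_um = xc_len,
       n_appendages = n_app, appendages_present = app_present,
       loose_adjacent_count = loose, partial_length_flag = partial,
       n_layers = layers)
}

# One-row record data frame in the machine schema for the pipeline
make_record_df <- function(genus, species = NA, morpho_group = NA,
                           phase = "heterococcolith", ...) {
  rec <- make_record(...)
  base <- list(record_id = rec$record_id, station = "T1", water_depth_m = 10,
               image_id = "img1", family = NA_character_, genus = genus,
               species = species, morpho_group = morpho_group,
               life_cycle_phase = phase, notes = NA_character_)
  as.data.frame(c(base, rec[setdiff(names(rec), "record_id")]),
                stringsAsFactors = FALSE)
}

write_measurement_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
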