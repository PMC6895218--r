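# shared fixture builders; everything is generated in code

# a hand-made rendered field (bypasses the packer) for grid-count tests
make_field <- function(profiles, width = 1400, height = 1300) {
  structure(profiles, field_width = width, field_height = height,
            class = c("ovary_field", "data.frame"))
}

# measurement rows with equal axes (spherical oocytes)
sphere_measurements <- function(stage, od, female_id = "F1",
                                through_nucleus = TRUE) {
  data.frame(female_id = female_id, stage = stage, L_um = od, S_um = od,
             through_nucleus = through_nucleus, stringsAsFactors = FALSE)
}

# grid counts for one field from a named hit vector (adds n_points)
counts_row <- function(field_id, hits) {
  data.frame(field_id = field_id, component = names(hits),
             hits = as.integer(hits), n_points = sum(hits),
             stringsAsFactors = FALSE)
}

# per-stage oocyte numbers that reproduce a reference-table cell:
# NO_m = (PF_m - PF_{m-1}) / 2 along the cumulative ladder
reference_cell_nos <- function(ref, class, season) {
  cell <- ref[ref$tl_class == class & ref$season == season, ]
  cell <- cell[match(cumulative_stage_labels(), cell$stage_label), ]
  no <- diff(c(0, cell$pf_thousands)) / 2
  names(no) <- accumulation_order()
  list(no = no, bf = cell$bf_thousands[1], batches = cell$batches,
       duration = cell$duration_months, pf = cell$pf_thousands)
}
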