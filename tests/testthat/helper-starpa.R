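# shared builders for the test suite

grk_targets <- c("anti-GRK2" = "GRK2", "anti-GRK3" = "GRK3",
                 "anti-GRK5" = "GRK5", "anti-GRK6" = "GRK6")

# two-isoform toy world used by the forward-model unit tests
toy_panel <- function() isoform_panel(c("a", "b"))

toy_antibody <- function(affinity = 2, cross_b = 0.33) {
  antibody_model("ab-a", "a", affinity = affinity,
                 cross_reactivity = c(b = cross_b))
}

toy_sample <- function(a = 0.5, b = 0.25, dilution = 1) {
  lysate_sample("U", c(a = a, b = b), dilution_factor = dilution)
}

toy_scenario <- function(..., antibodies = list(toy_antibody()),
                         samples = list(toy_sample())) {
  blot_scenario(toy_panel(), antibodies, samples, ...)
}

# hand-built standard-lane table for the cross-reactivity estimator:
# one blot, antibody x standard densities given as a named matrix
standard_lane_table <- function(dens, blot = "blot_1") {
  rows <- expand.grid(antibody_id = rownames(dens),
                      standard_isoform = colnames(dens),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    blot_id = blot,
    lane = seq_len(nrow(rows)),
    antibody_id = rows$antibody_id,
    sample_id = paste0("S-", rows$standard_isoform),
    sample_role = "standard",
    standard_isoform = rows$standard_isoform,
    dilution_factor = 1,
    density = dens[cbind(rows$antibody_id, rows$standard_isoform)]
  )
}
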