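# Shared in-code fixtures: a minimal single-species parameter set with round
# numbers so expected budgets are hand-computable, and a tiny survey builder.

toy_params <- function(sink_mode = "length_increment") {
  species_parameters(
    species = "toy", zone = "shallow",
    length_model = power_law(1, 1),                    # length == height
    afdm = linear_density(1000, 0, "mg_AFDM_per_cm"),  # 1 g per cm
    polyps_per_cm = linear_density(10, 0, "polyps_per_cm"),
    zooplankton_rate = 2, zooplankton_timebase = "per_day",  # ug C polyp-1 d-1
    respiration_rate = 1, respiration_timebase = "per_hour",
    growth_cm_yr = 1,
    c_content = linear_density(5, 0, "mg_C_per_cm"),
    sink_mode = sink_mode
  )
}

toy_params_set <- function(...) {
  p <- toy_params(...)
  stats::setNames(list(p), "toy.shallow")
}

toy_survey <- function(heights, depths = rep(20, length(heights)),
                       species = "toy", unit = "u1") {
  tibble::tibble(
    species = species, height_cm = heights, depth_m = depths,
    transect = "t1", sampling_unit = unit, assemblage = "a1"
  )
}
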