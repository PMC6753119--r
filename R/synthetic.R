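#' Configuration for the synthetic survey generator
#'
#' Describes a virtual ROV survey: transects split into fixed-area sampling
#' units, each unit assigned to a benthic assemblage; per species and zone, a
#' patchy colony count process (zero-inflated negative binomial: occupancy
#' times an overdispersed count) and a right-skewed height distribution
#' (lognormal truncated at a maximum height). Defaults emulate a
#' Mediterranean gorgonian survey: tens-of-cm colonies, strong patchiness so
#' that on-patch densities far exceed total densities, and a shallow/deep
#' split at 35 m.
#'
#' @param n_transects Number of transects.
#' @param units_per_transect Sampling units per transect.
#' @param unit_area_m2 Sampling-unit area (m2).
#' @param species Tibble-like list of per-species settings; see defaults.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_transects = 20, units_per_transect = 25,
                             unit_area_m2 = 1,
                             species = NULL) {
  if (is.null(species)) {
    species <- tibble::tribble(
      ~species, ~zone, ~occupancy, ~mean_count, ~dispersion,
      ~height_meanlog, ~height_sdlog, ~max_height_cm,
      "P_clavata", "shallow", 0.12, 6, 0.8, log(20), 0.5, 80,
      "P_clavata", "deep", 0.20, 5, 0.8, log(25), 0.5, 90,
      "E_singularis", "shallow", 0.45, 5, 1.0, log(18), 0.45, 60,
      "E_singularis", "deep", 0.55, 8, 1.0, log(16), 0.45, 55,
      "L_sarmentosa", "shallow", 0.03, 1.5, 1.5, log(15), 0.5, 50,
      "L_sarmentosa", "deep", 0.05, 1.5, 1.5, log(15), 0.5, 50
    )
  }
  stopifnot(all(species$occupancy >= 0 & species$occupancy <= 1),
            all(species$dispersion > 0), all(species$mean_count >= 0),
            n_transects >= 1, units_per_transect >= 1, unit_area_m2 > 0)
  structure(list(n_transects = n_transects,
                 units_per_transect = units_per_transect,
                 unit_area_m2 = unit_area_m2, species = species),
            class = "generator_config")
}

# truncated lognormal heights by rejection; cheap at survey sizes
r_trunc_lnorm <- function(n, meanlog, sdlog, max_value) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rlnorm(n, meanlog, sdlog)
    out <- c(out, draw[draw < max_value])
  }
  out[seq_len(n)]
}

#' Generate a synthetic colony survey with known ground truth
#'
#' Transects alternate between a shallow and a deep assemblage; within each
#' sampling unit, per-species colony counts follow a zero-inflated negative
#' binomial and heights a truncated lognormal. With the supplied parameter
#' set, the generator also records the exact per-compartment budget of the
#' realized colonies (the ground truth a pipeline run must reproduce).
#'
#' @param config A [generator_config()].
#' @param params_set Optional named [species_parameters()] list used to
#'   compute the ground-truth budget (e.g. [calibrated_parameters()]).
#' @param seed Integer seed; the draw is fully reproducible given the seed.
#' @param constants [conversion_constants()].
#' @return List with `survey` (colony tibble), `units` (all sampling units
#'   with per-species counts), `truth` (per-compartment budget tibble or
#'   `NULL`), and `seed`.
#' @export
generate_survey <- function(config, params_set = NULL, seed = 1,
                            constants = conversion_constants()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  shallow_assemblage <- "vertical_coralligenous"
  deep_assemblage <- "platform_coralligenous"
  unit_rows <- list()
  colony_rows <- list()
  for (t in seq_len(config$n_transects)) {
    zone_t <- if (t %% 2 == 1) "shallow" else "deep"
    assemblage <- if (zone_t == "shallow") shallow_assemblage else deep_assemblage
    depth_range <- if (zone_t == "shallow") c(10, 35) else c(36, 60)
    for (u in seq_len(config$units_per_transect)) {
      unit_id <- sprintf("t%02d_u%02d", t, u)
      depth <- stats::runif(1, depth_range[1], depth_range[2])
      for (i in seq_len(nrow(config$species))) {
        sp <- config$species[i, ]
        if (sp$zone != zone_t) next
        occupied <- stats::rbinom(1, 1, sp$occupancy)
        count <- if (occupied == 1) {
          stats::rnbinom(1, mu = sp$mean_count, size = sp$dispersion)
        } else 0L
        unit_rows[[length(unit_rows) + 1L]] <- tibble::tibble(
          sampling_unit = unit_id, transect = sprintf("t%02d", t),
          assemblage = assemblage, zone = zone_t,
          area_m2 = config$unit_area_m2, species = sp$species, count = count
        )
        if (count > 0) {
          h <- r_trunc_lnorm(count, sp$height_meanlog, sp$height_sdlog,
                             sp$max_height_cm)
          colony_rows[[length(colony_rows) + 1L]] <- tibble::tibble(
            species = sp$species, height_cm = h, depth_m = depth,
            transect = sprintf("t%02d", t), sampling_unit = unit_id,
            assemblage = assemblage
          )
        }
      }
    }
  }
  units <- dplyr::bind_rows(unit_rows)
  survey <- if (length(colony_rows) > 0) {
    dplyr::bind_rows(colony_rows)
  } else {
    tibble::tibble(species = character(), height_cm = numeric(),
                   depth_m = numeric(), transect = character(),
                   sampling_unit = character(), assemblage = character())
  }
  truth <- NULL
  if (!is.null(params_set) && nrow(survey) > 0) {
    truth <- aggregate_budget(
      colony_budget(survey, params_set, constants),
      season_days = constants$season_days
    )
  }
  list(survey = survey, units = units, truth = truth, seed = seed)
}

#' Generate noisy height-response measurement pairs
#'
#' Stands in for digitized colony photographs: heights drawn uniformly over
#' a size range, responses from a known power law with multiplicative
#' lognormal noise. At `noise_sd = 0` the pairs lie exactly on the law.
#'
#' @param model True [power_law()].
#' @param n Number of pairs (>= 3).
#' @param noise_sd SD of the lognormal noise on the log scale.
#' @param seed Integer seed.
#' @param height_range Range heights are drawn from (cm).
#' @return Tibble with `height_cm`, `response_value`, `response`.
#' @export
generate_measurement_pairs <- function(model, n, noise_sd = 0, seed = 1,
                                       height_range = c(5, 50)) {
  if (n < 3L) {
    stop("generate_measurement_pairs: need n >= 3", call. = FALSE)
  }
  if (noise_sd < 0) {
    stop("generate_measurement_pairs: noise_sd must be >= 0", call. = FALSE)
  }
  set.seed(seed)
  h <- stats::runif(n, height_range[1], height_range[2])
  y <- evaluate_power_law(model, h) * exp(stats::rnorm(n, 0, noise_sd))
  tibble::tibble(height_cm = h, response_value = y, response = model$response)
}
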