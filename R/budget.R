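#' Daily carbon ingestion of a colony
#'
#' Sums the configured ingestion channels for colonies of given heights:
#' zooplankton capture (per polyp), seston feeding on micro-/nano-plankton
#' and detrital POM (per g AFDM), and, for mixotrophs, the autotrophic input
#' of the symbionts (per cm2 of colony surface). All channels are converted
#' to a per-day base and from ug C to g C.
#'
#' @param params A [species_parameters()] object.
#' @param height_cm Colony heights (cm); vectorized.
#' @return Daily ingestion (g C d-1).
#' @export
colony_ingestion <- function(params, height_cm) {
  len <- evaluate_power_law(params$length_model, height_cm)
  total <- numeric(length(height_cm))
  if (!is.null(params$zooplankton_rate)) {
    polyps <-
      if (!is.null(params$polyps_per_cm)) {
        length_to_polyps(len, params$polyps_per_cm)
      } else if (!is.null(params$polyp_table)) {
        height_to_polyps_by_class(height_cm, params$polyp_table)
      } else {
        stop("colony_ingestion: zooplankton channel configured without a ",
             "polyp conversion for species ", params$species, call. = FALSE)
      }
    rate <- normalize_rate_timebase(params$zooplankton_rate,
                                    params$zooplankton_timebase, "per_day")
    total <- total + rate * polyps / 1e6
  }
  if (!is.null(params$seston_rate)) {
    afdm_g <- length_to_afdm(len, params$afdm)
    rate <- normalize_rate_timebase(params$seston_rate,
                                    params$seston_timebase, "per_day")
    total <- total + rate * afdm_g / 1e6
  }
  if (!is.null(params$autotrophic_rate)) {
    if (is.null(params$area_model)) {
      stop("colony_ingestion: autotrophic channel configured without a ",
           "height-area model for species ", params$species, call. = FALSE)
    }
    area <- evaluate_power_law(params$area_model, height_cm)
    rate <- normalize_rate_timebase(params$autotrophic_rate,
                                    params$autotrophic_timebase, "per_day")
    total <- total + rate * area / 1e6
  }
  if (is.null(params$zooplankton_rate) && is.null(params$seston_rate) &&
      is.null(params$autotrophic_rate)) {
    stop("colony_ingestion: no ingestion channel configured for species ",
         params$species, call. = FALSE)
  }
  total
}

#' Daily carbon respiration of a colony
#'
#' Oxygen consumption per g AFDM, converted to a per-day base and to
#' respired carbon via the O2-to-C factor:
#' `rate (mg O2 g-1) * AFDM (g) * o2_to_c / 1000 -> g C d-1`.
#'
#' @inheritParams colony_ingestion
#' @param constants [conversion_constants()].
#' @return Daily respiration (g C d-1).
#' @export
colony_respiration <- function(params, height_cm,
                               constants = conversion_constants()) {
  if (is.null(params$respiration_rate)) {
    stop("colony_respiration: no respiration rate configured for species ",
         params$species, call. = FALSE)
  }
  len <- evaluate_power_law(params$length_model, height_cm)
  afdm_g <- length_to_afdm(len, params$afdm)
  rate <- normalize_rate_timebase(params$respiration_rate,
                                  params$respiration_timebase, "per_day")
  o2_to_carbon(rate * afdm_g, constants$o2_to_c) / 1000
}

#' Net daily carbon flux
#'
#' Ingested minus respired carbon; the benthic-pelagic coupling quantity.
#' May be negative outside the productive season (a warning is emitted).
#'
#' @param ingestion,respiration Daily totals (g C d-1), >= 0.
#' @return Net flux (g C d-1).
#' @export
net_flux <- function(ingestion, respiration) {
  if (any(ingestion < 0) || any(respiration < 0)) {
    stop("net_flux: ingestion and respiration must be >= 0", call. = FALSE)
  }
  out <- ingestion - respiration
  if (any(out < 0)) {
    warning("net_flux: respiration exceeds ingestion for some entries",
            call. = FALSE)
  }
  out
}

#' Seasonal carbon flux
#'
#' @param daily_net Net daily flux (g C d-1).
#' @param season_days Season length in days (default 90, spring).
#' @return Seasonal flux (g C per season).
#' @export
seasonal_flux <- function(daily_net, season_days = 90) {
  if (season_days <= 0) stop("seasonal_flux: season_days must be > 0",
                             call. = FALSE)
  daily_net * season_days
}

#' Annual carbon sink of a colony
#'
#' Carbon immobilized in new tissue and skeleton over a year, by the
#' species' configured `sink_mode`:
#' \describe{
#'   \item{length_increment}{annual height growth -> length increment via the
#'     power law, times C content per cm.}
#'   \item{per_size_class_table}{published annual C investment per colony
#'     for the colony's height class (half-open classes, clamped ends).}
#'   \item{effective_biomass}{back-solved mg C g AFDM-1 yr-1 times colony
#'     AFDM.}
#' }
#'
#' @inheritParams colony_ingestion
#' @return Annual sink (g C yr-1).
#' @export
colony_sink <- function(params, height_cm) {
  switch(params$sink_mode,
    length_increment = {
      if (is.null(params$growth_cm_yr) || is.null(params$c_content)) {
        stop("colony_sink: length_increment mode needs growth_cm_yr and ",
             "c_content for species ", params$species, call. = FALSE)
      }
      check_units(params$c_content, "mg_C_per_cm", "colony_sink")
      dlen <- growth_to_length_increment(params$length_model, height_cm,
                                         params$growth_cm_yr)
      dlen * params$c_content$mean / 1000
    },
    per_size_class_table = {
      tab <- params$sink_table
      if (is.null(tab)) {
        stop("colony_sink: per_size_class_table mode needs sink_table for ",
             "species ", params$species, call. = FALSE)
      }
      k <- length(tab$gC_per_colony_yr)
      idx <- pmin(pmax(findInterval(height_cm, tab$edges), 1L), k)
      tab$gC_per_colony_yr[idx]
    },
    effective_biomass = {
      if (is.null(params$effective_sink)) {
        stop("colony_sink: effective_biomass mode needs effective_sink for ",
             "species ", params$species, call. = FALSE)
      }
      len <- evaluate_power_law(params$length_model, height_cm)
      params$effective_sink * length_to_afdm(len, params$afdm) / 1000
    }
  )
}

#' Per-colony carbon budget for a survey
#'
#' Runs the full allometric and rate chain for every colony: AFDM, daily
#' ingestion and respiration, net daily flux, seasonal flux, and annual sink.
#'
#' @param colonies Survey tibble (`species`, `height_cm`, `depth_m`, ...).
#' @param params_set Named list of [species_parameters()] keyed
#'   `species.zone`.
#' @param constants [conversion_constants()].
#' @param threshold_m Depth-zone boundary (m).
#' @return The input tibble with columns `zone`, `afdm_g`,
#'   `ingestion_gC_d`, `respiration_gC_d`, `net_gC_d`, `seasonal_gC`,
#'   `sink_gC_yr` appended.
#' @export
colony_budget <- function(colonies, params_set,
                          constants = conversion_constants(),
                          threshold_m = 35) {
  if (!"zone" %in% names(colonies)) {
    colonies <- assign_depth_zone(colonies, threshold_m)
  }
  n <- nrow(colonies)
  cols <- c("afdm_g", "ingestion_gC_d", "respiration_gC_d", "sink_gC_yr")
  for (cl in cols) colonies[[cl]] <- numeric(n)
  if (n > 0) {
    grp <- paste(colonies$species, colonies$zone, sep = ".")
    for (key in unique(grp)) {
      rows <- which(grp == key)
      p <- lookup_params(params_set, colonies$species[rows[1]],
                         colonies$zone[rows[1]])
      h <- colonies$height_cm[rows]
      colonies$afdm_g[rows] <-
        length_to_afdm(evaluate_power_law(p$length_model, h), p$afdm)
      colonies$ingestion_gC_d[rows] <- colony_ingestion(p, h)
      colonies$respiration_gC_d[rows] <- colony_respiration(p, h, constants)
      colonies$sink_gC_yr[rows] <- colony_sink(p, h)
    }
  }
  colonies$net_gC_d <- suppressWarnings(
    net_flux(colonies$ingestion_gC_d, colonies$respiration_gC_d))
  colonies$seasonal_gC <- seasonal_flux(colonies$net_gC_d,
                                        constants$season_days)
  colonies
}

#' Aggregate per-colony budgets into compartment and species totals
#'
#' Sums per-colony values over species-by-zone compartments and appends one
#' `total` row per species (shallow + deep exactly). In every row
#' `net = ingestion - respiration` and `seasonal = net * season_days` hold
#' exactly.
#'
#' @param per_colony Output of [colony_budget()].
#' @param season_days Season length used for the seasonal column.
#' @return A tibble with `species`, `zone` (shallow/deep/total),
#'   `n_colonies`, `biomass_g_afdm`, `daily_ingestion_gC`,
#'   `daily_respiration_gC`, `daily_net_gC`, `seasonal_net_gC`,
#'   `annual_sink_gC`.
#' @export
aggregate_budget <- function(per_colony, season_days = 90) {
  if (nrow(per_colony) == 0) {
    return(tibble::tibble(
      species = character(), zone = character(), n_colonies = integer(),
      biomass_g_afdm = numeric(), daily_ingestion_gC = numeric(),
      daily_respiration_gC = numeric(), daily_net_gC = numeric(),
      seasonal_net_gC = numeric(), annual_sink_gC = numeric()
    ))
  }
  comp <- dplyr::summarise(
    dplyr::group_by(per_colony, .data$species, .data$zone),
    n_colonies = dplyr::n(),
    biomass_g_afdm = sum(.data$afdm_g),
    daily_ingestion_gC = sum(.data$ingestion_gC_d),
    daily_respiration_gC = sum(.data$respiration_gC_d),
    annual_sink_gC = sum(.data$sink_gC_yr),
    .groups = "drop"
  )
  totals <- dplyr::summarise(
    dplyr::group_by(comp, .data$species),
    zone = "total",
    n_colonies = sum(.data$n_colonies),
    biomass_g_afdm = sum(.data$biomass_g_afdm),
    daily_ingestion_gC = sum(.data$daily_ingestion_gC),
    daily_respiration_gC = sum(.data$daily_respiration_gC),
    annual_sink_gC = sum(.data$annual_sink_gC),
    .groups = "drop"
  )
  out <- dplyr::bind_rows(comp, totals)
  out$daily_net_gC <- out$daily_ingestion_gC - out$daily_respiration_gC
  out$seasonal_net_gC <- out$daily_net_gC * season_days
  dplyr::arrange(
    out[, c("species", "zone", "n_colonies", "biomass_g_afdm",
            "daily_ingestion_gC", "daily_respiration_gC", "daily_net_gC",
            "seasonal_net_gC", "annual_sink_gC")],
    .data$species, match(.data$zone, c("shallow", "deep", "total"))
  )
}

#' Aggregate reported compartment summaries into species totals
#'
#' The depth-aggregation stage applied directly to compartment-level totals
#' (as produced by an external survey or by [reported_compartments()]):
#' species totals are shallow + deep sums, net flux is ingestion minus
#' respiration, all at full precision.
#'
#' @param compartments Tibble with `species`, `zone`, `n_colonies`,
#'   `biomass_g_afdm`, `daily_ingestion_gC`, `daily_respiration_gC`,
#'   `spring_flux_gC`, `annual_sink_gC`.
#' @return A tibble with one row per species of summed totals plus
#'   `daily_net_gC` per compartment input row retained in attributes.
#' @export
aggregate_compartments <- function(compartments) {
  compartments$daily_net_gC <-
    net_flux(compartments$daily_ingestion_gC,
             compartments$daily_respiration_gC)
  dplyr::summarise(
    dplyr::group_by(compartments, .data$species),
    n_colonies = sum(.data$n_colonies),
    biomass_g_afdm = sum(.data$biomass_g_afdm),
    daily_ingestion_gC = sum(.data$daily_ingestion_gC),
    daily_respiration_gC = sum(.data$daily_respiration_gC),
    daily_net_gC = sum(.data$daily_net_gC),
    spring_flux_gC = sum(.data$spring_flux_gC),
    annual_sink_gC = sum(.data$annual_sink_gC),
    .groups = "drop"
  )
}

#' Per-square-metre summaries of a colony budget
#'
#' Means and SDs of biomass, seasonal flux and annual sink per sampling
#' unit, under a declared denominator convention: `"occupied_units"`
#' averages over units holding at least one colony of the species;
#' `"all_units"` includes empty units (requires `all_units`, a tibble of
#' `sampling_unit` ids with `area_m2`). Reporting only -- the convention
#' behind published per-m2 values is not uniquely determined.
#'
#' @param per_colony Output of [colony_budget()].
#' @param unit_area_m2 Sampling-unit area (m2), default 1.
#' @param denominator `"occupied_units"` or `"all_units"`.
#' @param all_units Optional tibble of all sampling units (`sampling_unit`,
#'   optional `area_m2`) for the `all_units` convention.
#' @return Tibble per species: mean and SD of g AFDM m-2, seasonal
#'   g C m-2 and sink g C m-2 yr-1.
#' @export
per_area_summary <- function(per_colony, unit_area_m2 = 1,
                             denominator = c("occupied_units", "all_units"),
                             all_units = NULL) {
  denominator <- match.arg(denominator)
  per_unit <- dplyr::summarise(
    dplyr::group_by(per_colony, .data$species, .data$sampling_unit),
    biomass = sum(.data$afdm_g), seasonal = sum(.data$seasonal_gC),
    sink = sum(.data$sink_gC_yr), .groups = "drop"
  )
  if (denominator == "all_units") {
    if (is.null(all_units)) {
      stop("per_area_summary: `all_units` required for the all_units ",
           "denominator", call. = FALSE)
    }
    grid <- expand.grid(species = unique(per_unit$species),
                        sampling_unit = all_units$sampling_unit,
                        stringsAsFactors = FALSE)
    per_unit <- dplyr::left_join(tibble::as_tibble(grid), per_unit,
                                 by = c("species", "sampling_unit"))
    per_unit[is.na(per_unit)] <- 0
  }
  dplyr::summarise(
    dplyr::group_by(per_unit, .data$species),
    biomass_g_m2 = mean(.data$biomass / unit_area_m2),
    biomass_sd = stats::sd(.data$biomass / unit_area_m2),
    seasonal_gC_m2 = mean(.data$seasonal / unit_area_m2),
    seasonal_sd = stats::sd(.data$seasonal / unit_area_m2),
    sink_gC_m2_yr = mean(.data$sink / unit_area_m2),
    sink_sd = stats::sd(.data$sink / unit_area_m2),
    n_units = dplyr::n(),
    .groups = "drop"
  )
}

#' Format a budget table for reporting
#'
#' Rounds to 2 decimals at serialization time only; all internal arithmetic
#' is full precision.
#'
#' @param budget Output of [aggregate_budget()].
#' @return The budget with numeric columns rounded to 2 decimals.
#' @export
format_budget <- function(budget) {
  num <- vapply(budget, is.numeric, logical(1))
  budget[num] <- lapply(budget[num], round, digits = 2)
  budget
}
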