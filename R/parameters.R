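#' Conversion constants for the carbon budget
#'
#' @param o2_to_c mg C respired per mg O2 consumed (a respiratory-quotient
#'   based factor; default 0.281).
#' @param season_days Length of the productive season in days. Spring is the
#'   only season with a positive energy balance for Mediterranean passive
#'   suspension feeders and is treated as 90 days by default.
#' @return A named list of constants.
#' @export
conversion_constants <- function(o2_to_c = 0.281, season_days = 90) {
  stopifnot(o2_to_c > 0, season_days > 0)
  list(o2_to_c = o2_to_c, hours_per_day = 24, season_days = season_days)
}

#' Convert oxygen consumption to respired carbon
#'
#' @param mg_o2 Oxygen consumed (mg O2), >= 0; vectorized.
#' @param factor mg C per mg O2 (default 0.281).
#' @return Respired carbon (mg C).
#' @export
o2_to_carbon <- function(mg_o2, factor = 0.281) {
  if (any(mg_o2 < 0)) stop("o2_to_carbon: input must be >= 0", call. = FALSE)
  mg_o2 * factor
}

#' Convert a rate between per-hour and per-day time bases
#'
#' Literature rates mix h-1 and d-1 bases; all budget arithmetic runs on a
#' per-day base internally.
#'
#' @param rate Numeric rate(s).
#' @param from,to `"per_hour"` or `"per_day"`.
#' @export
normalize_rate_timebase <- function(rate, from, to) {
  bases <- c("per_hour", "per_day")
  if (!(from %in% bases) || !(to %in% bases)) {
    stop("normalize_rate_timebase: time base must be 'per_hour' or 'per_day'",
         call. = FALSE)
  }
  if (from == to) return(rate)
  if (from == "per_hour") rate * 24 else rate / 24
}

#' Per-species parameter set
#'
#' Bundles every conversion constant and physiological rate needed to turn a
#' colony height into daily carbon ingestion, respiration and annual carbon
#' sink for one species in one depth zone.
#'
#' Ingestion channels (any may be absent, but at least one must be present):
#' \describe{
#'   \item{zooplankton}{ug C polyp-1 on the declared time base; requires a
#'     polyp conversion (`polyps_per_cm` factor or `polyp_table`).}
#'   \item{seston}{ug C g AFDM-1 on the declared time base (micro-/nano-
#'     plankton and detrital POM, or back-solved effective rates).}
#'   \item{autotrophic}{ug C cm-2 on the declared time base; photosynthetic
#'     input of symbionts, requires a height-to-area model (mixotrophs only).}
#' }
#'
#' @param species Species identifier.
#' @param zone `"shallow"` or `"deep"` (35 m boundary, shallow inclusive).
#' @param length_model Height-to-length [power_law()].
#' @param afdm [linear_density()] in mg AFDM cm-1.
#' @param area_model Optional height-to-area [power_law()].
#' @param polyps_per_cm Optional [linear_density()] in polyps cm-1.
#' @param polyp_table Optional [polyp_size_table()].
#' @param zooplankton_rate,seston_rate,autotrophic_rate Optional ingestion
#'   rates; each given with its `*_timebase` (`"per_hour"`/`"per_day"`).
#' @param zooplankton_timebase,seston_timebase,autotrophic_timebase Time
#'   bases of the corresponding rates.
#' @param respiration_rate mg O2 g AFDM-1 on `respiration_timebase`.
#' @param respiration_timebase `"per_hour"` or `"per_day"`.
#' @param respiration_temp_c Reference temperature (metadata only; no
#'   temperature response is modelled).
#' @param growth_cm_yr Annual height increment (cm yr-1).
#' @param c_content Optional [linear_density()] in mg C cm-1.
#' @param sink_mode How the annual C sink is computed:
#'   `"length_increment"` (growth in length times C content per cm),
#'   `"per_size_class_table"` (published annual C investment per colony and
#'   size class), or `"effective_biomass"` (back-solved g-level rate).
#' @param sink_table For `per_size_class_table`: list with `edges` (cm) and
#'   `gC_per_colony_yr` per class.
#' @param effective_sink For `effective_biomass`: mg C g AFDM-1 yr-1.
#' @param mixotrophic Logical; mixotrophs must carry an autotrophic channel.
#' @return A `species_params` object.
#' @export
species_parameters <- function(species, zone = c("shallow", "deep"),
                               length_model, afdm,
                               area_model = NULL,
                               polyps_per_cm = NULL, polyp_table = NULL,
                               zooplankton_rate = NULL,
                               zooplankton_timebase = "per_day",
                               seston_rate = NULL,
                               seston_timebase = "per_hour",
                               autotrophic_rate = NULL,
                               autotrophic_timebase = "per_day",
                               respiration_rate = NULL,
                               respiration_timebase = "per_hour",
                               respiration_temp_c = NA_real_,
                               growth_cm_yr = NULL,
                               c_content = NULL,
                               sink_mode = c("length_increment",
                                             "per_size_class_table",
                                             "effective_biomass"),
                               sink_table = NULL,
                               effective_sink = NULL,
                               mixotrophic = FALSE) {
  zone <- match.arg(zone)
  sink_mode <- match.arg(sink_mode)
  structure(
    list(species = species, zone = zone,
         length_model = length_model, area_model = area_model, afdm = afdm,
         polyps_per_cm = polyps_per_cm, polyp_table = polyp_table,
         zooplankton_rate = zooplankton_rate,
         zooplankton_timebase = zooplankton_timebase,
         seston_rate = seston_rate, seston_timebase = seston_timebase,
         autotrophic_rate = autotrophic_rate,
         autotrophic_timebase = autotrophic_timebase,
         respiration_rate = respiration_rate,
         respiration_timebase = respiration_timebase,
         respiration_temp_c = respiration_temp_c,
         growth_cm_yr = growth_cm_yr, c_content = c_content,
         sink_mode = sink_mode, sink_table = sink_table,
         effective_sink = effective_sink, mixotrophic = mixotrophic),
    class = "species_params"
  )
}

#' Validate a species parameter set
#'
#' Never raises: returns a character vector of issues, empty when all
#' invariants hold.
#'
#' @param params A [species_parameters()] object.
#' @return Character vector of issue descriptions (possibly empty).
#' @export
validate_parameters <- function(params) {
  issues <- character()
  add <- function(msg) issues <<- c(issues, msg)
  if (!inherits(params, "species_params")) {
    return("not a species_params object")
  }
  if (!inherits(params$length_model, "power_law")) {
    add("length_model: must be a power_law")
  }
  if (!inherits(params$afdm, "linear_density") ||
      params$afdm$units != "mg_AFDM_per_cm") {
    add("afdm: must be a linear_density in mg_AFDM_per_cm")
  }
  for (f in c("zooplankton_rate", "seston_rate", "autotrophic_rate",
              "respiration_rate", "growth_cm_yr", "effective_sink")) {
    v <- params[[f]]
    if (!is.null(v) && !is.na(v) && v < 0) add(paste0(f, ": must be >= 0"))
  }
  for (f in c("zooplankton_timebase", "seston_timebase",
              "autotrophic_timebase", "respiration_timebase")) {
    if (!params[[f]] %in% c("per_hour", "per_day")) {
      add(paste0(f, ": must be 'per_hour' or 'per_day'"))
    }
  }
  if (isTRUE(params$mixotrophic) && is.null(params$autotrophic_rate)) {
    add("autotrophic_rate: required for a mixotrophic species")
  }
  if (!is.null(params$autotrophic_rate) && is.null(params$area_model)) {
    add("area_model: required when an autotrophic (per cm2) channel is set")
  }
  if (!is.null(params$zooplankton_rate) &&
      is.null(params$polyps_per_cm) && is.null(params$polyp_table)) {
    add("polyps: a per-polyp channel needs polyps_per_cm or polyp_table")
  }
  if (is.null(params$zooplankton_rate) && is.null(params$seston_rate) &&
      is.null(params$autotrophic_rate)) {
    add("ingestion: at least one ingestion channel must be configured")
  }
  if (params$sink_mode == "length_increment" &&
      (is.null(params$growth_cm_yr) || is.null(params$c_content))) {
    add("sink: length_increment mode needs growth_cm_yr and c_content")
  }
  if (params$sink_mode == "per_size_class_table" && is.null(params$sink_table)) {
    add("sink: per_size_class_table mode needs sink_table")
  }
  if (params$sink_mode == "effective_biomass" && is.null(params$effective_sink)) {
    add("sink: effective_biomass mode needs effective_sink")
  }
  issues
}

#' Back-solve effective per-biomass rates from compartment totals
#'
#' Divides observed compartment-level daily ingestion and respiration (and
#' optionally the annual sink) by compartment biomass, yielding effective
#' rates in mg C g AFDM-1 d-1 (sink: mg C g AFDM-1 yr-1). Feeding these
#' rates back through the budget against the same biomass returns the
#' original totals exactly (closure), which calibrates a runnable parameter
#' set when the underlying literature rates are not available.
#'
#' @param biomass_g_afdm Compartment biomass (g AFDM), > 0.
#' @param daily_ingestion_gC,daily_respiration_gC Compartment totals
#'   (g C d-1), >= 0.
#' @param annual_sink_gC Optional compartment sink (g C yr-1).
#' @return List with `ingestion_mgC_g_d`, `respiration_mgC_g_d` and (when
#'   the sink is supplied) `sink_mgC_g_yr`.
#' @export
back_solve_effective_rates <- function(biomass_g_afdm, daily_ingestion_gC,
                                       daily_respiration_gC,
                                       annual_sink_gC = NULL) {
  if (any(biomass_g_afdm <= 0)) {
    stop("back_solve_effective_rates: biomass must be > 0", call. = FALSE)
  }
  out <- list(
    ingestion_mgC_g_d = daily_ingestion_gC / biomass_g_afdm * 1000,
    respiration_mgC_g_d = daily_respiration_gC / biomass_g_afdm * 1000
  )
  if (!is.null(annual_sink_gC)) {
    out$sink_mgC_g_yr <- annual_sink_gC / biomass_g_afdm * 1000
  }
  out
}

# Published allometric models and tissue densities for the three species.
# The L. sarmentosa height-length coefficient has been reported both as
# 2.1167 and 0.21167; the larger value is the default (it keeps total branch
# length above height for ramified colonies) and can be overridden.
species_allometry_defaults <- function() {
  list(
    P_clavata = list(
      shallow = list(length = power_law(1.06, 1.69),
                     afdm = linear_density(18.35, 2.33, "mg_AFDM_per_cm")),
      deep = list(length = power_law(1.06, 1.69),
                  afdm = linear_density(18.35, 2.33, "mg_AFDM_per_cm"))
    ),
    E_singularis = list(
      shallow = list(
        length = power_law(0.2869, 1.9652, r_squared = 0.78, n_fit = 28),
        area = power_law(0.0609, 2.4655, response = "surface_area_cm2",
                         r_squared = 0.81, n_fit = 28),
        afdm = linear_density(5.69, 0.47, "mg_AFDM_per_cm"),
        polyps = linear_density(31.1, 1.1, "polyps_per_cm")
      ),
      deep = list(
        length = power_law(0.4669, 1.8432, r_squared = 0.66, n_fit = 44),
        afdm = linear_density(4.43, 0.37, "mg_AFDM_per_cm"),
        polyps = linear_density(31.1, 1.1, "polyps_per_cm")
      )
    ),
    L_sarmentosa = list(
      shallow = list(length = power_law(2.1167, 1.3684, r_squared = 0.74,
                                        n_fit = 16),
                     afdm = linear_density(2.94, 0.67, "mg_AFDM_per_cm")),
      deep = list(length = power_law(2.1167, 1.3684, r_squared = 0.74,
                                     n_fit = 16),
                  afdm = linear_density(2.94, 0.67, "mg_AFDM_per_cm"))
    )
  )
}

#' Reported compartment summaries for the Cap de Creus survey
#'
#' Observed totals per species-by-depth-zone compartment over the 1.14 ha of
#' video transects: colony counts, biomass, daily carbon ingestion and
#' respiration, spring carbon flux and annual carbon sink. These are the
#' aggregates that calibrate the effective rates in
#' [calibrated_parameters()].
#'
#' @return A tibble with one row per compartment.
#' @export
reported_compartments <- function() {
  path <- system.file("extdata", "cap_de_creus_compartments.csv",
                      package = "gorgC", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}

#' Reported per-species habitat-wide sink rates
#'
#' Carbon sequestered annually per hectare of suitable habitat by each
#' species over the whole study area (kg C ha-1 yr-1). Used as inputs to the
#' combined area-wide total.
#'
#' @return A tibble with columns `species`, `sink_kgC_ha_yr`.
#' @export
reported_per_ha_sinks <- function() {
  path <- system.file("extdata", "cap_de_creus_per_ha_sinks.csv",
                      package = "gorgC", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}

#' Calibrated effective parameter sets for the three gorgonian species
#'
#' Builds a complete, runnable parameter set per species-by-zone compartment
#' by back-solving effective per-biomass rates from the reported compartment
#' totals ([reported_compartments()]). The feeding channel is a single
#' effective seston-type rate (ug C g AFDM-1 d-1) that folds together
#' zooplankton, micro-/nano-plankton, detrital POM and -- for shallow
#' Eunicella singularis -- the autotrophic input; the respiration rate is
#' expressed back in mg O2 g AFDM-1 d-1 via the 0.281 conversion; the sink
#' uses the `effective_biomass` mode. These are effective rates tied to the
#' surveyed populations, not the physiological literature rates.
#'
#' @param constants [conversion_constants()].
#' @return Named list of [species_parameters()], keyed `species.zone`.
#' @export
calibrated_parameters <- function(constants = conversion_constants()) {
  comp <- reported_compartments()
  allo <- species_allometry_defaults()
  out <- list()
  for (i in seq_len(nrow(comp))) {
    row <- comp[i, ]
    eff <- back_solve_effective_rates(row$biomass_g_afdm,
                                      row$daily_ingestion_gC,
                                      row$daily_respiration_gC,
                                      row$annual_sink_gC)
    sp_allo <- allo[[row$species]][[row$zone]]
    out[[paste(row$species, row$zone, sep = ".")]] <- species_parameters(
      species = row$species, zone = row$zone,
      length_model = sp_allo$length, area_model = sp_allo$area,
      afdm = sp_allo$afdm, polyps_per_cm = sp_allo$polyps,
      seston_rate = eff$ingestion_mgC_g_d * 1000,  # mg -> ug C g-1 d-1
      seston_timebase = "per_day",
      respiration_rate = eff$respiration_mgC_g_d / constants$o2_to_c,
      respiration_timebase = "per_day",
      respiration_temp_c = if (row$zone == "shallow") 16 else 14,
      sink_mode = "effective_biomass",
      effective_sink = eff$sink_mgC_g_yr
    )
  }
  out
}

params_key <- function(species, zone) paste(species, zone, sep = ".")

lookup_params <- function(params_set, species, zone) {
  p <- params_set[[params_key(species, zone)]]
  if (is.null(p)) {
    stop(sprintf("no parameters configured for species '%s', zone '%s'",
                 species, zone), call. = FALSE)
  }
  p
}

#' Write / read a parameter set to YAML
#'
#' Serializes the numeric content of a named parameter set (allometric
#' coefficients, densities, rates with explicit unit-bearing field names) so
#' a run is reproducible from its config alone.
#'
#' @param params_set Named list of [species_parameters()].
#' @param path File path.
#' @return `write_parameters_yaml` returns `path` invisibly;
#'   `read_parameters_yaml` returns the parameter set.
#' @export
write_parameters_yaml <- function(params_set, path) {
  ser_model <- function(m) {
    if (is.null(m)) return(NULL)
    list(a = m$a, b = m$b, response = m$response,
         r_squared = m$r_squared, n_fit = m$n_fit)
  }
  ser_ld <- function(d) {
    if (is.null(d)) return(NULL)
    list(mean = d$mean, se = d$se, units = d$units)
  }
  doc <- lapply(params_set, function(p) {
    list(species = p$species, zone = p$zone,
         length_model = ser_model(p$length_model),
         area_model = ser_model(p$area_model),
         afdm_mg_per_cm = ser_ld(p$afdm),
         polyps_per_cm = ser_ld(p$polyps_per_cm),
         zooplankton_ugC_per_polyp = p$zooplankton_rate,
         zooplankton_timebase = p$zooplankton_timebase,
         seston_ugC_per_gAFDM = p$seston_rate,
         seston_timebase = p$seston_timebase,
         autotrophic_ugC_per_cm2 = p$autotrophic_rate,
         autotrophic_timebase = p$autotrophic_timebase,
         respiration_mgO2_per_gAFDM = p$respiration_rate,
         respiration_timebase = p$respiration_timebase,
         respiration_temp_c = p$respiration_temp_c,
         growth_cm_yr = p$growth_cm_yr,
         c_content_mg_per_cm = ser_ld(p$c_content),
         sink_mode = p$sink_mode,
         effective_sink_mgC_per_gAFDM_yr = p$effective_sink,
         mixotrophic = p$mixotrophic)
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_parameters_yaml
#' @export
read_parameters_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  de_model <- function(m) {
    if (is.null(m)) return(NULL)
    power_law(m$a, m$b, response = m$response %||% "linear_length_cm",
              r_squared = m$r_squared, n_fit = m$n_fit)
  }
  de_ld <- function(d) {
    if (is.null(d)) return(NULL)
    linear_density(d$mean, d$se %||% 0, d$units)
  }
  out <- lapply(doc, function(p) {
    species_parameters(
      species = p$species, zone = p$zone,
      length_model = de_model(p$length_model),
      area_model = de_model(p$area_model),
      afdm = de_ld(p$afdm_mg_per_cm),
      polyps_per_cm = de_ld(p$polyps_per_cm),
      zooplankton_rate = p$zooplankton_ugC_per_polyp,
      zooplankton_timebase = p$zooplankton_timebase %||% "per_day",
      seston_rate = p$seston_ugC_per_gAFDM,
      seston_timebase = p$seston_timebase %||% "per_hour",
      autotrophic_rate = p$autotrophic_ugC_per_cm2,
      autotrophic_timebase = p$autotrophic_timebase %||% "per_day",
      respiration_rate = p$respiration_mgO2_per_gAFDM,
      respiration_timebase = p$respiration_timebase %||% "per_hour",
      respiration_temp_c = p$respiration_temp_c %||% NA_real_,
      growth_cm_yr = p$growth_cm_yr,
      c_content = de_ld(p$c_content_mg_per_cm),
      sink_mode = p$sink_mode %||% "length_increment",
      effective_sink = p$effective_sink_mgC_per_gAFDM_yr,
      mixotrophic = isTRUE(p$mixotrophic)
    )
  })
  names(out) <- vapply(out, function(p) params_key(p$species, p$zone), "")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
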