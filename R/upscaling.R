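#' Load a habitat-area table
#'
#' Hectares of suitable benthic assemblage per species, with the zone
#' (shallow/deep) of each assemblage. `species_list` is a
#' semicolon-separated set of species the assemblage is suitable for.
#'
#' @param path CSV with columns `assemblage`, `area_ha`, `zone`,
#'   `species_list`. Defaults to the shipped synthetic fixture (the real
#'   per-assemblage areas of the study region are not public).
#' @return A long tibble: `assemblage`, `area_ha`, `zone`, `species`.
#' @export
load_habitat_areas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_habitat_areas.csv",
                        package = "gorgC", mustWork = TRUE)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (any(df$area_ha <= 0)) {
    stop("load_habitat_areas: areas must be > 0", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    tibble::tibble(assemblage = df$assemblage[i], area_ha = df$area_ha[i],
                   zone = df$zone[i],
                   species = strsplit(df$species_list[i], ";")[[1]])
  })
  dplyr::bind_rows(rows)
}

#' Potential number of colonies on a suitable assemblage
#'
#' Extrapolates the *total* density (mean over sampling units with and
#' without gorgonians) to the full assemblage area. Passing the on-patch
#' density here would overstate abundance by the occupancy factor, so the
#' argument names are explicit.
#'
#' @param area_ha Suitable assemblage area (hectares), >= 0.
#' @param total_density Total density (colonies m-2), >= 0.
#' @return Expected colony number (real, not rounded).
#' @export
potential_colonies <- function(area_ha, total_density) {
  if (any(area_ha < 0) || any(total_density < 0)) {
    stop("potential_colonies: area and density must be >= 0", call. = FALSE)
  }
  area_ha * 1e4 * total_density
}

#' Potential carbon budget over suitable habitat
#'
#' Combines potential colony numbers per assemblage with mean per-colony
#' seasonal flux and annual sink of the matching species-by-zone compartment
#' (shallow assemblages use shallow compartment means, deep use deep).
#'
#' @param habitat Long habitat tibble from [load_habitat_areas()].
#' @param densities Density tibble (as [assemblage_densities()]): `species`,
#'   `assemblage`, `total_density`.
#' @param per_colony_means Tibble with `species`, `zone`,
#'   `mean_seasonal_gC`, `mean_sink_gC_yr` (per-colony compartment means).
#' @return Tibble per species-by-assemblage: `potential_colonies`,
#'   `potential_seasonal_gC`, `potential_sink_gC_yr`, plus per-species
#'   totals with `sink_kgC_ha_yr` over the summed suitable area.
#' @export
potential_budget <- function(habitat, densities, per_colony_means) {
  joined <- dplyr::inner_join(habitat, densities[, c("species", "assemblage",
                                                     "total_density")],
                              by = c("species", "assemblage"))
  joined <- dplyr::left_join(joined, per_colony_means,
                             by = c("species", "zone"))
  if (any(is.na(joined$mean_seasonal_gC)) ||
      any(is.na(joined$mean_sink_gC_yr))) {
    bad <- unique(joined$species[is.na(joined$mean_seasonal_gC) |
                                   is.na(joined$mean_sink_gC_yr)])
    stop("potential_budget: missing per-colony compartment means for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  joined$potential_colonies <-
    potential_colonies(joined$area_ha, joined$total_density)
  joined$potential_seasonal_gC <-
    joined$potential_colonies * joined$mean_seasonal_gC
  joined$potential_sink_gC_yr <-
    joined$potential_colonies * joined$mean_sink_gC_yr
  by_species <- dplyr::summarise(
    dplyr::group_by(joined, .data$species),
    suitable_area_ha = sum(.data$area_ha),
    potential_colonies = sum(.data$potential_colonies),
    potential_seasonal_gC = sum(.data$potential_seasonal_gC),
    potential_sink_gC_yr = sum(.data$potential_sink_gC_yr),
    .groups = "drop"
  )
  by_species$sink_kgC_ha_yr <-
    by_species$potential_sink_gC_yr / 1000 / by_species$suitable_area_ha
  list(by_assemblage = tibble::as_tibble(joined), by_species = by_species)
}

#' Combine per-species per-hectare sinks into an area-wide total
#'
#' Sums per-species sink rates (kg C ha-1 yr-1) and converts to
#' t C ha-1 yr-1, the unit used to compare animal forests with terrestrial
#' and seagrass carbon sinks.
#'
#' @param sink_kgC_ha_yr Per-species sink rates (kg C ha-1 yr-1).
#' @return Combined sink in t C ha-1 yr-1.
#' @export
combined_sink_t_ha_yr <- function(sink_kgC_ha_yr) {
  if (any(sink_kgC_ha_yr < 0)) {
    stop("combined_sink_t_ha_yr: sink rates must be >= 0", call. = FALSE)
  }
  sum(sink_kgC_ha_yr) / 1000
}
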