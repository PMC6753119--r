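#' Read a colony survey table
#'
#' One row per observed colony with columns `species`, `height_cm`,
#' `depth_m`, `transect`, `sampling_unit`, `assemblage`. Row-level problems
#' (non-positive or unparsable heights, negative depths) are reported with
#' their line numbers.
#'
#' @param path CSV file path.
#' @return A tibble of validated colony records.
#' @export
load_survey <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("species", "height_cm", "depth_m", "transect",
                "sampling_unit", "assemblage")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("load_survey: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$height_cm <- suppressWarnings(as.numeric(df$height_cm))
  df$depth_m <- suppressWarnings(as.numeric(df$depth_m))
  bad <- which(!is.finite(df$height_cm) | df$height_cm <= 0 |
                 !is.finite(df$depth_m) | df$depth_m < 0)
  if (length(bad) > 0) {
    stop("load_survey: invalid height/depth at data row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df[required])
}

#' Assign depth zones and partition a survey
#'
#' The shallow/deep boundary is 35 m (the light-driven shift from
#' precoralligenous and shallow coralligenous to deep coralligenous
#' assemblages); 35.0 m itself is shallow.
#'
#' @param colonies Survey tibble with a `depth_m` column.
#' @param threshold_m Zone boundary in metres (default 35).
#' @return `assign_depth_zone`: the tibble with a `zone` factor column.
#'   `partition_by_depth`: a list with elements `shallow` and `deep`.
#' @export
assign_depth_zone <- function(colonies, threshold_m = 35) {
  if (any(!is.finite(colonies$depth_m))) {
    stop("assign_depth_zone: missing depth for row(s): ",
         paste(which(!is.finite(colonies$depth_m)), collapse = ", "),
         call. = FALSE)
  }
  zone <- rep("deep", nrow(colonies))
  zone[colonies$depth_m <= threshold_m] <- "shallow"
  colonies$zone <- zone
  colonies
}

#' @rdname assign_depth_zone
#' @export
partition_by_depth <- function(colonies, threshold_m = 35) {
  z <- assign_depth_zone(colonies, threshold_m)
  list(shallow = z[z$zone == "shallow", , drop = FALSE],
       deep = z[z$zone == "deep", , drop = FALSE])
}

#' Build a population size structure
#'
#' Histogram of colony heights over half-open classes `[lo, hi)`. Colonies
#' outside the edge range are assigned to the end classes with a warning, so
#' counts always sum to the number of colonies.
#'
#' @param heights Colony heights (cm).
#' @param edges Strictly increasing class edges (cm), length k + 1.
#' @return A tibble with `lower`, `upper`, `count`.
#' @export
build_size_structure <- function(heights, edges) {
  if (any(diff(edges) <= 0)) {
    stop("build_size_structure: edges must be strictly increasing",
         call. = FALSE)
  }
  k <- length(edges) - 1L
  idx <- findInterval(heights, edges, left.open = FALSE)
  if (any(idx == 0L) || any(heights >= edges[k + 1L])) {
    warning("build_size_structure: heights outside the edge range assigned ",
            "to the end classes", call. = FALSE)
  }
  idx <- pmin(pmax(idx, 1L), k)
  tibble::tibble(
    lower = edges[-(k + 1L)], upper = edges[-1L],
    count = tabulate(idx, nbins = k)
  )
}

#' Total and on-patch density for one species in one assemblage
#'
#' Total density averages colony count / unit area over *all* sampling units
#' of the assemblage (occupied or not); on-patch density averages only over
#' units where the species occurs. Strong patchiness makes the on-patch
#' density much larger than the total density; upscaling must use the total.
#' With a single occupied unit the patch SD is undefined and reported `NA`.
#'
#' @param counts Colony counts, one per sampling unit.
#' @param area_m2 Sampling-unit area(s) in m2 (scalar or per-unit).
#' @param species,assemblage Labels carried into the output.
#' @return A one-row tibble: `total_density`, `total_sd`, `n_units`,
#'   `patch_density`, `patch_sd`, `n_occupied`.
#' @export
density_summary <- function(counts, area_m2 = 1, species = NA_character_,
                            assemblage = NA_character_) {
  if (length(counts) < 1L) {
    stop("density_summary: at least one sampling unit required", call. = FALSE)
  }
  if (any(counts < 0) || any(area_m2 <= 0)) {
    stop("density_summary: counts must be >= 0 and areas > 0", call. = FALSE)
  }
  dens <- counts / area_m2
  occ <- dens[counts > 0]
  tibble::tibble(
    species = species, assemblage = assemblage,
    total_density = mean(dens),
    total_sd = if (length(dens) > 1) stats::sd(dens) else NA_real_,
    n_units = length(dens),
    patch_density = if (length(occ) > 0) mean(occ) else NA_real_,
    patch_sd = if (length(occ) > 1) stats::sd(occ) else NA_real_,
    n_occupied = length(occ)
  )
}

#' Reported assemblage densities for the Cap de Creus survey
#'
#' Total and on-patch densities (colonies m-2, mean +/- SD) of the three
#' gorgonian species per benthic assemblage, with the number of sampling
#' units behind each mean.
#'
#' @return A tibble, one row per species-by-assemblage combination.
#' @export
assemblage_densities <- function() {
  path <- system.file("extdata", "cap_de_creus_assemblage_densities.csv",
                      package = "gorgC", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}

#' Population biomass per compartment
#'
#' Sums colony AFDM (height -> length via the power law, length -> AFDM via
#' the per-cm density) over species-by-zone compartments. Additive over any
#' partition of the colonies.
#'
#' @param colonies Survey tibble (zone assigned if absent).
#' @param params_set Named list of [species_parameters()].
#' @param threshold_m Depth boundary passed to [assign_depth_zone()].
#' @return A tibble with `species`, `zone`, `n_colonies`, `biomass_g_afdm`.
#' @export
population_biomass <- function(colonies, params_set, threshold_m = 35) {
  if (nrow(colonies) == 0) {
    return(tibble::tibble(species = character(), zone = character(),
                          n_colonies = integer(), biomass_g_afdm = numeric()))
  }
  if (!"zone" %in% names(colonies)) {
    colonies <- assign_depth_zone(colonies, threshold_m)
  }
  afdm <- colony_afdm(colonies, params_set)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(species = colonies$species,
                                   zone = colonies$zone, afdm = afdm),
                    .data$species, .data$zone),
    n_colonies = dplyr::n(), biomass_g_afdm = sum(.data$afdm),
    .groups = "drop"
  )
  out
}

# Per-colony AFDM (g) through the allometric chain; vectorized over rows.
colony_afdm <- function(colonies, params_set) {
  vapply(seq_len(nrow(colonies)), function(i) {
    p <- lookup_params(params_set, colonies$species[i], colonies$zone[i])
    length_to_afdm(evaluate_power_law(p$length_model, colonies$height_cm[i]),
                   p$afdm)
  }, numeric(1))
}
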