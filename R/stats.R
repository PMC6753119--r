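#' Square-root transform
#'
#' Variance-stabilizing transform applied to biomass, flux and sink values
#' before ANOVA.
#'
#' @param values Non-negative numeric vector.
#' @return Element-wise square roots.
#' @export
sqrt_transform <- function(values) {
  if (any(values < 0)) {
    stop("sqrt_transform: values must be >= 0", call. = FALSE)
  }
  sqrt(values)
}

as_group_data <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need >= 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("every group needs >= 2 observations", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
}

#' One-way ANOVA across groups
#'
#' Classical between/within mean-square F ratio via [stats::aov()].
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with >= 2
#'   observations).
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  dat <- as_group_data(groups)
  k <- nlevels(dat$group)
  if (stats::var(dat$value) == 0) {  # all observations identical: no effect
    return(list(F = 0, p = 1, df_between = k - 1L,
                df_within = nrow(dat) - k))
  }
  tab <- summary(stats::aov(value ~ group, data = dat))[[1]]
  list(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       df_between = tab[["Df"]][1], df_within = tab[["Df"]][2])
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range family-wise adjusted pairwise tests via
#' [stats::TukeyHSD()].
#'
#' @inheritParams one_way_anova
#' @return Tibble with `pair`, `diff`, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  dat <- as_group_data(groups)
  if (stats::var(dat$value) == 0) {  # degenerate: all observations equal
    nm <- levels(dat$group)
    pairs <- utils::combn(nm, 2, paste, collapse = "-")
    return(tibble::tibble(pair = pairs, diff = 0, p_adj = 1))
  }
  tk <- stats::TukeyHSD(stats::aov(value ~ group, data = dat))$group
  tibble::tibble(pair = rownames(tk), diff = tk[, "diff"],
                 p_adj = tk[, "p adj"])
}

#' Compare species-level responses as in the survey analysis
#'
#' Square-root transforms a per-observational-unit response (biomass, flux
#' or sink, by default per transect) and runs one-way ANOVA plus Tukey HSD
#' across species.
#'
#' @param data Tibble with a species column and a numeric response column.
#' @param response Name of the response column.
#' @param species_col Name of the grouping column (default `"species"`).
#' @return List with `response`, `anova` (F, p) and `tukey` (pairwise table).
#' @export
compare_species <- function(data, response, species_col = "species") {
  vals <- sqrt_transform(data[[response]])
  groups <- split(vals, data[[species_col]])
  list(response = response, anova = one_way_anova(groups),
       tukey = tukey_hsd(groups))
}
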