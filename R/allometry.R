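#' Allometric power-law model
#'
#' Constructs a power law `y = a * x^b` relating colony height (cm) to a
#' response: total linear branch length (cm) or colony surface area (cm2).
#' Gorgonian biomass scales with total branch length, not height, so these
#' relationships are the first link of every downstream carbon calculation.
#'
#' @param a Positive coefficient: response value at height 1 cm.
#' @param b Exponent; `b > 1` for ramified colonies whose branching increases
#'   with size.
#' @param response One of `"linear_length_cm"` or `"surface_area_cm2"`.
#' @param r_squared Optional fit diagnostic in `[0, 1]` (log-log space).
#' @param n_fit Optional number of colonies the law was fitted on.
#' @param ci Optional 2x2 matrix of 95% confidence limits for `(a, b)`.
#' @return An object of class `power_law`.
#' @examples
#' m <- power_law(0.2869, 1.9652)
#' evaluate_power_law(m, 10)
#' @export
power_law <- function(a, b, response = c("linear_length_cm", "surface_area_cm2"),
                      r_squared = NULL, n_fit = NULL, ci = NULL) {
  response <- match.arg(response)
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (a <= 0) stop("power_law: coefficient `a` must be > 0", call. = FALSE)
  if (!is.null(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("power_law: `r_squared` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(a = a, b = b, response = response, predictor = "height_cm",
         r_squared = r_squared, n_fit = n_fit, ci = ci),
    class = "power_law"
  )
}

#' @export
print.power_law <- function(x, ...) {
  cat(sprintf("Power law: y = %.4g * x^%.4g  (%s ~ height_cm)\n",
              x$a, x$b, x$response))
  if (!is.null(x$r_squared)) cat(sprintf("  R^2 (log-log) = %.3f", x$r_squared))
  if (!is.null(x$n_fit)) cat(sprintf("  n = %d", x$n_fit))
  if (!is.null(x$r_squared) || !is.null(x$n_fit)) cat("\n")
  invisible(x)
}

#' Evaluate a power law at given colony heights
#'
#' @param model A [power_law()] object.
#' @param height_cm Non-negative heights (cm); vectorized.
#' @return Response values (cm or cm2); exactly 0 at height 0.
#' @export
evaluate_power_law <- function(model, height_cm) {
  stopifnot(inherits(model, "power_law"))
  if (any(!is.finite(height_cm)) || any(height_cm < 0)) {
    stop("evaluate_power_law: heights must be finite and >= 0", call. = FALSE)
  }
  out <- model$a * height_cm^model$b
  out[height_cm == 0] <- 0  # guard b <= 0 edge; laws pass through the origin
  out
}

#' Invert a power law
#'
#' Returns the height at which the law attains a given response value;
#' used to build pseudo-colonies of prescribed biomass.
#'
#' @param model A [power_law()] object with `b != 0`.
#' @param y Non-negative response values.
#' @return Heights (cm).
#' @export
invert_power_law <- function(model, y) {
  stopifnot(inherits(model, "power_law"), model$b != 0)
  if (any(y < 0)) stop("invert_power_law: response must be >= 0", call. = FALSE)
  (y / model$a)^(1 / model$b)
}

#' Fit a power law to height-response measurement pairs
#'
#' Ordinary least squares on the log-log scale
#' (`log y = log a + b log x`), the standard estimator for allometric
#' scaling. `r_squared` is reported in log space; 95% confidence limits
#' for `(a, b)` are stored alongside the point estimates.
#'
#' @param height_cm Positive heights (cm), length >= 3.
#' @param response_value Positive responses, same length.
#' @inheritParams power_law
#' @return A [power_law()] object with `r_squared`, `n_fit` and `ci` filled.
#' @export
fit_power_law <- function(height_cm, response_value,
                          response = c("linear_length_cm", "surface_area_cm2")) {
  response <- match.arg(response)
  n <- length(height_cm)
  if (n < 3L || length(response_value) != n) {
    stop("fit_power_law: need >= 3 height/response pairs of equal length",
         call. = FALSE)
  }
  if (any(height_cm <= 0) || any(response_value <= 0)) {
    stop("fit_power_law: all measurements must be > 0", call. = FALSE)
  }
  fit <- stats::lm(log(response_value) ~ log(height_cm))
  cf <- stats::coef(fit)
  ci_log <- suppressWarnings(stats::confint(fit, level = 0.95))
  ci <- rbind(a = exp(ci_log[1, ]), b = ci_log[2, ])
  power_law(
    a = exp(unname(cf[1])), b = unname(cf[2]), response = response,
    # noiseless calibration pairs are a supported input; silence the
    # "essentially perfect fit" note summary.lm emits for them
    r_squared = suppressWarnings(summary(fit)$r.squared), n_fit = n, ci = ci
  )
}

#' Linear density factor (per-cm conversion)
#'
#' Gorgonian tissue properties that scale with total branch length: ash-free
#' dry mass, polyp number, or carbon content per cm of branch.
#'
#' @param mean Positive mean (mg AFDM cm-1, polyps cm-1 or mg C cm-1).
#' @param se Non-negative standard error.
#' @param units One of `"mg_AFDM_per_cm"`, `"polyps_per_cm"`, `"mg_C_per_cm"`.
#' @return A `linear_density` object.
#' @export
linear_density <- function(mean, se = 0,
                           units = c("mg_AFDM_per_cm", "polyps_per_cm",
                                     "mg_C_per_cm")) {
  units <- match.arg(units)
  if (!is.numeric(mean) || mean <= 0) {
    stop("linear_density: `mean` must be > 0", call. = FALSE)
  }
  if (se < 0) stop("linear_density: `se` must be >= 0", call. = FALSE)
  structure(list(mean = mean, se = se, units = units), class = "linear_density")
}

check_units <- function(factor, expected, what) {
  if (!inherits(factor, "linear_density")) {
    stop(what, ": `factor` must be a linear_density object", call. = FALSE)
  }
  if (factor$units != expected) {
    stop(sprintf("%s: factor has units '%s', expected '%s'",
                 what, factor$units, expected), call. = FALSE)
  }
  invisible(factor)
}

#' Convert total branch length to ash-free dry mass
#'
#' @param length_cm Non-negative total colony length (cm); vectorized.
#' @param factor A [linear_density()] with units `mg_AFDM_per_cm`.
#' @return AFDM in grams.
#' @export
length_to_afdm <- function(length_cm, factor) {
  check_units(factor, "mg_AFDM_per_cm", "length_to_afdm")
  if (any(length_cm < 0)) stop("length_to_afdm: length must be >= 0", call. = FALSE)
  length_cm * factor$mean / 1000
}

#' Convert total branch length to number of polyps
#'
#' Continuous (not rounded): the count enters rate arithmetic, not censuses.
#'
#' @inheritParams length_to_afdm
#' @param factor A [linear_density()] with units `polyps_per_cm`.
#' @export
length_to_polyps <- function(length_cm, factor) {
  check_units(factor, "polyps_per_cm", "length_to_polyps")
  if (any(length_cm < 0)) stop("length_to_polyps: length must be >= 0", call. = FALSE)
  length_cm * factor$mean
}

#' Polyps-per-colony size-class table
#'
#' For species whose polyp number is tabulated by height class rather than
#' per cm (e.g. Paramuricea clavata, whose published table spans 630 to
#' 26175 polyps per colony across the size range).
#'
#' @param edges Strictly increasing height-class edges (cm), length k + 1.
#' @param polyps Non-decreasing polyps-per-colony values, length k.
#' @param se Optional standard errors, length k.
#' @return A `polyp_size_table` object.
#' @export
polyp_size_table <- function(edges, polyps, se = NULL) {
  if (length(edges) < 2L || length(polyps) != length(edges) - 1L) {
    stop("polyp_size_table: need k+1 edges for k polyp values", call. = FALSE)
  }
  if (any(diff(edges) <= 0)) {
    stop("polyp_size_table: edges must be strictly increasing", call. = FALSE)
  }
  if (any(diff(polyps) < 0)) {
    stop("polyp_size_table: polyp counts must be non-decreasing", call. = FALSE)
  }
  structure(list(edges = edges, polyps = polyps, se = se),
            class = "polyp_size_table")
}

#' Look up polyps per colony by height class
#'
#' Classes are half-open `[lower, upper)`; a height on a boundary belongs to
#' the upper class. Heights outside the table range are clamped to the end
#' classes with a warning (the laws are applied across the full observed
#' size range, so out-of-range colonies are extrapolated, not dropped).
#'
#' @param height_cm Heights (cm); vectorized.
#' @param table A [polyp_size_table()].
#' @return Polyps per colony.
#' @export
height_to_polyps_by_class <- function(height_cm, table) {
  if (!inherits(table, "polyp_size_table")) {
    stop("height_to_polyps_by_class: `table` must be a polyp_size_table",
         call. = FALSE)
  }
  edges <- table$edges
  k <- length(table$polyps)
  idx <- findInterval(height_cm, edges, left.open = FALSE)  # [lo, hi)
  if (any(idx == 0L) || any(height_cm >= edges[k + 1L])) {
    warning("height_to_polyps_by_class: heights outside the table range ",
            "clamped to the end classes", call. = FALSE)
  }
  idx <- pmin(pmax(idx, 1L), k)
  table$polyps[idx]
}

#' Annual length increment from an annual height increment
#'
#' Growth rates are published as height increase (cm yr-1); carbon invested
#' in growth scales with the increase in total branch length, obtained by
#' differencing the height-length power law:
#' `delta_L = a * (h + dh)^b - a * h^b`.
#'
#' @param model A height-to-length [power_law()].
#' @param height_cm Current colony heights (cm), >= 0.
#' @param dheight_cm Annual height increment (cm yr-1), >= 0.
#' @return Length increment (cm yr-1), non-negative for `b > 0`.
#' @export
growth_to_length_increment <- function(model, height_cm, dheight_cm) {
  if (any(dheight_cm < 0)) {
    stop("growth_to_length_increment: height increment must be >= 0",
         call. = FALSE)
  }
  evaluate_power_law(model, height_cm + dheight_cm) -
    evaluate_power_law(model, height_cm)
}
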