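Package: gorgC
Title: Carbon Flux and Carbon Sink Budgets for Gorgonian Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the contribution of gorgonian (octocoral)
    populations to benthic-pelagic carbon coupling and blue-carbon storage.
    Converts colony height observations into linear length, surface area,
    polyp counts and ash-free dry mass through allometric power laws; applies
    per-species feeding, respiration and growth rates to obtain daily and
    seasonal carbon fluxes (ingestion minus respiration) and annual carbon
    sinks (carbon immobilized in growth); aggregates colonies into
    species-by-depth-zone compartments; and upscales observed densities to
    habitat-wide potential estimates via suitable-assemblage areas. Includes
    a synthetic survey generator with known ground truth, density summaries
    distinguishing total and on-patch densities, and square-root-transformed
    ANOVA with Tukey HSD comparisons across species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
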