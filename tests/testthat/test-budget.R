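# Per-colony carbon budgets and compartment aggregation.

test_that("ingestion sums the configured channels with unit conversions", {
  # toy colony: height 100 -> length 100 cm -> 1000 polyps at 10 cm-1;
  # 2 ug C polyp-1 d-1 -> 0.002 g C d-1
  p <- toy_params()
  expect_equal(colony_ingestion(p, 100), 0.002)
  p0 <- toy_params()
  p0$zooplankton_rate <- 0
  expect_equal(colony_ingestion(p0, 100), 0)
  # seston channel: per-hour rate x 24 x AFDM
  p2 <- toy_params()
  p2$zooplankton_rate <- NULL
  p2$seston_rate <- 50          # ug C g AFDM-1 h-1
  p2$seston_timebase <- "per_hour"
  # height 10 -> AFDM 10 g -> 50*24*10 ug = 0.012 g C d-1
  expect_equal(colony_ingestion(p2, 10), 0.012)
  # autotrophic channel requires an area model
  p3 <- toy_params()
  p3$autotrophic_rate <- 100    # ug C cm-2 d-1
  expect_error(colony_ingestion(p3, 10), "height-area model")
  p3$area_model <- power_law(2, 1, response = "surface_area_cm2")
  # area 20 cm2 at h=10 -> 100*20 ug = 0.002; plus zoo 2*100/1e6 = 2e-4
  expect_equal(colony_ingestion(p3, 10), 0.002 + 2e-4)
  p4 <- toy_params()
  p4$zooplankton_rate <- NULL
  expect_error(colony_ingestion(p4, 10), "no ingestion channel")
})

test_that("respiration follows the O2 chain rate*24*AFDM*0.281/1000", {
  # AFDM 1 g (height 1), 1 mg O2 g-1 h-1 -> 0.006744 g C d-1
  p <- toy_params()
  expect_equal(colony_respiration(p, 1), 0.006744)
  p0 <- toy_params()
  p0$respiration_rate <- 0
  expect_equal(colony_respiration(p0, 1), 0)
  p1 <- toy_params()
  p1$respiration_rate <- NULL
  expect_error(colony_respiration(p1, 1), "no respiration rate")
  # per-day base is not multiplied by 24
  p2 <- toy_params()
  p2$respiration_timebase <- "per_day"
  expect_equal(colony_respiration(p2, 1), 0.281 / 1000)
})

test_that("net and seasonal flux arithmetic", {
  expect_equal(net_flux(10.04, 5.14), 4.90)
  expect_equal(net_flux(3.3, 3.3), 0)
  expect_equal(net_flux(0.06, 0.02), 0.04)
  expect_warning(out <- net_flux(1, 2), "exceeds")
  expect_equal(out, -1)
  expect_error(net_flux(-1, 0), ">= 0")
  expect_equal(seasonal_flux(4.90, 90), 441)
  expect_equal(seasonal_flux(0, 90), 0)
  expect_equal(seasonal_flux(1, 90), 90)
  expect_error(seasonal_flux(1, 0), "> 0")
})

test_that("colony sink dispatches on sink_mode", {
  # length_increment: linear law, growth 1 cm -> Δlength 1 cm x 5 mg C cm-1
  p <- toy_params()
  expect_equal(colony_sink(p, 10), 0.005)
  p0 <- toy_params()
  p0$growth_cm_yr <- 0
  expect_equal(colony_sink(p0, 10), 0)
  # Δlength 10 cm x 5 mg C cm-1 = 0.05 g C yr-1
  p10 <- toy_params()
  p10$growth_cm_yr <- 10
  expect_equal(colony_sink(p10, 10), 0.05)
  # per-size-class table
  pt <- toy_params(sink_mode = "per_size_class_table")
  pt$sink_table <- list(edges = c(0, 10, 20, 30),
                        gC_per_colony_yr = c(0.1, 0.5, 2))
  expect_equal(colony_sink(pt, c(5, 15, 25, 99)), c(0.1, 0.5, 2, 2))
  # effective biomass: 2 mg C g-1 yr-1 on a 10 g colony
  pe <- toy_params(sink_mode = "effective_biomass")
  pe$effective_sink <- 2
  expect_equal(colony_sink(pe, 10), 0.02)
  pm <- toy_params()
  pm$c_content <- NULL
  expect_error(colony_sink(pm, 10), "c_content")
})

test_that("aggregated budgets are additive with exact internal identities", {
  ps <- toy_params_set()
  s <- toy_survey(c(5, 10, 20, 40))
  pc <- colony_budget(s, ps)
  agg <- aggregate_budget(pc, season_days = 90)
  # identities hold exactly in every row
  expect_equal(agg$daily_net_gC,
               agg$daily_ingestion_gC - agg$daily_respiration_gC)
  expect_equal(agg$seasonal_net_gC, agg$daily_net_gC * 90)
  # species total equals shallow + deep exactly
  s2 <- toy_survey(c(5, 10, 20, 40), depths = c(10, 20, 40, 50))
  agg2 <- aggregate_budget(colony_budget(s2, c(
    toy_params_set(),
    stats::setNames(list(local({p <- toy_params(); p$zone <- "deep"; p})),
                    "toy.deep"))))
  tot <- agg2[agg2$zone == "total", ]
  sh <- agg2[agg2$zone == "shallow", ]
  dp <- agg2[agg2$zone == "deep", ]
  for (col in c("n_colonies", "biomass_g_afdm", "daily_ingestion_gC",
                "daily_respiration_gC", "annual_sink_gC")) {
    expect_identical(tot[[col]], sh[[col]] + dp[[col]])
  }
  # additivity over disjoint colony sets
  a <- aggregate_budget(colony_budget(s[1:2, ], ps))
  b <- aggregate_budget(colony_budget(s[3:4, ], ps))
  expect_equal(a$daily_ingestion_gC + b$daily_ingestion_gC,
               agg$daily_ingestion_gC)
  expect_equal(a$annual_sink_gC + b$annual_sink_gC, agg$annual_sink_gC)
})

test_that("budget totals on a synthetic population match ground truth", {
  # deterministic pipeline: per-colony sums recomputed by hand
  ps <- toy_params_set()
  h <- c(3, 8, 13, 21, 34)
  pc <- colony_budget(toy_survey(h), ps)
  expect_equal(sum(pc$afdm_g), sum(h))             # 1 g per cm, length = h
  expect_equal(sum(pc$ingestion_gC_d), sum(2 * 10 * h) / 1e6)
  expect_equal(sum(pc$respiration_gC_d), sum(h) * 24 * 0.281 / 1000)
  expect_equal(sum(pc$sink_gC_yr), length(h) * 0.005)
})

test_that("per-area summaries honour the denominator convention", {
  ps <- toy_params_set()
  s <- dplyr::bind_rows(toy_survey(c(10, 10), unit = "u1"),
                        toy_survey(20, unit = "u2"))
  pc <- colony_budget(s, ps)
  occ <- per_area_summary(pc)  # occupied units only
  expect_equal(occ$biomass_g_m2, mean(c(20, 20)))
  all_units <- tibble::tibble(sampling_unit = c("u1", "u2", "u3", "u4"))
  alls <- per_area_summary(pc, denominator = "all_units",
                           all_units = all_units)
  expect_equal(alls$biomass_g_m2, mean(c(20, 20, 0, 0)))
  expect_error(per_area_summary(pc, denominator = "all_units"), "all_units")
})
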