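# Depth partition, size structures, density summaries and population biomass.

test_that("depth partition is exhaustive, exclusive and boundary-correct", {
  s <- toy_survey(c(10, 10, 10), depths = c(10, 35, 35.1))
  parts <- partition_by_depth(s)
  expect_equal(nrow(parts$shallow), 2)  # 35.0 m is shallow
  expect_equal(nrow(parts$deep), 1)
  expect_equal(nrow(parts$shallow) + nrow(parts$deep), nrow(s))
  empty <- toy_survey(numeric(0), depths = numeric(0))
  pe <- partition_by_depth(empty)
  expect_equal(nrow(pe$shallow), 0)
  expect_equal(nrow(pe$deep), 0)
  bad <- toy_survey(5, depths = NA_real_)
  expect_error(partition_by_depth(bad), "missing depth")
})

test_that("depth partition conserves counts on random surveys", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(1:200, 1)
    s <- toy_survey(runif(n, 1, 50), depths = runif(n, 0, 70))
    parts <- partition_by_depth(s)
    expect_equal(nrow(parts$shallow) + nrow(parts$deep), n)
    expect_true(all(parts$shallow$depth_m <= 35))
    expect_true(all(parts$deep$depth_m > 35))
  }
})

test_that("size structure counts are a half-open histogram summing to n", {
  ss <- build_size_structure(c(5, 15, 25), c(0, 10, 20, 30))
  expect_equal(ss$count, c(1, 1, 1))
  expect_equal(build_size_structure(numeric(0), c(0, 10, 20))$count, c(0, 0))
  # boundary height goes to the upper class
  expect_equal(build_size_structure(10, c(0, 10, 20))$count, c(0, 1))
  # brute-force recount oracle on a seeded lognormal sample
  set.seed(99)
  h <- rlnorm(1000, log(15), 0.6)
  edges <- seq(0, 200, by = 10)
  got <- suppressWarnings(build_size_structure(h, edges))
  manual <- vapply(seq_len(length(edges) - 1), function(i) {
    if (i < length(edges) - 1) sum(h >= edges[i] & h < edges[i + 1])
    else sum(h >= edges[i])  # end class absorbs clamped heights
  }, integer(1))
  expect_equal(got$count, manual)
  expect_equal(sum(got$count), 1000)
  expect_error(build_size_structure(h, c(0, 10, 5)), "increasing")
})

test_that("density summary separates total and on-patch densities", {
  d <- density_summary(c(0, 0, 2, 2), area_m2 = 1)
  expect_equal(d$total_density, 1.0)
  expect_equal(d$patch_density, 2.0)
  expect_equal(d$n_units, 4)
  expect_equal(d$n_occupied, 2)
  # single occupied unit: patch SD undefined
  d1 <- density_summary(c(0, 1), area_m2 = c(1, 2))
  expect_true(is.na(d1$patch_sd))
  expect_equal(d1$patch_density, 0.5)
  # all-zero counts: no patch density
  d0 <- density_summary(c(0, 0, 0))
  expect_equal(d0$total_density, 0)
  expect_true(is.na(d0$patch_density))
  expect_error(density_summary(numeric(0)), "at least one")
  expect_error(density_summary(c(-1, 2)), ">= 0")
})

test_that("patch density always dominates total density", {
  set.seed(5)
  for (i in 1:20) {
    counts <- rnbinom(50, mu = 2, size = 0.5)
    if (sum(counts) == 0) next
    d <- density_summary(counts)
    expect_gte(d$patch_density, d$total_density)
    if (all(counts > 0)) expect_equal(d$patch_density, d$total_density)
  }
})

test_that("shipped density table obeys total = patch x occupancy", {
  tab <- assemblage_densities()
  expect_gte(nrow(tab), 14)
  expect_true(all(tab$patch_density >= tab$total_density))
  rederived <- tab$patch_density * tab$n_occupied / tab$n_units
  # published values are rounded to 3 decimals
  expect_true(all(abs(rederived - tab$total_density) <= 5e-3))
})

test_that("population biomass is additive and matches the allometric chain", {
  ps <- toy_params_set()
  # one colony, length == height, 1 g per cm: height 12 -> 12 g
  b1 <- population_biomass(toy_survey(12), ps)
  expect_equal(b1$biomass_g_afdm, 12)
  expect_equal(nrow(population_biomass(toy_survey(numeric(0),
                                                  depths = numeric(0)), ps)), 0)
  # two equal colonies are exactly twice one
  b2 <- population_biomass(toy_survey(c(12, 12)), ps)
  expect_equal(b2$biomass_g_afdm, 2 * b1$biomass_g_afdm)
  # additivity over a partition
  s <- toy_survey(c(3, 7, 19, 30))
  whole <- population_biomass(s, ps)$biomass_g_afdm
  part <- population_biomass(s[1:2, ], ps)$biomass_g_afdm +
    population_biomass(s[3:4, ], ps)$biomass_g_afdm
  expect_equal(whole, part)
  expect_error(population_biomass(toy_survey(5, species = "unknown"), ps),
               "no parameters")
})

test_that("survey loader validates schema and rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,height_cm,depth_m,transect,sampling_unit,assemblage",
               "toy,10,20,t1,u1,a1", "toy,12,40,t1,u2,a1", "toy,5,8,t2,u3,a2"),
             path)
  s <- load_survey(path)
  expect_equal(nrow(s), 3)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,depth_m,transect,sampling_unit,assemblage",
               "toy,20,t1,u1,a1"), bad)
  expect_error(load_survey(bad), "height_cm")
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,height_cm,depth_m,transect,sampling_unit,assemblage",
               "toy,10,20,t1,u1,a1", "toy,-5,20,t1,u2,a1"), bad2)
  expect_error(load_survey(bad2), "row\\(s\\): 2")
})
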