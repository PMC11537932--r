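# Synthetic trial-network generator: design bookkeeping, determinism,
# degenerate cases, planted-signal recoverability.

test_that("config validation catches bad dimensions and variances", {
  expect_error(sim_config(n_genotypes = 0), "non-positive")
  expect_error(sim_config(n_genotypes = 5, n_genotypes_year1 = 9),
               "n_genotypes_year1")
  expect_error(sim_config(var_components = list(genotype = -1, gxe = 0,
                                                block = 0, row = 0, col = 0,
                                                residual = 0)), ">= 0")
  expect_error(simulate_weather(n_days = 100), ">= 148")
})

test_that("plot counts follow the incidence design; replicates >= 3", {
  cfg <- sim_config(seed = 5)
  net <- simulate_network(cfg)
  # year 1: 9 genotypes, year 2: 25, 18 locations, 3 blocks
  expect_equal(nrow(net$plots), (9 + 25) * 18 * 3)
  by_year <- tapply(net$plots$genotype, net$plots$year,
                    function(g) length(unique(g)))
  expect_equal(as.numeric(by_year), c(9, 25))
  # year-1 genotypes are a subset of year-2 genotypes
  g1 <- unique(net$plots$genotype[net$plots$year == 2021])
  g2 <- unique(net$plots$genotype[net$plots$year == 2022])
  expect_true(all(g1 %in% g2))
  # every trial has >= 3 replicates and unique (row, column) per plot
  for (key in split(net$plots, paste(net$plots$location, net$plots$year))) {
    expect_gte(length(unique(key$replicate)), 3)
    expect_false(any(duplicated(key[, c("row", "column")])))
  }
  expect_true(all(is.finite(net$plots$yield)))
})

test_that("identical seeds are byte-identical; different seeds differ", {
  a <- simulate_network(tiny_config(seed = 42))
  b <- simulate_network(tiny_config(seed = 42))
  expect_identical(serialize(a$plots, NULL), serialize(b$plots, NULL))
  expect_identical(serialize(a$weather, NULL), serialize(b$weather, NULL))
  expect_identical(serialize(a$soil, NULL), serialize(b$soil, NULL))
  expect_identical(serialize(a$production, NULL), serialize(b$production, NULL))
  c <- simulate_network(tiny_config(seed = 43))
  expect_false(identical(a$plots$yield, c$plots$yield))
  # design skeleton unchanged
  expect_identical(a$plots[, c("location", "year", "replicate")],
                   c$plots[, c("location", "year", "replicate")])
})

test_that("all-zero variances and effects give constant yield at mu", {
  cfg <- tiny_config(
    var_components = list(genotype = 0, gxe = 0, block = 0, row = 0,
                          col = 0, residual = 0),
    yield_cov_sd = 0, loc_sd = 0, env_sd = 0,
    year_effects = c(0, 0), mu = 9000)
  net <- simulate_network(cfg)
  expect_true(all(net$plots$yield == 9000))
})

test_that("weather respects min <= mean <= max and archetype window offsets", {
  w <- simulate_weather(n_days = 149, seed = 1)
  expect_true(all(w$T2M_MIN <= w$T2M & w$T2M <= w$T2M_MAX))
  expect_equal(nrow(w), 149)

  # zero daily variance: constant series at archetype means
  vars <- enviromet:::.sim_primitives()
  w0 <- simulate_weather(archetype = list(daily_sd = setNames(
    rep(0, length(vars)), names(vars))), n_days = 149, seed = 1)
  expect_equal(length(unique(w0$T2MDEW)), 1)
  expect_equal(unique(w0$T2MDEW), unname(vars["T2MDEW"]))

  # two archetypes 5 degrees apart in dew point over days 75-104:
  # window means differ by ~5 in PRE.FLW_FLW and FLW_POST.FLW
  offs <- matrix(0, 1, 6, dimnames = list("T2MDEW", phenology_calendar()$stage))
  offs[1, c("PRE.FLW_FLW", "FLW_POST.FLW")] <- 5
  wa <- simulate_weather(seed = 2, n_days = 149)
  wb <- simulate_weather(archetype = list(window_offsets = offs), seed = 2,
                         n_days = 149)
  for (win in list(75:89, 90:104)) {
    da <- mean(wa$T2MDEW[wa$day %in% win])
    db <- mean(wb$T2MDEW[wb$day %in% win])
    expect_equal(db - da, 5, tolerance = 0.4)
  }
})

test_that("production shares sum to one and are skewed", {
  net <- simulate_network(sim_config(seed = 3))
  expect_equal(sum(net$production$production_share), 1, tolerance = 1e-12)
  expect_true(all(net$production$production_share >= 0))
  # skew: the top decile of counties holds well over its proportional share
  sh <- sort(net$production$production_share, decreasing = TRUE)
  expect_gt(sum(sh[1:7]) / sum(sh), 0.2)
})

test_that("k-means on the true window means recovers the planted partition", {
  for (s in c(1, 2, 3)) {
    net <- simulate_network(sim_config(seed = s))
    truth <- net$truth$cluster_assignments
    cl <- kmeans_fit(scale(net$truth$informative_profile), 5, seed = s,
                     n_init = 20)
    expect_equal(adjusted_rand(cl$assignments, truth), 1)
  }
})
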