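# Scenario runners, cost arithmetic, reduction simulations.

# a small stage-2 dataset generated directly at the BLUE level
make_blues <- function(seed = 50, n_g = 10, n_loc = 8, noise = 30) {
  set.seed(seed)
  g <- paste0("g", seq_len(n_g)); locs <- paste0("L", seq_len(n_loc))
  d <- expand.grid(genotype = g, location = locs, year = c(2021, 2022),
                   stringsAsFactors = FALSE)
  ge <- matrix(rnorm(n_g * n_loc, 0, 25), n_g, n_loc)
  d$blue <- 9000 + rnorm(n_g, 0, 40)[match(d$genotype, g)] +
    rnorm(n_loc, 0, 60)[match(d$location, locs)] +
    ge[cbind(match(d$genotype, g), match(d$location, locs))] +
    rnorm(nrow(d), 0, noise)
  d$se <- noise
  d
}

test_that("cost model arithmetic is exact", {
  cm <- cost_model(25, 3, 25, 18, 2)
  expect_identical(trial_cost(cm), 67500)
  cm5 <- cost_model(25, 3, 25, 5, 2)
  expect_identical(trial_cost(cm5), 18750)
  expect_error(cost_model(0, 3, 25, 18, 2), "positive")
  expect_equal(h2_per_dollar(0.9, 9000), 1e-4)
  expect_equal(h2_per_dollar(0.9, 18000), 0.5e-4)
  expect_error(h2_per_dollar(0.9, 0), "positive")
})

test_that("scenario runners return valid, reproducible results", {
  d <- make_blues()
  cm <- cost_model(10, 3, 25, 8, 2)
  met <- suppressMessages(run_met(d, cm))
  expect_true(met$h2 >= 0 && met$h2 <= 1)
  expect_equal(met$cost, 10 * 3 * 25 * 8 * 2)
  expect_true(is.na(met$h2_sd))
  met2 <- suppressMessages(run_met(d, cm))
  expect_identical(met$h2, met2$h2)

  # single genotype errors
  expect_error(run_met(d[d$genotype == "g1", ]), ">= 2 genotypes")

  # MET_EC with identity kernel equals MET
  locs <- sort(unique(d$location))
  I <- diag(length(locs)); dimnames(I) <- list(locs, locs)
  ec <- suppressMessages(run_met_ec(d, I, cm))
  expect_equal(ec$h2, met$h2, tolerance = 1e-6)

  # WC with everything in one cluster equals MET
  one <- setNames(rep(1L, length(locs)), locs)
  wc <- suppressMessages(run_wc_met(d, one, cm))
  expect_equal(wc$h2, met$h2, tolerance = 1e-6)

  # WC excludes a single-environment cluster with a warning
  d1y <- d[d$year == 2021 | d$location != "L1", ]
  a <- setNames(c(1, rep(2, 7)), locs)
  # cluster 1 holds only L1; with both years it has 2 envs, so force one
  dsub <- d[!(d$location == "L1" & d$year == 2022), ]
  expect_warning(suppressMessages(run_wc_met(dsub, a, cm)), "single")
})

test_that("OPT_MET degenerates correctly and respects seeding", {
  d <- make_blues()
  locs <- sort(unique(d$location))
  # clusters of size one: all replicates identical, SD = 0
  singletons <- setNames(seq_along(locs), locs)
  opt <- suppressMessages(run_opt_met(d, singletons, n_reps = 3, seed = 1))
  expect_equal(opt$h2_sd, 0)
  met <- suppressMessages(run_met(d))
  expect_equal(opt$h2, met$h2, tolerance = 1e-6)
  expect_error(run_opt_met(d, singletons, n_reps = 0), "n_reps")
  two <- setNames(rep(1:2, each = 4), locs)
  o1 <- suppressMessages(run_opt_met(d, two, n_reps = 4, seed = 9))
  o2 <- suppressMessages(run_opt_met(d, two, n_reps = 4, seed = 9))
  expect_identical(o1$detail$h2, o2$detail$h2)
})

test_that("reduction arithmetic and simulation match hand computation", {
  expect_equal(reduction_advanced(18, 18), 0)
  expect_equal(reduction_advanced(1, 4), 75.0)
  expect_equal(reduction_advanced(5, 18), 72.2)

  # toy counts with <= 64 draw combinations: mean equals exhaustive expectation
  counts <- setNames(c(10, 10, 20, 40), paste0("L", 1:4))
  a <- setNames(c(1, 1, 2, 3), paste0("L", 1:4))
  rn <- reduction_network(counts, a, n_iters = 400, seed = 1)
  # exhaustive: cluster1 picks L1 or L2 (10 either way), plus 20 + 40
  exp_red <- 100 * (1 - (10 + 20 + 40) / 80)
  expect_equal(mean(rn$per_iter), exp_red, tolerance = 1e-9)
  # every location its own cluster: nothing is dropped
  solo <- setNames(1:4, paste0("L", 1:4))
  expect_equal(reduction_network(counts, solo, n_iters = 2,
                                 seed = 1)$mean_reduction, 0)
})

test_that("reallocation report converts savings into capacity", {
  cm <- cost_model(25, 3, 25, 18, 2)
  r <- reallocation_report(48750, cm)
  expect_equal(r$plots, 1950)
  expect_equal(r$genotypes, 650)
  expect_equal(r$lines, 8125)
  r0 <- reallocation_report(0, cm)
  expect_equal(unlist(r0), c(plots = 0, genotypes = 0, lines = 0))
})

test_that("kernel-structured GxE improves variance recovery when planted", {
  # plant GxE whose covariance follows a known location kernel; the
  # kernel-aware fit should estimate s2_ge with smaller bias than identity
  set.seed(60)
  n_g <- 12; n_loc <- 8
  locs <- paste0("L", seq_len(n_loc))
  W <- scale(matrix(rnorm(n_loc * 3), n_loc, 3))
  rownames(W) <- locs
  Om <- env_kernel(W)
  L <- t(chol(unclass(Om) + diag(1e-8, n_loc)))
  s2ge <- 900
  errs <- sapply(1:8, function(i) {
    set.seed(60 + i)
    ge <- matrix(rnorm(n_g * n_loc), n_g, n_loc) %*% t(L) * sqrt(s2ge)
    d <- expand.grid(genotype = paste0("g", 1:n_g), location = locs,
                     year = c(2021, 2022), stringsAsFactors = FALSE)
    d$blue <- 900 + rnorm(n_g, 0, 30)[match(d$genotype, paste0("g", 1:n_g))] +
      ge[cbind(match(d$genotype, paste0("g", 1:n_g)),
               match(d$location, locs))] + rnorm(nrow(d), 0, 15)
    fid <- suppressMessages(stage2_fit(d, "MET"))
    fec <- suppressMessages(stage2_fit(d, "MET_EC", kernel = Om))
    c(abs(fid$varcomp["gxe"] - s2ge), abs(fec$varcomp["gxe"] - s2ge))
  })
  expect_lt(median(errs[2, ]), median(errs[1, ]))
})
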