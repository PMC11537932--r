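# REML engine: closed-form equivalence, grid-search oracle dominance,
# GLS oracles for BLUEs, BLUP shrinkage, Cullis identities.

test_that("balanced one-way REML matches the closed-form ANOVA estimators", {
  set.seed(7)
  a <- 8; n <- 6
  s2g <- 4; s2e <- 1
  g <- rep(rnorm(a, 0, sqrt(s2g)), each = n)
  y <- 10 + g + rnorm(a * n, 0, sqrt(s2e))
  d <- data.frame(y = y, grp = factor(rep(seq_len(a), each = n)))
  fit <- fit_reml(d, "y", fixed = ~1, random = list(grp = "grp"))
  # closed form: MSB/MSW from the one-way ANOVA (REML = ANOVA when balanced)
  msw <- sum(tapply(y, d$grp, function(v) sum((v - mean(v))^2))) / (a * (n - 1))
  msb <- n * sum((tapply(y, d$grp, mean) - mean(y))^2) / (a - 1)
  expect_equal(unname(fit$varcomp["residual"]), msw, tolerance = 1e-6)
  expect_equal(unname(fit$varcomp["grp"]), (msb - msw) / n, tolerance = 1e-6)
})

test_that("engine log-likelihood dominates a brute-force grid on a tiny fit", {
  set.seed(21)
  d <- expand.grid(genotype = factor(paste0("g", 1:3)),
                   env = factor(paste0("e", 1:2)),
                   rep = factor(1:4))
  d$y <- rnorm(nrow(d), 10, 1) + rep(c(-1, 0, 1), 8)
  fit <- fit_reml(d, "y", fixed = ~env, random = list(genotype = "genotype"))
  X <- model.matrix(~env, d)
  Z <- model.matrix(~ 0 + genotype, d)
  Gs <- list(tcrossprod(Z), diag(nrow(d)))
  grid <- as.matrix(expand.grid(s2g = seq(0.01, 4, length.out = 50),
                                s2e = seq(0.05, 4, length.out = 50)))
  best_grid <- max(apply(grid, 1, function(th)
    reml_loglik_oracle(th, d$y, X, Gs)))
  expect_gte(fit$loglik, best_grid - 1e-6)
})

test_that("noise-free fixed genotype effects are reproduced exactly", {
  d <- expand.grid(genotype = factor(paste0("g", 1:4)), rep = factor(1:3))
  eff <- c(g1 = 100, g2 = -50, g3 = 0, g4 = 25)
  d$yield <- 5000 + eff[d$genotype]
  d$location <- "L1"; d$year <- 2021
  d$replicate <- d$rep; d$row <- as.integer(d$rep)
  # latin-square-ish columns so no factor is aliased with genotype
  d$column <- ((as.integer(d$genotype) + as.integer(d$rep)) %% 4) + 1
  b <- stage1_blues(d)
  expect_equal(b$blue, unname(5000 + eff[b$genotype]), tolerance = 1e-6)
})

test_that("stage-1 BLUEs equal genotype means in a balanced RCBD with blocks", {
  set.seed(3)
  g <- paste0("g", 1:6)
  d <- expand.grid(genotype = g, replicate = 1:3)
  blk <- c(200, -100, -100)
  # block effects plus a trace of residual noise keeps the REML problem
  # non-degenerate; blocks are orthogonal to genotypes, so BLUE ~ mean
  d$yield <- 8000 + rep(seq(-250, 250, length.out = 6), 3) +
    blk[d$replicate] + rnorm(18, 0, 0.5)
  d$location <- "L1"; d$year <- 2022
  d$row <- as.integer(d$replicate)
  d$column <- ((as.integer(factor(d$genotype)) +
                  as.integer(d$replicate)) %% 6) + 1
  b <- stage1_blues(d)
  gm <- tapply(d$yield, d$genotype, mean)
  expect_lt(max(abs(b$blue[match(names(gm), b$genotype)] - as.numeric(gm))),
            1)
})

test_that("unbalanced stage-1 BLUEs equal the dense GLS oracle", {
  set.seed(9)
  d <- expand.grid(genotype = paste0("g", 1:5), replicate = 1:3)
  d$yield <- 7000 + rnorm(nrow(d), 0, 100)
  d$location <- "L1"; d$year <- 2021
  d$row <- as.integer(d$replicate); d$column <- rep(1:5, 3)
  d <- d[-7, ] # one missing plot
  b <- stage1_blues(d)
  # oracle: V from the fitted variance components, dense inversion
  fit <- fit_reml(
    data.frame(yield = d$yield, genotype = factor(d$genotype),
               replicate = factor(d$replicate), frow = factor(d$row),
               fcol = factor(d$column)),
    "yield", fixed = ~ 0 + genotype,
    random = list(replicate = "replicate", row = "frow", col = "fcol"))
  Zr <- model.matrix(~ 0 + factor(d$replicate))
  Zw <- model.matrix(~ 0 + factor(d$row))
  Zc <- model.matrix(~ 0 + factor(d$column))
  v <- fit$varcomp
  V <- v["replicate"] * tcrossprod(Zr) + v["row"] * tcrossprod(Zw) +
    v["col"] * tcrossprod(Zc) + v["residual"] * diag(nrow(d))
  X <- model.matrix(~ 0 + factor(d$genotype))
  expect_equal(b$blue, as.numeric(gls_oracle(d$yield, X, V)),
               tolerance = 1e-6)
})

test_that("MET_EC with identity kernel equals plain MET", {
  net <- simulate_network(tiny_config(seed = 2))
  blues <- suppressWarnings(network_blues(net$plots))
  locs <- sort(unique(blues$location))
  I <- diag(length(locs)); dimnames(I) <- list(locs, locs)
  f1 <- suppressMessages(stage2_fit(blues, "MET"))
  f2 <- suppressMessages(stage2_fit(blues, "MET_EC", kernel = I))
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("stage-2 preconditions: environments, kernels, single cluster", {
  net <- simulate_network(tiny_config(seed = 2))
  blues <- suppressWarnings(network_blues(net$plots))
  one_env <- blues[blues$location == blues$location[1] &
                     blues$year == blues$year[1], ]
  expect_error(stage2_fit(one_env, "MET"), ">= 2 environments")
  expect_error(suppressMessages(stage2_fit(blues, "MET_EC",
                                           kernel = diag(3))),
               "kernel")
  expect_error(stage2_fit(blues, "WC"), "subset required")
})

test_that("BLUP shrinkage: genotype BLUPs shrink to zero as noise grows", {
  set.seed(4)
  d <- expand.grid(genotype = factor(c("a", "b")), rep = factor(1:5))
  d$y <- c(-2, 2)[d$genotype] + rnorm(nrow(d), 0, 0.1)
  norms <- sapply(c(0.1, 10, 1000), function(s2e) {
    n <- nrow(d)
    Z <- model.matrix(~ 0 + genotype, d)
    # closed-form BLUP with fixed variances (s2g = 1)
    V <- tcrossprod(Z) + s2e * diag(n)
    X <- matrix(1, n, 1)
    Vi <- solve(V)
    P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi
    sqrt(sum((t(Z) %*% P %*% d$y)^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("Cullis H2 identities and monotone degradation", {
  # construct an lmm_fit shell with controlled PEV
  mk <- function(pev, s2g) {
    tab <- data.frame(level = c("a", "b"), blup = c(0, 0), pev = diag(pev))
    attr(tab, "pev_matrix") <- pev
    structure(list(varcomp = c(genotype = s2g, residual = 1),
                   blups = list(genotype = tab)), class = "lmm_fit")
  }
  # vbar_delta = 0 -> H2 = 1
  expect_equal(cullis_h2(mk(matrix(c(1, 1, 1, 1), 2), 2)), 1)
  # vbar_delta = 2 s2g -> H2 = 0
  expect_equal(cullis_h2(mk(diag(2), 1)), 0)
  # dense-algebra oracle on a balanced toy
  set.seed(5)
  d <- expand.grid(genotype = factor(paste0("g", 1:6)), rep = factor(1:4))
  d$y <- rnorm(nrow(d), 0, 1) + rep(rnorm(6, 0, 2), 4)
  fit <- fit_reml(d, "y", fixed = ~1, random = list(genotype = "genotype"))
  pev <- attr(fit$blups$genotype, "pev_matrix")
  dg <- diag(pev)
  vd <- outer(dg, dg, `+`) - 2 * pev
  h2_hand <- 1 - mean(vd[upper.tri(vd)]) / (2 * fit$varcomp["genotype"])
  expect_equal(cullis_h2(fit), unname(h2_hand))
  # zero genotype variance -> H2 = 0 with warning
  d0 <- d; d0$y <- rnorm(nrow(d0))
  fit0 <- fit_reml(d0, "y", fixed = ~1, random = list(genotype = "genotype"))
  if (fit0$varcomp["genotype"] == 0) {
    expect_warning(h0 <- cullis_h2(fit0), "zero")
    expect_equal(h0, 0)
  }
  # inflating residual variance degrades H2 (same data, scaled noise)
  d2 <- d; set.seed(6); d2$y <- d$y + rnorm(nrow(d), 0, 4)
  fit2 <- fit_reml(d2, "y", fixed = ~1, random = list(genotype = "genotype"))
  expect_lt(cullis_h2(fit2), cullis_h2(fit))
})

test_that("variance partition proportions sum to one; planted GxE dominates", {
  set.seed(12)
  # direct second-stage simulation with dominant GxE
  g <- paste0("g", 1:10); loc <- paste0("L", 1:8); yr <- c(2021, 2022)
  d <- expand.grid(genotype = g, location = loc, year = yr)
  ge <- matrix(rnorm(80, 0, 30), 10, 8)
  d$blue <- 900 + rnorm(10, 0, 8)[match(d$genotype, g)] +
    ge[cbind(match(d$genotype, g), match(d$location, loc))] +
    rnorm(nrow(d), 0, 5)
  vp <- suppressMessages(variance_partition(d))
  expect_equal(sum(vp$proportion), 1, tolerance = 1e-10)
  nonres <- vp[vp$component != "residual", ]
  expect_equal(nonres$component[which.max(nonres$variance)], "gxe")
  # null term estimated near zero: year had no effect
  expect_lt(vp$variance[vp$component == "year"],
            0.2 * vp$variance[vp$component == "gxe"])
})

test_that("noise-free stage1 -> stage2 returns the planted genotype ranking", {
  cfg <- tiny_config(
    var_components = list(genotype = 250000, gxe = 0, block = 10000,
                          row = 0, col = 0, residual = 0),
    yield_cov_sd = 0, loc_sd = 0, env_sd = 0, seed = 8)
  net <- simulate_network(cfg)
  blues <- suppressWarnings(network_blues(net$plots))
  fit <- suppressMessages(suppressWarnings(stage2_fit(blues, "MET")))
  blup <- fit$blups$genotype
  truth <- net$truth$genotype_effects[blup$level]
  expect_equal(order(blup$blup), order(unname(truth)))
})
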