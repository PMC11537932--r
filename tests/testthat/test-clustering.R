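# K-means mega-environment delimitation, elbow rule, cluster means,
# centroid assignment, PCA, and allocation economics.

test_that("k-means recovers well-separated planted archetypes", {
  set.seed(40)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  X <- centers[rep(1:3, each = 8), ] + matrix(rnorm(48, 0, 0.5), 24, 2)
  rownames(X) <- paste0("L", 1:24)
  cl <- kmeans_fit(X, 3, seed = 1, n_init = 20)
  expect_equal(adjusted_rand(cl$assignments, rep(1:3, each = 8)), 1)
  # k = n -> WSS 0
  expect_equal(kmeans_fit(X[1:5, ], 5, seed = 1)$wss, 0)
  # identical rows, k = 1 -> centroid is the row, WSS 0
  X1 <- matrix(1, 4, 2, dimnames = list(paste0("L", 1:4), NULL))
  f1 <- kmeans_fit(X1, 1, seed = 1)
  expect_equal(f1$wss, 0)
  expect_equal(unname(f1$centroids[1, ]), c(1, 1))
  expect_error(kmeans_fit(X, 0), "k must be")
  expect_error(kmeans_fit(X, 99), "exceeds")
  # determinism under seed; cross-check WSS against stats::kmeans many-start
  cl2 <- kmeans_fit(X, 3, seed = 1, n_init = 20)
  expect_identical(cl$assignments, cl2$assignments)
  ref <- stats::kmeans(X, 3, nstart = 25)
  expect_equal(cl$wss, ref$tot.withinss, tolerance = 1e-8)
})

test_that("WSS trace is non-increasing and the elbow picks the planted k", {
  set.seed(41)
  centers <- matrix(c(0, 0, 8, 0, 0, 8, 8, 8, 4, 16), 5, 2, byrow = TRUE)
  X <- centers[rep(1:5, each = 6), ] + matrix(rnorm(60, 0, 0.4), 30, 2)
  rownames(X) <- paste0("L", 1:30)
  wss <- wss_trace(X, 8, seed = 2, n_init = 20)
  expect_true(all(diff(wss) <= 1e-8))
  expect_equal(as.integer(choose_k(wss)), 5)
  # single blob: trace monotone; chosen k small
  Xb <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("L", 1:30), NULL))
  wb <- wss_trace(Xb, 6, seed = 3, n_init = 20)
  expect_true(all(diff(wb) <= 1e-8))
  # k_max = 1 -> 1
  expect_equal(as.integer(choose_k(wss_trace(X, 1, seed = 1))), 1)
})

test_that("cluster adjusted means equal planted offsets on clean data", {
  g <- paste0("g", 1:6)
  locs <- paste0("L", 1:4)
  assign <- setNames(c(1, 1, 2, 2), locs)
  offs <- c(`1` = -300, `2` = 300)
  d <- expand.grid(location = locs, genotype = g)
  d$year <- 2021
  d$blue <- 9000 + offs[as.character(assign[d$location])]
  am <- suppressWarnings(suppressMessages(cluster_adjusted_means(d, assign)))
  expect_equal(am$mean[order(am$cluster)], c(8700, 9300), tolerance = 1e-4)
  # balanced data: adjusted means equal raw cluster means
  set.seed(42)
  d2 <- d; d2$blue <- d$blue + rep(rnorm(6, 0, 50), each = 4) +
    rnorm(nrow(d), 0, 20)
  am2 <- suppressMessages(cluster_adjusted_means(d2, assign))
  raw <- tapply(d2$blue, assign[d2$location], mean)
  expect_equal(am2$mean[order(am2$cluster)], as.numeric(raw),
               tolerance = 1e-4)
  expect_error(cluster_adjusted_means(d, assign[1:2]), "assigned")
})

test_that("site assignment matches a brute-force distance scan; ties logged", {
  set.seed(43)
  C <- matrix(rnorm(8), 4, 2)
  P <- matrix(rnorm(30), 15, 2)
  rownames(P) <- paste0("s", 1:15)
  a <- assign_sites(P, C)
  brute <- apply(P, 1, function(x) which.min(colSums((t(C) - x)^2)))
  expect_equal(unname(a), unname(brute))
  # profile equal to a centroid goes to it
  expect_equal(unname(assign_sites(C[2, , drop = FALSE], C)), 2)
  # equidistant profile -> lowest index, message
  Ct <- rbind(c(-1, 0), c(1, 0))
  expect_message(at <- assign_sites(matrix(0, 1, 2), Ct), "tie")
  expect_equal(unname(at), 1)
})

test_that("assign_sites reproduces kmeans assignments on training rows", {
  set.seed(44)
  X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 6), 10, 2))
  rownames(X) <- paste0("L", 1:20)
  cl <- kmeans_fit(X, 2, seed = 5, n_init = 10)
  expect_equal(assign_sites(X, cl$centroids), cl$assignments,
               ignore_attr = TRUE)
})

test_that("PCA summary: rank-1 fraction, reconstruction identity", {
  u <- rnorm(10); v <- rnorm(4)
  W <- outer(u, v)
  rownames(W) <- paste0("L", 1:10)
  p <- pca_summary(W)
  expect_equal(p$var_explained[1], 1, tolerance = 1e-10)
  # scores %*% t(loadings) reconstructs the centered matrix
  set.seed(45)
  W2 <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("L", 1:10), NULL))
  p2 <- pca_summary(W2)
  expect_lt(max(abs(p2$scores %*% t(p2$loadings) - scale(W2, scale = FALSE))),
            1e-8)
  expect_true(all(p2$var_explained >= 0 & p2$var_explained <= 1))
  expect_lte(sum(p2$var_explained), 1 + 1e-10)
})

test_that("economic importance and trial allocation sum to 100", {
  prod <- data.frame(county = c("A", "B", "C"),
                     production_share = c(0.5, 0.3, 0.2))
  a <- setNames(c(1, 1, 2), c("A", "B", "C"))
  ei <- economic_importance(prod, a)
  expect_equal(unname(ei), c(80, 20))
  expect_equal(sum(ei), 100, tolerance = 1e-9)
  # all in one cluster
  expect_equal(unname(economic_importance(prod, setNames(c(1, 1, 1),
                                                         c("A", "B", "C")))),
               100)
  # random table vs hand summation
  set.seed(46)
  prod2 <- data.frame(county = paste0("c", 1:20),
                      production_share = runif(20))
  prod2$production_share <- prod2$production_share /
    sum(prod2$production_share)
  a2 <- setNames(sample(1:3, 20, replace = TRUE), prod2$county)
  ei2 <- economic_importance(prod2, a2)
  hand <- 100 * tapply(prod2$production_share, a2[prod2$county], sum)
  expect_equal(unname(ei2), unname(as.numeric(hand)))

  # trial allocation: weighted counts toy
  counts <- setNames(c(10, 10, 20, 40), paste0("L", 1:4))
  at <- setNames(c(1, 1, 2, 3), paste0("L", 1:4))
  ta <- trial_allocation(counts, at)
  expect_equal(unname(ta), c(25, 25, 50))
  expect_equal(sum(ta), 100, tolerance = 1e-9)
  expect_equal(unname(trial_allocation(counts, setNames(rep(1, 4),
                                                        paste0("L", 1:4)))),
               100)
})

test_that("allocation percentages follow from the partition sizes", {
  # 18 locations, one trial each, clusters of sizes 7/9/1/1
  counts <- setNames(rep(1, 18), paste0("L", 1:18))
  a <- setNames(rep(1:4, times = c(7, 9, 1, 1)), paste0("L", 1:18))
  ta <- trial_allocation(counts, a)
  expect_equal(round(unname(ta), 1), c(38.9, 50.0, 5.6, 5.6))
})

test_that("two-step TPE delimitation drops a small remote outlier group", {
  set.seed(47)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 8))
  main <- centers[rep(1:3, each = 20), ] + matrix(rnorm(120, 0, 0.8), 60, 2)
  outlier <- matrix(rnorm(8, 0, 0.5), 4, 2) +
    matrix(c(40, 40), 4, 2, byrow = TRUE)
  X <- rbind(main, outlier)
  rownames(X) <- paste0("c", 1:64)
  res <- tpe_delimit(X, k_max = 6, seed = 1, n_init = 20)
  expect_true(all(paste0("c", 61:64) %in% res$outliers))
  expect_equal(res$k, 3)
  expect_equal(adjusted_rand(
    res$model$assignments[paste0("c", 1:60)],
    rep(1:3, each = 20)), 1)
})
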