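# Mega-environment delimitation: k-means with k-means++ seeding, elbow choice
# of k, cluster adjusted means, centroid assignment of new sites, PCA
# summaries, and the economics of trial allocation across target populations
# of environments (TPEs).

# k-means++ initial centers (on rows of X), drawn with R's RNG
.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  if (k > 1) {
    d2 <- colSums((t(X) - centers[1, ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        pick <- sample.int(n, 1)
      } else {
        pick <- sample.int(n, 1, prob = d2)
      }
      centers[j, ] <- X[pick, ]
      d2 <- pmin(d2, colSums((t(X) - centers[j, ])^2))
    }
  }
  centers
}

#' K-means clustering of environments
#'
#' Lloyd's algorithm with k-means++ seeding, repeated over `n_init` starts;
#' the start with the lowest total within-cluster sum of squares (WSS) wins.
#' Deterministic given `seed`.
#'
#' @param W matrix of (scaled) covariates, rows = environments
#' @param k number of clusters, `1 <= k <= nrow(W)`
#' @param seed integer seed
#' @param n_init number of independent starts
#' @param max_iter Lloyd iteration cap per start
#' @return A `cluster_model`: `k`, `assignments` (named), `centroids`,
#'   `wss` (total within-cluster SS), `seed`, `n_init`.
#' @export
kmeans_fit <- function(W, k, seed = 1, n_init = 50, max_iter = 300) {
  X <- as.matrix(W)
  if (k < 1) stop("kmeans_fit: k must be >= 1")
  if (k > nrow(X)) stop("kmeans_fit: k exceeds the number of environments")
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    centers <- .kmeanspp_centers(X, k)
    km <- suppressWarnings(stats::kmeans(X, centers = centers,
                                         iter.max = max_iter,
                                         algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  structure(list(
    k = k,
    assignments = stats::setNames(best$cluster, rownames(X)),
    centroids = best$centers,
    wss = best$tot.withinss,
    wss_per_cluster = best$withinss,
    seed = seed, n_init = n_init
  ), class = "cluster_model")
}

#' Within-cluster sum-of-squares trace over candidate k
#'
#' @param W matrix of (scaled) covariates
#' @param k_max largest k to evaluate
#' @inheritParams kmeans_fit
#' @return Named numeric vector `wss[k]`, k = 1..k_max (non-increasing).
#' @export
wss_trace <- function(W, k_max, seed = 1, n_init = 50, max_iter = 300) {
  k_max <- min(k_max, nrow(as.matrix(W)))
  wss <- vapply(seq_len(k_max), function(k) {
    kmeans_fit(W, k, seed = seed + k, n_init = n_init,
               max_iter = max_iter)$wss
  }, numeric(1))
  stats::setNames(wss, seq_len(k_max))
}

#' Choose the number of clusters from a WSS trace
#'
#' Elbow rule: the chosen k is the smallest k whose WSS drop to k+1 falls
#' below `drop_frac` (default 10%) of the k=1 to k=2 drop. Returns `k_max` if
#' every drop stays large, and 1 when the trace is flat.
#'
#' @param wss WSS trace from [wss_trace()] (index k = 1..k_max)
#' @param drop_frac threshold as a fraction of the first drop
#' @return Chosen k (integer); the full trace is attached as an attribute.
#' @export
choose_k <- function(wss, drop_frac = 0.1) {
  k_max <- length(wss)
  if (k_max == 1) return(structure(1L, trace = wss))
  drops <- -diff(wss)
  if (drops[1] <= 0) return(structure(1L, trace = wss))
  small <- which(drops < drop_frac * drops[1])
  k <- if (length(small) == 0) k_max else as.integer(small[1])
  structure(k, trace = wss)
}

#' Cluster adjusted means of grain yield
#'
#' Fits the cluster model on stage-1 BLUEs — cluster fixed (cell means),
#' genotype random, genotype-by-cluster interaction random — and returns each
#' cluster's adjusted mean yield on the response scale.
#'
#' @param blues BLUE table ([stage1_blues()] format)
#' @param assignments named cluster id per location
#' @return data frame: `cluster`, `mean` (kg/ha), `se`.
#' @export
cluster_adjusted_means <- function(blues, assignments) {
  if (!all(unique(blues$location) %in% names(assignments))) {
    stop("cluster_adjusted_means: every location must be assigned")
  }
  counts <- table(assignments[blues$location])
  if (any(counts == 0)) stop("cluster_adjusted_means: empty cluster")
  fit <- stage2_fit(blues, variant = "CLUSTER", assignments = assignments)
  data.frame(
    cluster = sub("^clustercluster", "", names(fit$beta)),
    mean = as.numeric(fit$beta), se = as.numeric(fit$beta_se),
    stringsAsFactors = FALSE
  )
}

#' Assign sites to clusters by nearest centroid
#'
#' Each profile goes to the centroid at minimum Euclidean distance in the
#' scaled covariate space; exact ties go to the lowest cluster index (logged
#' via a message).
#'
#' @param profiles matrix of scaled covariate profiles (rows = sites),
#'   columns matching the centroids
#' @param centroids matrix of cluster centroids (e.g. from [kmeans_fit()])
#' @return Named integer vector of cluster assignments.
#' @export
assign_sites <- function(profiles, centroids) {
  P <- as.matrix(profiles)
  C <- as.matrix(centroids)
  if (ncol(P) != ncol(C)) stop("assign_sites: column mismatch with centroids")
  if (!is.null(colnames(P)) && !is.null(colnames(C))) {
    if (!all(colnames(C) %in% colnames(P))) {
      stop("assign_sites: profiles lack centroid covariates")
    }
    P <- P[, colnames(C), drop = FALSE]
  }
  out <- integer(nrow(P))
  for (i in seq_len(nrow(P))) {
    d2 <- rowSums((C - matrix(P[i, ], nrow(C), ncol(C), byrow = TRUE))^2)
    hits <- which(d2 == min(d2))
    if (length(hits) > 1) {
      message("assign_sites: tie for site ", i, "; lowest cluster index used")
    }
    out[i] <- hits[1]
  }
  stats::setNames(out, rownames(P))
}

#' Principal component summary of the covariate matrix
#'
#' @param W (scaled) covariate matrix
#' @return A `pca_summary` list: `scores` (environments x components),
#'   `loadings` (covariates x components), `var_explained` (fractions).
#' @export
pca_summary <- function(W) {
  X <- unclass(as.matrix(W))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  structure(list(
    scores = pc$x, loadings = pc$rotation,
    var_explained = pc$sdev^2 / sum(pc$sdev^2)
  ), class = "pca_summary")
}

#' Economic importance of TPE clusters
#'
#' Sums county production shares within clusters, as percentages.
#'
#' @param production data frame with `county` and `production_share`
#' @param assignments named cluster id per county
#' @return Named numeric vector of per-cluster production percentages
#'   (sums to 100).
#' @export
economic_importance <- function(production, assignments) {
  stopifnot(all(c("county", "production_share") %in% names(production)))
  if (!all(production$county %in% names(assignments))) {
    stop("economic_importance: every county must be assigned")
  }
  cl <- assignments[production$county]
  shares <- tapply(production$production_share, cl, sum)
  out <- 100 * shares / sum(production$production_share)
  stats::setNames(as.numeric(out), names(out))
}

#' Trial share per cluster
#'
#' Percentage of trials falling in each cluster, from per-location trial
#' counts.
#'
#' @param trial_counts named numeric, trials per location
#' @param assignments named cluster id per location
#' @return Named numeric vector of per-cluster trial percentages
#'   (sums to 100).
#' @export
trial_allocation <- function(trial_counts, assignments) {
  if (!all(names(trial_counts) %in% names(assignments))) {
    stop("trial_allocation: every location must be assigned")
  }
  cl <- assignments[names(trial_counts)]
  tot <- tapply(as.numeric(trial_counts), cl, sum)
  out <- 100 * tot / sum(trial_counts)
  stats::setNames(as.numeric(out), names(out))
}

#' Two-step TPE delimitation with outlier-cluster removal
#'
#' Clusters all county profiles, flags any cluster that is both small
#' (at most `size_frac` of counties) and remote (its centroid farther from
#' the nearest other centroid than `dist_mult` times the pooled
#' within-cluster RMS spread of the remaining clusters), drops the flagged
#' counties, and re-clusters the remainder. This mirrors the practice of
#' first detecting an environmentally isolated production region and then
#' delimiting the TPEs of the homogeneous rest.
#'
#' @param profiles scaled covariate profiles (rows = counties)
#' @param k_max largest k scanned in each step
#' @param size_frac,dist_mult outlier-cluster thresholds
#' @param seed,n_init passed to the k-means fits
#' @return list: `first` (initial `cluster_model`), `outliers` (dropped row
#'   ids), `model` (final `cluster_model` on the retained profiles), `k`.
#' @export
tpe_delimit <- function(profiles, k_max = 8, size_frac = 0.15, dist_mult = 2,
                        seed = 1, n_init = 50) {
  P <- as.matrix(profiles)
  k1 <- choose_k(wss_trace(P, k_max, seed = seed, n_init = n_init))
  first <- kmeans_fit(P, max(as.integer(k1), 2L), seed = seed, n_init = n_init)
  sizes <- as.numeric(table(factor(first$assignments,
                                   levels = seq_len(first$k))))
  cd <- as.matrix(stats::dist(first$centroids))
  diag(cd) <- Inf
  nearest <- apply(cd, 1, min)
  flagged <- integer(0)
  for (k in seq_len(first$k)) {
    if (sizes[k] > size_frac * nrow(P)) next
    other_n <- sum(sizes[-k])
    rms_other <- sqrt(sum(first$wss_per_cluster[-k]) / max(other_n, 1))
    if (rms_other == 0 || nearest[k] > dist_mult * rms_other) {
      flagged <- c(flagged, k)
    }
  }
  outliers <- names(first$assignments)[first$assignments %in% flagged]
  keep <- setdiff(rownames(P), outliers)
  P2 <- P[keep, , drop = FALSE]
  k2 <- choose_k(wss_trace(P2, min(k_max, nrow(P2)), seed = seed,
                           n_init = n_init))
  model <- kmeans_fit(P2, as.integer(k2), seed = seed, n_init = n_init)
  list(first = first, outliers = outliers, model = model,
       k = as.integer(k2))
}
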