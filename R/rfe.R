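#' Recursive feature elimination with a random-forest learner
#'
#' Selects the environmental covariates most predictive of environment-level
#' mean yield. The outer loop is repeated K-fold cross-validation over
#' environments (5 folds x 5 repeats by default). Within each resample a
#' random forest is fitted on the training environments with all candidate
#' covariates, covariates are ranked by impurity importance, and for each
#' candidate subset size the forest is refitted on the top-ranked covariates
#' and evaluated on the held-out environments. The chosen size maximizes the
#' mean cross-validated R2; the final model is refitted on all environments at
#' that size using the full-data ranking.
#'
#' R2 is computed per repeat as `1 - SSE/SST` over the pooled held-out
#' predictions (it can be negative for models worse than the mean), then
#' averaged over repeats. Both the cross-validated R2 (the headline) and the
#' training R2 of the final model are reported.
#'
#' @param W covariate matrix (rows = environments), e.g. from [build_W()]
#'   after [filter_collinear()]
#' @param env_response named numeric, per-environment response — typically the
#'   per-environment mean of stage-1 genotype BLUEs ([env_mean_response()])
#' @param folds,repeats cross-validation configuration
#' @param subset_sizes candidate subset sizes; default
#'   `{2,4,6,8,10,12,16,24,32,p}` intersected with `1..p`
#' @param seed integer seed controlling fold assignment and forests
#' @param ntree trees per forest
#' @return An `rfe_result` list: `selected`, `chosen_size`, `sizes`,
#'   `cv_r2` (mean per size), `cv_r2_se`, `importance` (full-data fit),
#'   `train_r2`, `final_model`, `config`.
#' @export
rfe_select <- function(W, env_response, folds = 5, repeats = 5,
                       subset_sizes = NULL, seed = 1, ntree = 500) {
  W <- as.matrix(W)
  if (!is.null(names(env_response)) && !is.null(rownames(W))) {
    if (!all(rownames(W) %in% names(env_response))) {
      stop("rfe_select: response missing for some environments")
    }
    env_response <- env_response[rownames(W)]
  }
  n <- nrow(W)
  p <- ncol(W)
  if (n < folds) stop("rfe_select: fewer environments than folds")
  if (is.null(subset_sizes)) {
    subset_sizes <- unique(pmin(c(2, 4, 6, 8, 10, 12, 16, 24, 32, p), p))
  }
  subset_sizes <- sort(unique(as.integer(subset_sizes)))
  if (length(subset_sizes) == 0) stop("rfe_select: empty subset_sizes")
  if (any(subset_sizes < 1 | subset_sizes > p)) {
    stop("rfe_select: subset sizes must be in 1..ncol(W)")
  }
  y <- as.numeric(env_response)

  set.seed(seed)
  r2_mat <- matrix(NA_real_, repeats, length(subset_sizes))
  for (r in seq_len(repeats)) {
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    preds <- matrix(NA_real_, n, length(subset_sizes))
    for (f in seq_len(folds)) {
      test <- fold_id == f
      rf_all <- random_forest(W[!test, , drop = FALSE], y[!test],
                              ntree = ntree)
      ranking <- order(rf_all$importance, decreasing = TRUE)
      for (si in seq_along(subset_sizes)) {
        s <- subset_sizes[si]
        top <- ranking[seq_len(s)]
        rf_s <- random_forest(W[!test, top, drop = FALSE], y[!test],
                              ntree = ntree)
        preds[test, si] <- predict(rf_s, W[test, top, drop = FALSE])
      }
    }
    sst <- sum((y - mean(y))^2)
    r2_mat[r, ] <- 1 - colSums((preds - y)^2) / sst
  }
  cv_r2 <- colMeans(r2_mat)
  cv_r2_se <- apply(r2_mat, 2, stats::sd) / sqrt(repeats)
  chosen <- subset_sizes[which.max(cv_r2)]

  rf_full <- random_forest(W, y, ntree = ntree)
  full_rank <- order(rf_full$importance, decreasing = TRUE)
  selected <- colnames(W)[full_rank[seq_len(chosen)]]
  rf_final <- random_forest(W[, selected, drop = FALSE], y, ntree = ntree)
  fitted <- predict(rf_final, W[, selected, drop = FALSE])
  train_r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)

  structure(list(
    selected = selected, chosen_size = chosen, sizes = subset_sizes,
    cv_r2 = stats::setNames(cv_r2, subset_sizes),
    cv_r2_se = stats::setNames(cv_r2_se, subset_sizes),
    cv_r2_by_repeat = r2_mat,
    importance = rf_full$importance, train_r2 = train_r2,
    final_model = rf_final,
    config = list(folds = folds, repeats = repeats, ntree = ntree,
                  seed = seed)
  ), class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat("RFE (random forest,", x$config$folds, "folds x", x$config$repeats,
      "repeats):", x$chosen_size, "covariates selected\n")
  cat("  CV R2 at chosen size:",
      round(x$cv_r2[as.character(x$chosen_size)], 3),
      "| training R2 of final model:", round(x$train_r2, 3), "\n")
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Per-environment mean response from stage-1 BLUEs
#'
#' Averages genotype BLUEs within each location, giving the environment-level
#' yield response used by [rfe_select()].
#'
#' @param blues a BLUE table from [stage1_blues()] (columns `location`,
#'   `genotype`, `blue`)
#' @return Named numeric vector, one mean BLUE per location.
#' @export
env_mean_response <- function(blues) {
  stopifnot(all(c("location", "blue") %in% names(blues)))
  tapply(blues$blue, blues$location, mean)
}
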