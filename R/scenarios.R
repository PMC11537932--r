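# Evaluation scenarios for trial-network optimization: joint-model variants,
# Cullis heritability per scenario, phenotyping costs, heritability per
# dollar, and the two trial-reduction simulations.

# round half-up to `digits` decimals (report parity for percentages)
.round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Phenotyping cost model
#'
#' @param n_genotypes,n_replicates,n_locations,n_years network dimensions
#' @param price_per_plot phenotyping cost per plot (USD)
#' @param price_per_genotyped_line genotyping cost per line (USD)
#' @return A `cost_model` list.
#' @export
cost_model <- function(n_genotypes, n_replicates, price_per_plot = 25,
                       n_locations = NULL, n_years = NULL,
                       price_per_genotyped_line = 6) {
  vals <- c(n_genotypes, n_replicates, price_per_plot,
            n_locations, n_years, price_per_genotyped_line)
  if (any(vals <= 0)) stop("cost_model: all fields must be positive")
  structure(list(n_genotypes = n_genotypes, n_replicates = n_replicates,
                 price_per_plot = price_per_plot, n_locations = n_locations,
                 n_years = n_years,
                 price_per_genotyped_line = price_per_genotyped_line),
            class = "cost_model")
}

#' Total phenotyping cost of a trial network
#'
#' genotypes x replicates x price per plot x locations x years.
#'
#' @param cm a [cost_model()] with `n_locations` and `n_years` set
#' @return Cost in USD.
#' @export
trial_cost <- function(cm) {
  stopifnot(inherits(cm, "cost_model"))
  if (is.null(cm$n_locations) || is.null(cm$n_years)) {
    stop("trial_cost: n_locations and n_years required")
  }
  cm$n_genotypes * cm$n_replicates * cm$price_per_plot *
    cm$n_locations * cm$n_years
}

#' Heritability per dollar invested
#'
#' @param h2 heritability
#' @param cost total cost (USD, > 0)
#' @return `h2 / cost` (1/USD).
#' @export
h2_per_dollar <- function(h2, cost) {
  if (cost <= 0) stop("h2_per_dollar: cost must be positive")
  h2 / cost
}

.scenario_result <- function(scenario, h2, h2_sd = NA_real_, cost = NA_real_,
                             detail = NULL, fit = NULL) {
  structure(list(scenario = scenario, h2 = h2, h2_sd = h2_sd, cost = cost,
                 h2_per_dollar = if (is.na(cost)) NA_real_ else
                   h2_per_dollar(h2, cost),
                 detail = detail, fit = fit),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(x$scenario, ": H2 =", round(x$h2, 4),
      if (!is.na(x$h2_sd)) paste("+/-", round(x$h2_sd, 4)) else "",
      if (!is.na(x$cost)) paste("| cost $", format(x$cost, big.mark = ","),
                                "| H2/$ =", format(x$h2_per_dollar,
                                                   digits = 4)) else "",
      "\n")
  invisible(x)
}

.check_blues <- function(blues) {
  if (length(unique(blues$genotype)) < 2) {
    stop("scenario: need >= 2 genotypes")
  }
}

#' Scenario I: multi-environment model (MET)
#'
#' The complete joint model with identity genotype-by-environment covariance.
#'
#' @param blues BLUE table ([stage1_blues()] format)
#' @param cm optional [cost_model()] for the cost and H2-per-dollar columns
#' @return A `scenario_result`.
#' @export
run_met <- function(blues, cm = NULL) {
  .check_blues(blues)
  fit <- stage2_fit(blues, "MET")
  .scenario_result("MET", cullis_h2(fit),
                   cost = if (is.null(cm)) NA_real_ else trial_cost(cm),
                   fit = fit)
}

#' Scenario II: MET with enviromic kernel (MET_EC)
#'
#' @inheritParams run_met
#' @param omega enviromic kernel from [env_kernel()] (locations as rows)
#' @return A `scenario_result`.
#' @export
run_met_ec <- function(blues, omega, cm = NULL) {
  .check_blues(blues)
  fit <- stage2_fit(blues, "MET_EC", kernel = omega)
  .scenario_result("MET_EC", cullis_h2(fit),
                   cost = if (is.null(cm)) NA_real_ else trial_cost(cm),
                   fit = fit)
}

#' Scenario III: within-cluster MET (WC_MET)
#'
#' Fits the MET model separately inside each cluster and reports the
#' unweighted mean and SD of the per-cluster Cullis heritabilities. Clusters
#' with a single environment cannot support the model and are excluded with
#' a warning.
#'
#' @inheritParams run_met
#' @param assignments named cluster id per location
#' @return A `scenario_result`; `detail` holds per-cluster H2.
#' @export
run_wc_met <- function(blues, assignments, cm = NULL) {
  .check_blues(blues)
  if (!all(unique(blues$location) %in% names(assignments))) {
    stop("run_wc_met: every location must be assigned")
  }
  clusters <- sort(unique(assignments[unique(blues$location)]))
  h2s <- c()
  for (cl in clusters) {
    locs <- names(assignments)[assignments == cl]
    locs <- intersect(locs, unique(blues$location))
    sub <- blues[blues$location %in% locs, , drop = FALSE]
    n_env <- length(unique(paste(sub$location, sub$year)))
    if (n_env < 2) {
      warning("run_wc_met: cluster ", cl,
              " has a single environment; excluded")
      next
    }
    fit <- stage2_fit(blues, "WC", subset = locs)
    h2s[as.character(cl)] <- cullis_h2(fit)
  }
  if (length(h2s) == 0) stop("run_wc_met: no cluster with >= 2 environments")
  .scenario_result("WC_MET", mean(h2s),
                   h2_sd = if (length(h2s) > 1) stats::sd(h2s) else 0,
                   cost = if (is.null(cm)) NA_real_ else trial_cost(cm),
                   detail = h2s)
}

#' Scenario IV: optimized MET (OPT_MET)
#'
#' Samples one location per cluster (uniformly, without replacement within
#' cluster), fits the MET model on the sampled subset, and repeats
#' `n_reps` times; reports the mean and SD of the replicate heritabilities.
#'
#' @inheritParams run_wc_met
#' @param n_reps number of sampling replicates
#' @param seed integer seed for the location draws
#' @return A `scenario_result`; `detail` holds per-replicate H2 and the
#'   sampled locations.
#' @export
run_opt_met <- function(blues, assignments, n_reps = 10, seed = 1, cm = NULL) {
  .check_blues(blues)
  if (n_reps < 1) stop("run_opt_met: n_reps must be >= 1")
  if (!all(unique(blues$location) %in% names(assignments))) {
    stop("run_opt_met: every location must be assigned")
  }
  assignments <- assignments[names(assignments) %in% unique(blues$location)]
  clusters <- sort(unique(assignments))
  set.seed(seed)
  h2s <- numeric(n_reps)
  picks <- vector("list", n_reps)
  for (h in seq_len(n_reps)) {
    locs <- vapply(clusters, function(cl) {
      cands <- names(assignments)[assignments == cl]
      if (length(cands) == 1) cands else sample(cands, 1)
    }, character(1))
    picks[[h]] <- locs
    fit <- stage2_fit(blues, "OPT", subset = locs)
    h2s[h] <- cullis_h2(fit)
  }
  .scenario_result("OPT_MET", mean(h2s),
                   h2_sd = if (n_reps > 1) stats::sd(h2s) else 0,
                   cost = if (is.null(cm)) NA_real_ else trial_cost(cm),
                   detail = list(h2 = h2s, locations = picks))
}

#' Percent reduction from keeping a subset of locations
#'
#' `100 * (1 - n_selected / n_total)`, reported half-up to one decimal.
#'
#' @param n_selected,n_total retained and total counts
#' @return Percentage reduction.
#' @export
reduction_advanced <- function(n_selected, n_total) {
  stopifnot(n_total > 0, n_selected >= 0, n_selected <= n_total)
  .round_half_up(100 * (1 - n_selected / n_total), 1)
}

#' Simulated trial reduction across a whole network
#'
#' Each iteration samples one location per cluster, sums the historical trial
#' counts of the sampled locations, and computes the percentage reduction
#' relative to the total trial count; the mean over iterations is reported.
#'
#' @param trial_counts named numeric, historical trials per location
#' @param assignments named cluster id per location
#' @param n_iters sampling iterations
#' @param seed integer seed
#' @return list: `mean_reduction` (%), `mean_retained` (trials), `per_iter`.
#' @export
reduction_network <- function(trial_counts, assignments, n_iters = 10,
                              seed = 1) {
  if (n_iters < 1) stop("reduction_network: n_iters must be >= 1")
  if (!all(names(trial_counts) %in% names(assignments))) {
    stop("reduction_network: every location must be assigned")
  }
  total <- sum(trial_counts)
  clusters <- sort(unique(assignments[names(trial_counts)]))
  set.seed(seed)
  retained <- numeric(n_iters)
  for (i in seq_len(n_iters)) {
    locs <- vapply(clusters, function(cl) {
      cands <- intersect(names(assignments)[assignments == cl],
                         names(trial_counts))
      if (length(cands) == 1) cands else sample(cands, 1)
    }, character(1))
    retained[i] <- sum(trial_counts[locs])
  }
  list(mean_reduction = .round_half_up(100 * (1 - mean(retained) / total), 1),
       mean_retained = mean(retained),
       per_iter = 100 * (1 - retained / total))
}

#' Reallocation of phenotyping savings
#'
#' Translates a cost saving into the extra capacity it buys at an earlier
#' breeding stage: additional plots (`savings / price_per_plot`), additional
#' phenotyped genotypes (`plots / n_replicates`), and additional genotyped
#' lines (`savings / price_per_genotyped_line`).
#'
#' @param savings USD saved (>= 0)
#' @param cm a [cost_model()]
#' @return list: `plots`, `genotypes`, `lines`.
#' @export
reallocation_report <- function(savings, cm) {
  stopifnot(inherits(cm, "cost_model"), savings >= 0)
  plots <- savings / cm$price_per_plot
  list(plots = plots,
       genotypes = plots / cm$n_replicates,
       lines = savings / cm$price_per_genotyped_line)
}
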