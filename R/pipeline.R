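# End-to-end pipeline: simulate (optional) -> stage-1 BLUEs -> W build/QC ->
# RFE -> Omega -> clustering -> scenarios -> TPE report, with every artifact
# written to disk and a manifest of checksums and seeds.

#' Pipeline configuration
#'
#' Collects the stage settings and seeds of [run_pipeline()]. Every
#' stochastic stage has an explicit seed derived from `seed` so a rerun with
#' the same configuration is byte-identical (manifest checksums match).
#'
#' @param out_dir artifact directory (created if needed)
#' @param seed master seed; per-stage seeds are derived from it
#' @param sim a [sim_config()] (its own seed is overridden by `seed`)
#' @param cardinal a [cardinal_temps()]
#' @param collinearity_threshold threshold for [filter_collinear()]
#' @param rfe_folds,rfe_repeats,rfe_ntree RFE settings
#' @param k_max largest k scanned when choosing the cluster count
#' @param kmeans_n_init k-means starts
#' @param opt_reps OPT_MET sampling replicates
#' @param price_per_plot,price_per_genotyped_line cost rates (USD)
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("enviromet_"), seed = 1,
                            sim = sim_config(),
                            cardinal = cardinal_temps(),
                            collinearity_threshold = 0.95,
                            rfe_folds = 5, rfe_repeats = 5, rfe_ntree = 500,
                            k_max = 8, kmeans_n_init = 50, opt_reps = 10,
                            price_per_plot = 25,
                            price_per_genotyped_line = 6) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 cardinal = cardinal,
                 collinearity_threshold = collinearity_threshold,
                 rfe_folds = rfe_folds, rfe_repeats = rfe_repeats,
                 rfe_ntree = rfe_ntree, k_max = k_max,
                 kmeans_n_init = kmeans_n_init, opt_reps = opt_reps,
                 price_per_plot = price_per_plot,
                 price_per_genotyped_line = price_per_genotyped_line),
            class = "pipeline_config")
}

#' Run the full trial-network optimization pipeline
#'
#' Executes, in order: synthetic-network simulation, stage-1 BLUEs, covariate
#' matrix construction and collinearity QC, recursive feature elimination,
#' enviromic kernel, mega-environment clustering, the four evaluation
#' scenarios with costs, the reduction simulations, the TPE economic report,
#' and the enviromic-vs-yield kernel comparison. Each stage's artifact is
#' written to `config$out_dir`; `manifest.json` records seeds and md5
#' checksums of every artifact.
#'
#' @param config a [pipeline_config()]
#' @return Invisibly, a list with the in-memory results of every stage and
#'   `artifacts` (named file paths).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(config$out_dir, f)
  paths <- c()

  # 1. simulate
  sim_cfg <- config$sim
  sim_cfg$seed <- config$seed
  net <- simulate_network(sim_cfg)
  write_plots(net$plots, art("plots.csv")); paths["plots"] <- art("plots.csv")
  write_weather(net$weather, art("weather.csv"))
  paths["weather"] <- art("weather.csv")
  write_soil(net$soil, art("soil.csv")); paths["soil"] <- art("soil.csv")
  write_production(net$production, art("production.csv"))
  paths["production"] <- art("production.csv")
  jsonlite::write_json(
    list(var_components = net$truth$var_components,
         informative = net$truth$informative$id,
         cluster_assignments = as.list(net$truth$cluster_assignments)),
    art("truth.json"), auto_unbox = TRUE, digits = NA)
  paths["truth"] <- art("truth.json")

  # 2. stage-1 BLUEs
  blues <- network_blues(net$plots)
  write_blues(blues, art("blues.csv")); paths["blues"] <- art("blues.csv")

  # 3. covariate matrix + QC
  ws <- summarize_stage(net$weather, cardinal = config$cardinal)
  W <- build_W(ws, net$soil)
  W <- filter_collinear(W, config$collinearity_threshold)
  write_matrix_csv(W, art("W.csv")); paths["W"] <- art("W.csv")
  jsonlite::write_json(attr(W, "scaling"), art("scaling.json"),
                       auto_unbox = TRUE, digits = NA)
  paths["scaling"] <- art("scaling.json")

  # 4. RFE
  resp <- env_mean_response(blues)
  rfe <- rfe_select(W, resp, folds = config$rfe_folds,
                    repeats = config$rfe_repeats, ntree = config$rfe_ntree,
                    seed = config$seed + 1)
  jsonlite::write_json(
    list(selected = rfe$selected, chosen_size = rfe$chosen_size,
         sizes = rfe$sizes, cv_r2 = as.list(rfe$cv_r2),
         train_r2 = rfe$train_r2, importance = as.list(rfe$importance),
         config = rfe$config),
    art("rfe.json"), auto_unbox = TRUE, digits = NA)
  paths["rfe"] <- art("rfe.json")
  W_sel <- W[, rfe$selected, drop = FALSE]

  # 5. kernels
  omega <- env_kernel(W_sel)
  write_matrix_csv(omega, art("omega.csv")); paths["omega"] <- art("omega.csv")
  omega_y <- yield_kernel(blues)
  write_matrix_csv(omega_y, art("omega_yield.csv"))
  paths["omega_yield"] <- art("omega_yield.csv")
  comp <- compare_kernels(omega, omega_y)
  jsonlite::write_json(list(pearson_r = comp$r, density = comp$density),
                       art("kernel_comparison.json"), auto_unbox = TRUE,
                       digits = NA)
  paths["kernel_comparison"] <- art("kernel_comparison.json")

  # 6. clustering of the trial network
  wss <- wss_trace(W_sel, min(config$k_max, nrow(W_sel) - 1),
                   seed = config$seed + 2, n_init = config$kmeans_n_init)
  k <- as.integer(choose_k(wss))
  cl <- kmeans_fit(W_sel, k, seed = config$seed + 3,
                   n_init = config$kmeans_n_init)
  write_clusters(cl$assignments, art("clusters.csv"))
  paths["clusters"] <- art("clusters.csv")
  write_matrix_csv(cl$centroids, art("centroids.csv"))
  paths["centroids"] <- art("centroids.csv")
  .write_table(data.frame(k = seq_along(wss), wss = as.numeric(wss)),
               art("wss.csv"))
  paths["wss"] <- art("wss.csv")
  pca <- pca_summary(W_sel)
  write_matrix_csv(pca$scores, art("pca_scores.csv"))
  paths["pca_scores"] <- art("pca_scores.csv")
  write_matrix_csv(pca$loadings, art("pca_loadings.csv"))
  paths["pca_loadings"] <- art("pca_loadings.csv")

  # 7. scenarios + economics
  n_loc <- length(unique(blues$location))
  n_yr <- length(unique(blues$year))
  n_gen <- length(unique(blues$genotype))
  cm_full <- cost_model(n_gen, sim_cfg$n_blocks,
                        price_per_plot = config$price_per_plot,
                        n_locations = n_loc, n_years = n_yr,
                        price_per_genotyped_line =
                          config$price_per_genotyped_line)
  cm_opt <- cost_model(n_gen, sim_cfg$n_blocks,
                       price_per_plot = config$price_per_plot,
                       n_locations = k, n_years = n_yr,
                       price_per_genotyped_line =
                         config$price_per_genotyped_line)
  sc <- list(
    MET = run_met(blues, cm_full),
    MET_EC = run_met_ec(blues, omega, cm_full),
    WC_MET = run_wc_met(blues, cl$assignments, cm_full),
    OPT_MET = run_opt_met(blues, cl$assignments, n_reps = config$opt_reps,
                          seed = config$seed + 4, cm = cm_opt)
  )
  jsonlite::write_json(
    lapply(sc, function(s) list(h2 = s$h2, h2_sd = s$h2_sd, cost = s$cost,
                                h2_per_dollar = s$h2_per_dollar)),
    art("scenarios.json"), auto_unbox = TRUE, digits = NA)
  paths["scenarios"] <- art("scenarios.json")

  savings <- sc$MET$cost - sc$OPT_MET$cost
  env_tab <- unique(blues[, c("location", "year")])
  counts_loc <- tapply(rep(1, nrow(env_tab)), env_tab$location, sum)
  red <- list(
    advanced = reduction_advanced(k, n_loc),
    retained_share = .round_half_up(100 * k / n_loc, 1),
    network = reduction_network(counts_loc, cl$assignments,
                                n_iters = config$opt_reps,
                                seed = config$seed + 5),
    savings = savings,
    reallocation = reallocation_report(savings, cm_full)
  )
  jsonlite::write_json(red, art("reductions.json"), auto_unbox = TRUE,
                       digits = NA)
  paths["reductions"] <- art("reductions.json")

  # 8. TPE delimitation + economics on county profiles
  prof_cols <- intersect(colnames(net$production), rfe$selected)
  tpe_report <- NULL
  if (length(prof_cols) >= 2) {
    prof <- as.matrix(net$production[, prof_cols, drop = FALSE])
    rownames(prof) <- net$production$county
    prof <- scale(prof)
    tpe <- tpe_delimit(prof, k_max = config$k_max, seed = config$seed + 6,
                       n_init = config$kmeans_n_init)
    econ <- economic_importance(
      net$production[net$production$county %in%
                       names(tpe$model$assignments), , drop = FALSE],
      tpe$model$assignments)
    # network coverage: assign trial locations to the TPE centroids
    loc_prof <- net$truth$informative_profile[, prof_cols, drop = FALSE]
    loc_prof <- scale(loc_prof,
                      center = attr(prof, "scaled:center"),
                      scale = attr(prof, "scaled:scale"))
    site_assign <- assign_sites(loc_prof, tpe$model$centroids)
    trials <- trial_allocation(
      stats::setNames(rep(n_yr, n_loc), rownames(loc_prof)), site_assign)
    tpe_report <- list(k = tpe$k, outliers = tpe$outliers,
                       production_pct = as.list(econ),
                       trial_pct = as.list(trials))
    jsonlite::write_json(tpe_report, art("tpe.json"), auto_unbox = TRUE,
                         digits = NA)
    paths["tpe"] <- art("tpe.json")
  }

  manifest <- list(
    seed = config$seed,
    stage_seeds = list(simulate = config$seed, rfe = config$seed + 1,
                       wss = config$seed + 2, kmeans = config$seed + 3,
                       opt_met = config$seed + 4, network = config$seed + 5,
                       tpe = config$seed + 6),
    checksums = as.list(tools::md5sum(unname(paths)))
  )
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE)
  paths["manifest"] <- art("manifest.json")

  invisible(list(network = net, blues = blues, W = W, rfe = rfe,
                 omega = omega, omega_yield = omega_y, comparison = comp,
                 clusters = cl, wss = wss, scenarios = sc, reductions = red,
                 tpe = tpe_report, pca = pca, artifacts = paths))
}
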