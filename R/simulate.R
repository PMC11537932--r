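# Synthetic trial-network generator.
#
# The generator emulates the structure of an advanced rice breeding network:
# 25 genotypes (9 in year 1, all 25 in year 2, the 9 common), 18 locations
# grouped into climate/soil archetype clusters, 2 years, RCBD with 3 blocks,
# daily weather per location, soil covariates per location, and skewed county
# production shares. Yields follow a linear reaction-norm: genotype-specific
# slopes on planted informative covariates plus i.i.d. Gaussian components for
# every random term of the two-stage analysis model, so every quantity the
# pipeline estimates has a known truth.

# Primitive daily variables simulated directly; T2M and T2M_MAX are derived
# from T2M_MIN + range so min <= mean <= max holds by construction. Stage
# summaries add GDD and T2M_RANGE, giving 19 base covariates per stage.
.sim_primitives <- function() {
  c(T2M_MIN = 21, RANGE = 10, T2MDEW = 19, RH2M = 78, PRECTOTCORR = 5,
    WS2M = 2.5, ALLSKY_SFC_SW_DWN = 20, ALLSKY_SFC_LW_DWN = 38, PS = 101,
    QV2M = 15, EVLAND = 4, VPD = 1.1, GWETTOP = 0.6, GWETROOT = 0.55,
    T2MWET = 20, CLRSKY_SFC_SW_DWN = 24)
}

.sim_daily_sd <- function() {
  sds <- c(T2M_MIN = 1.5, RANGE = 1.5, T2MDEW = 1.5, RH2M = 5, PRECTOTCORR = 4,
           WS2M = 0.8, ALLSKY_SFC_SW_DWN = 4, ALLSKY_SFC_LW_DWN = 3, PS = 0.5,
           QV2M = 1.5, EVLAND = 1, VPD = 0.25, GWETTOP = 0.08, GWETROOT = 0.06,
           T2MWET = 1.5, CLRSKY_SFC_SW_DWN = 2)
  sds
}

.soil_vars <- function() {
  # 11 soil covariates; TCEQ (g/kg) and SILT (g/100g) carry the planted signal
  list(
    means = c(TCEQ = 30, SILT = 40, CLAY = 25, SAND = 35, PHAQ = 6.5,
              CECS = 18, ORGC = 12, TOTN = 1.2, BDWS = 1.4, ELCO = 0.4,
              WV33 = 32),
    sds = c(TCEQ = 8, SILT = 3, CLAY = 4, SAND = 5, PHAQ = 0.4,
            CECS = 3, ORGC = 3, TOTN = 0.3, BDWS = 0.1, ELCO = 0.1,
            WV33 = 4)
  )
}

#' Default informative environmental covariates
#'
#' The eight covariates the generator plants as drivers of the
#' genotype-by-environment reaction norm: dew-point temperature in three
#' reproductive windows, minimum temperature and diurnal range around panicle
#' initiation, thermal time at flowering, and the two soil variables TCEQ
#' (calcium carbonate equivalent, g/kg) and SILT (total silt, g/100g).
#'
#' @return data frame with columns `variable`, `stage` (`NA` for soil),
#'   `effect` (relative reaction-norm weight) and `loc_sd` (within-cluster
#'   location SD on the variable's own scale).
#' @export
default_informative_covariates <- function() {
  data.frame(
    variable = c("T2MDEW", "T2MDEW", "T2MDEW", "T2M_MIN", "GDD", "T2M_RANGE",
                 "TCEQ", "SILT"),
    stage = c("FLW_POST.FLW", "PRE.FLW_FLW", "PAN.INIT_PRE.FLW",
              "MAX.TIL_PAN.INIT", "PRE.FLW_FLW", "MAX.TIL_PAN.INIT",
              NA, NA),
    effect = rep(1, 8),
    loc_sd = c(0.7, 0.7, 0.7, 0.7, 0.7, 0.7, 8, 3),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for a synthetic trial network
#'
#' Dimensions default to the advanced-trial structure the pipeline targets:
#' 25 genotypes of which 9 were tested in year 1, 18 locations in 5
#' climate/soil archetype clusters, 2 years, 3 blocks. Variance components are
#' on the (kg/ha)^2 scale of rice grain yield around a 9,000 kg/ha mean.
#'
#' @param n_genotypes,n_genotypes_year1 total genotypes and the subset tested
#'   in year 1 (the subset is common to both years)
#' @param n_locations,n_years,n_blocks network dimensions
#' @param n_clusters number of planted archetype clusters
#' @param cluster_sizes optional integer vector (sums to `n_locations`)
#' @param var_components named list: `genotype`, `gxe`, `block`, `row`, `col`,
#'   `residual`, in (kg/ha)^2
#' @param mu overall mean yield (kg/ha)
#' @param year_effects fixed year effects (kg/ha), length `n_years`
#' @param cluster_yield_offsets additional fixed cluster mean-yield offsets
#'   (kg/ha), length `n_clusters`; default 0 — location mean yield is driven
#'   by the informative covariates (see `yield_cov_sd`)
#' @param yield_cov_sd SD (kg/ha) of the covariate-driven component of the
#'   location main effect: locations gain `gamma' w` with `w` the scaled
#'   informative profile and `gamma` proportional to the covariate effect
#'   weights, scaled to this SD — this is what makes environment-level mean
#'   yield predictable from the covariates
#' @param loc_sd,env_sd SDs (kg/ha) of the unexplained location main effect
#'   and of the location-by-year effect
#' @param informative_covariates data frame as
#'   [default_informative_covariates()]
#' @param separation archetype separation between adjacent cluster levels, in
#'   units of the within-cluster location SD of each informative covariate
#' @param gxe_structured_share fraction of the GxE variance carried by the
#'   covariate reaction norm (the rest is i.i.d.)
#' @param field_cols columns of the per-trial field grid (rows are derived);
#'   `NULL` gives a near-square grid
#' @param n_counties,n_days counties in the production table; days of daily
#'   weather (day 0 = emergence)
#' @param soil_missing_location if `TRUE`, add one extra location with weather
#'   but no soil record (emulating a site whose soil data cannot be retrieved)
#' @param seed integer seed; identical seeds give byte-identical output
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genotypes = 25, n_genotypes_year1 = 9,
                       n_locations = 18, n_years = 2, n_blocks = 3,
                       n_clusters = 5, cluster_sizes = NULL,
                       var_components = list(genotype = 250000, gxe = 80000,
                                             block = 40000, row = 22500,
                                             col = 22500, residual = 200000),
                       mu = 9000,
                       year_effects = NULL,
                       cluster_yield_offsets = NULL,
                       yield_cov_sd = 400,
                       loc_sd = 150, env_sd = 150,
                       informative_covariates = default_informative_covariates(),
                       separation = 6,
                       gxe_structured_share = 0.8,
                       field_cols = NULL,
                       n_counties = 71, n_days = 149,
                       soil_missing_location = FALSE,
                       seed = 101) {
  if (n_genotypes < 1 || n_locations < 1 || n_years < 1 || n_blocks < 1 ||
      n_clusters < 1) {
    stop("sim_config: non-positive dimensions")
  }
  if (n_genotypes_year1 > n_genotypes) {
    stop("sim_config: n_genotypes_year1 > n_genotypes")
  }
  need <- c("genotype", "gxe", "block", "row", "col", "residual")
  if (!all(need %in% names(var_components))) {
    stop("sim_config: var_components must name ", paste(need, collapse = ", "))
  }
  if (any(unlist(var_components[need]) < 0)) {
    stop("sim_config: variances must be >= 0")
  }
  if (n_clusters > n_locations) stop("sim_config: more clusters than locations")
  if (is.null(cluster_sizes)) {
    cluster_sizes <- rep(n_locations %/% n_clusters, n_clusters)
    extra <- n_locations - sum(cluster_sizes)
    if (extra > 0) cluster_sizes[seq_len(extra)] <- cluster_sizes[seq_len(extra)] + 1L
  }
  if (sum(cluster_sizes) != n_locations) {
    stop("sim_config: cluster_sizes must sum to n_locations")
  }
  if (is.null(year_effects)) {
    year_effects <- if (n_years == 1) 0 else seq(0, 200, length.out = n_years)
  }
  stopifnot(length(year_effects) == n_years)
  if (is.null(cluster_yield_offsets)) {
    cluster_yield_offsets <- rep(0, n_clusters)
  }
  stopifnot(length(cluster_yield_offsets) == n_clusters,
            yield_cov_sd >= 0)
  stopifnot(gxe_structured_share >= 0, gxe_structured_share <= 1)
  if (n_days < 148) stop("sim_config: n_days must be >= 148")
  cfg <- list(
    n_genotypes = as.integer(n_genotypes),
    n_genotypes_year1 = as.integer(n_genotypes_year1),
    n_locations = as.integer(n_locations), n_years = as.integer(n_years),
    n_blocks = as.integer(n_blocks), n_clusters = as.integer(n_clusters),
    cluster_sizes = as.integer(cluster_sizes),
    var_components = var_components, mu = mu,
    year_effects = year_effects,
    cluster_yield_offsets = cluster_yield_offsets,
    yield_cov_sd = yield_cov_sd,
    loc_sd = loc_sd, env_sd = env_sd,
    informative_covariates = informative_covariates,
    separation = separation,
    gxe_structured_share = gxe_structured_share,
    field_cols = field_cols,
    n_counties = as.integer(n_counties), n_days = as.integer(n_days),
    soil_missing_location = isTRUE(soil_missing_location),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# cluster x informative-covariate archetype pattern. Clusters sit on two
# environmental gradients: odd-numbered covariates load on a primary ladder
# (think south-to-north temperature), even-numbered ones on an alternating
# secondary contrast (e.g. coastal/inland). Every cluster occupies a distinct
# position in this 2-D archetype space, so the planted partition is separable
# in the informative covariates, and the covariates carry a strong shared
# yield gradient.
.archetype_pattern <- function(n_clusters, n_cov) {
  if (n_clusters == 1) return(matrix(0, 1, n_cov))
  t_lv <- seq(-2, 2, length.out = n_clusters)
  v_lv <- rep(c(1.5, -1.5), length.out = n_clusters)
  # each covariate loads on the two gradients at its own angle, spread over
  # +/- 70 degrees around the primary axis: no covariate pair is collinear
  # enough to trip the 0.95 QC filter, and any pair of selected covariates
  # spans the archetype plane
  theta <- if (n_cov == 1) 0 else seq(-70, 70, length.out = n_cov) * pi / 180
  out <- matrix(0, n_clusters, n_cov)
  for (c in seq_len(n_cov)) {
    out[, c] <- cos(theta[c]) * t_lv + sin(theta[c]) * v_lv
  }
  out
}

#' Simulate daily weather for one location
#'
#' Draws independent Gaussian daily values around an archetype mean profile
#' (base mean + per-stage window offsets), then derives `T2M_MAX` and `T2M`
#' from `T2M_MIN` plus a non-negative diurnal range, enforcing
#' min <= mean <= max by construction.
#'
#' @param archetype list with named numeric `means` (see package defaults),
#'   optional `window_offsets` (primitive variable x 6-stage matrix) and
#'   `daily_sd` (named; 0 gives constant series)
#' @param n_days number of days simulated, day 0 = emergence; must cover the
#'   full phenological calendar (>= 148)
#' @param seed optional integer seed; `NULL` uses the current RNG stream
#' @param calendar a [phenology_calendar()]
#' @return data frame: `day` plus 17 daily weather variables.
#' @export
simulate_weather <- function(archetype = list(), n_days = 149, seed = NULL,
                             calendar = phenology_calendar()) {
  if (n_days < 148) stop("simulate_weather: n_days must be >= 148")
  if (!is.null(seed)) set.seed(seed)
  means <- .sim_primitives()
  if (!is.null(archetype$means)) means[names(archetype$means)] <- archetype$means
  sds <- .sim_daily_sd()
  if (!is.null(archetype$daily_sd)) sds[names(archetype$daily_sd)] <- archetype$daily_sd
  offs <- archetype$window_offsets # matrix var x stage or NULL
  days <- 0:(n_days - 1)
  stage_of <- rep(NA_character_, n_days)
  for (i in seq_len(nrow(calendar))) {
    sel <- days >= calendar$start[i] & days <= calendar$end[i]
    stage_of[sel] <- calendar$stage[i]
  }
  vals <- matrix(0, n_days, length(means), dimnames = list(NULL, names(means)))
  for (v in names(means)) {
    m <- rep(means[[v]], n_days)
    if (!is.null(offs) && v %in% rownames(offs)) {
      for (s in colnames(offs)) m[stage_of == s] <- m[stage_of == s] + offs[v, s]
    }
    vals[, v] <- m + stats::rnorm(n_days, 0, sds[[v]])
  }
  vals[, "RANGE"] <- pmax(vals[, "RANGE"], 0)
  out <- data.frame(day = days)
  out$T2M_MIN <- vals[, "T2M_MIN"]
  out$T2M_MAX <- vals[, "T2M_MIN"] + vals[, "RANGE"]
  out$T2M <- (out$T2M_MIN + out$T2M_MAX) / 2
  for (v in setdiff(colnames(vals), c("T2M_MIN", "RANGE"))) out[[v]] <- vals[, v]
  out
}

# serpentine fill of b*g plots into a rows x cols grid
.serpentine <- function(n_plots, n_cols) {
  n_rows <- ceiling(n_plots / n_cols)
  cells <- do.call(rbind, lapply(seq_len(n_rows), function(r) {
    cols <- if (r %% 2 == 1) seq_len(n_cols) else rev(seq_len(n_cols))
    cbind(row = r, col = cols)
  }))
  cells[seq_len(n_plots), , drop = FALSE]
}

#' Simulate a complete multi-environment trial network
#'
#' Generates plot-level yields, daily weather per location, a soil table,
#' a county production table, and the ground truth used by recovery tests.
#' Yields are `mu + year + location + loc:year + g_i + ge_il + block + row +
#' col + residual`, with `ge_il` a linear reaction norm on the planted
#' informative covariates (genotype-specific sensitivities) plus an i.i.d.
#' component, scaled so its total variance matches `var_components$gxe`.
#'
#' @param config a [sim_config()]
#' @return A `trial_network` list: `plots` (plot records), `weather` (long
#'   data frame location/day/variable/value), `soil`, `production`, `truth`.
#' @export
simulate_network <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  vc <- config$var_components
  g_ids <- sprintf("G%02d", seq_len(config$n_genotypes))
  loc_ids <- sprintf("L%02d", seq_len(config$n_locations))
  years <- 2021L + seq_len(config$n_years) - 1L
  cluster_of <- rep(seq_len(config$n_clusters), times = config$cluster_sizes)
  names(cluster_of) <- loc_ids

  info <- config$informative_covariates
  n_info <- nrow(info)
  cov_id <- ifelse(is.na(info$stage), info$variable,
                   paste(info$variable, info$stage, sep = "_"))
  pattern <- .archetype_pattern(config$n_clusters, n_info)

  # deterministic location-level values of the informative covariates:
  # archetype level + within-cluster jitter (these are the "true window means")
  soil_def <- .soil_vars()
  base_val <- vapply(seq_len(n_info), function(c) {
    v <- info$variable[c]
    if (v %in% names(soil_def$means)) soil_def$means[[v]]
    else if (v == "GDD") NA_real_ # filled below on the GDD scale
    else if (v == "T2M_RANGE") .sim_primitives()[["RANGE"]]
    else .sim_primitives()[[v]]
  }, numeric(1))
  profile <- matrix(NA_real_, config$n_locations, n_info,
                    dimnames = list(loc_ids, cov_id))
  for (c in seq_len(n_info)) {
    offs <- pattern[cluster_of, c] * config$separation * info$loc_sd[c] +
      stats::rnorm(config$n_locations, 0, info$loc_sd[c])
    base <- if (is.na(base_val[c])) 0 else base_val[c]
    profile[, c] <- base + offs
  }

  # weather: per location, translate informative weather offsets into window
  # offsets on the primitive daily series
  calendar <- phenology_calendar()
  stages <- calendar$stage
  weather_list <- vector("list", config$n_locations)
  extra_loc <- NULL
  for (l in seq_len(config$n_locations)) {
    offs <- matrix(0, length(.sim_primitives()), length(stages),
                   dimnames = list(names(.sim_primitives()), stages))
    for (c in seq_len(n_info)) {
      v <- info$variable[c]; s <- info$stage[c]
      if (is.na(s)) next # soil
      delta <- profile[l, c] - (if (is.na(base_val[c])) 0 else base_val[c])
      prim <- switch(v, T2M_RANGE = "RANGE", GDD = "T2M_MIN",
                     T2M = "T2M_MIN", T2M_MAX = "T2M_MIN", v)
      offs[prim, s] <- offs[prim, s] + delta
    }
    weather_list[[l]] <- simulate_weather(
      archetype = list(window_offsets = offs), n_days = config$n_days)
  }
  all_loc_ids <- loc_ids
  if (config$soil_missing_location) {
    extra_loc <- sprintf("L%02d", config$n_locations + 1L)
    weather_list[[config$n_locations + 1L]] <-
      simulate_weather(n_days = config$n_days)
    all_loc_ids <- c(loc_ids, extra_loc)
  }
  weather <- do.call(rbind, lapply(seq_along(weather_list), function(l) {
    w <- weather_list[[l]]
    vars <- setdiff(names(w), "day")
    data.frame(location = all_loc_ids[l],
               day = rep(w$day, length(vars)),
               variable = rep(vars, each = nrow(w)),
               value = unlist(w[vars], use.names = FALSE),
               stringsAsFactors = FALSE)
  }))

  # soil table (informative soil covariates take their planted profile)
  soil <- data.frame(location = loc_ids, stringsAsFactors = FALSE)
  for (v in names(soil_def$means)) {
    idx <- which(info$variable == v & is.na(info$stage))
    if (length(idx) == 1) {
      soil[[v]] <- profile[, idx]
    } else {
      soil[[v]] <- soil_def$means[[v]] +
        stats::rnorm(config$n_locations, 0, soil_def$sds[[v]])
    }
  }

  # genetic and environmental effects
  g_eff <- stats::rnorm(config$n_genotypes, 0, sqrt(vc$genotype))
  names(g_eff) <- g_ids
  w_scaled <- scale(profile)
  w_scaled[is.nan(w_scaled)] <- 0
  # location mean yield: covariate-driven component + unexplained noise
  gamma <- info$effect / sqrt(sum(info$effect^2)) * config$yield_cov_sd
  loc_eff <- config$cluster_yield_offsets[cluster_of] +
    as.numeric(w_scaled %*% gamma) +
    stats::rnorm(config$n_locations, 0, config$loc_sd)
  names(loc_eff) <- loc_ids
  env_eff <- matrix(stats::rnorm(config$n_locations * config$n_years, 0,
                                 config$env_sd),
                    config$n_locations, config$n_years,
                    dimnames = list(loc_ids, as.character(years)))

  # reaction-norm GxE on the scaled informative profile
  sens <- matrix(stats::rnorm(config$n_genotypes * n_info), config$n_genotypes,
                 n_info, dimnames = list(g_ids, cov_id))
  sens <- sweep(sens, 2, info$effect, `*`)
  ge <- matrix(0, config$n_genotypes, config$n_locations,
               dimnames = list(g_ids, loc_ids))
  if (vc$gxe > 0) {
    raw <- sens %*% t(w_scaled)
    vr <- stats::var(as.vector(raw))
    structured <- if (vr > 0)
      raw * sqrt(config$gxe_structured_share * vc$gxe / vr) else raw * 0
    ge <- structured +
      matrix(stats::rnorm(length(ge), 0,
                          sqrt((1 - config$gxe_structured_share) * vc$gxe)),
             nrow(ge), ncol(ge))
  }

  # plot records
  g_year <- list()
  for (y in seq_len(config$n_years)) {
    g_year[[y]] <- if (y == 1 && config$n_years > 1)
      g_ids[seq_len(config$n_genotypes_year1)] else g_ids
  }
  if (config$n_years == 1) g_year[[1]] <- g_ids
  trial_locs <- all_loc_ids
  if (config$soil_missing_location) {
    loc_eff <- c(loc_eff, stats::setNames(config$cluster_yield_offsets[1], extra_loc))
    env_eff <- rbind(env_eff, matrix(stats::rnorm(config$n_years, 0, config$env_sd),
                                     1, dimnames = list(extra_loc, NULL)))
    ge <- cbind(ge, matrix(0, config$n_genotypes, 1,
                           dimnames = list(NULL, extra_loc)))
  }
  plots <- list()
  for (y in seq_len(config$n_years)) {
    gy <- g_year[[y]]
    for (l in trial_locs) {
      n_plots <- length(gy) * config$n_blocks
      n_cols <- if (is.null(config$field_cols)) ceiling(sqrt(n_plots))
                else config$field_cols
      cells <- .serpentine(n_plots, n_cols)
      n_rows <- max(cells[, "row"])
      row_eff <- stats::rnorm(n_rows, 0, sqrt(vc$row))
      col_eff <- stats::rnorm(n_cols, 0, sqrt(vc$col))
      blk_eff <- stats::rnorm(config$n_blocks, 0, sqrt(vc$block))
      geno_seq <- unlist(lapply(seq_len(config$n_blocks),
                                function(b) sample(gy)))
      blk_seq <- rep(seq_len(config$n_blocks), each = length(gy))
      resid <- stats::rnorm(n_plots, 0, sqrt(vc$residual))
      yield <- config$mu + config$year_effects[y] + loc_eff[l] +
        env_eff[l, y] + g_eff[geno_seq] + ge[cbind(geno_seq, l)] +
        blk_eff[blk_seq] + row_eff[cells[, "row"]] + col_eff[cells[, "col"]] +
        resid
      plots[[length(plots) + 1L]] <- data.frame(
        genotype = geno_seq, location = l, year = years[y],
        replicate = blk_seq, row = cells[, "row"], column = cells[, "col"],
        yield = as.numeric(yield), stringsAsFactors = FALSE)
    }
  }
  plots <- do.call(rbind, plots)
  rownames(plots) <- NULL

  # county production table: skewed shares, cluster-archetype profiles
  county_ids <- sprintf("C%03d", seq_len(config$n_counties))
  county_cluster <- rep(seq_len(config$n_clusters),
                        length.out = config$n_counties)
  county_cluster <- sample(county_cluster)
  raw_share <- stats::rlnorm(config$n_counties, meanlog = 0, sdlog = 1)
  share <- raw_share / sum(raw_share)
  county_prof <- matrix(NA_real_, config$n_counties, n_info,
                        dimnames = list(county_ids, cov_id))
  for (c in seq_len(n_info)) {
    base <- if (is.na(base_val[c])) 0 else base_val[c]
    county_prof[, c] <- base +
      pattern[county_cluster, c] * config$separation * info$loc_sd[c] +
      stats::rnorm(config$n_counties, 0, info$loc_sd[c])
  }
  production <- data.frame(county = county_ids, production_share = share,
                           stringsAsFactors = FALSE)
  production <- cbind(production, as.data.frame(county_prof))

  truth <- list(
    genotype_effects = g_eff, ge = ge, sensitivities = sens,
    var_components = vc, informative = cbind(info, id = cov_id),
    cluster_assignments = cluster_of, informative_profile = profile,
    location_effects = loc_eff, year_effects = config$year_effects,
    env_effects = env_eff, county_cluster = stats::setNames(county_cluster,
                                                            county_ids),
    mu = config$mu
  )
  structure(list(plots = plots, weather = weather, soil = soil,
                 production = production, truth = truth, config = config),
            class = "trial_network")
}

#' @export
print.trial_network <- function(x, ...) {
  cat("Synthetic trial network:",
      length(unique(x$plots$genotype)), "genotypes,",
      length(unique(x$plots$location)), "locations,",
      length(unique(x$plots$year)), "years,",
      nrow(x$plots), "plots\n")
  invisible(x)
}
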