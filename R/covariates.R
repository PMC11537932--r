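# Environment x covariate matrix construction: stage-windowed weather
# summaries, soil join, centering/scaling, collinearity QC.

# reshape long weather (location, day, variable, value) to per-location wide
.weather_wide <- function(weather) {
  stopifnot(all(c("location", "day", "variable", "value") %in% names(weather)))
  split(weather, weather$location)
}

#' Stage-windowed weather summaries
#'
#' Summarizes daily weather into one covariate per (base variable, stage)
#' pair: the window mean of each daily variable, plus two derived covariates
#' per stage — `GDD` (window sum of daily degree-days from `T2M_MIN`/`T2M_MAX`
#' via [gdd_daily()]) and `T2M_RANGE` (window mean of the daily max - min
#' range). With 17 daily variables this yields the canonical 19 base
#' covariates x 6 stages = 114 columns.
#'
#' @param weather long data frame: `location`, `day`, `variable`, `value`
#' @param calendar a [phenology_calendar()]
#' @param cardinal a [cardinal_temps()] used for GDD
#' @return matrix, rows = locations, columns named `VARIABLE_STAGE`, with a
#'   `provenance` attribute (data frame: id, source, variable, stage).
#' @export
summarize_stage <- function(weather, calendar = phenology_calendar(),
                            cardinal = cardinal_temps()) {
  by_loc <- .weather_wide(weather)
  locs <- names(by_loc)
  need_days <- unlist(lapply(seq_len(nrow(calendar)),
                             function(i) calendar$start[i]:calendar$end[i]))
  vars <- sort(unique(weather$variable))
  has_temp <- all(c("T2M_MIN", "T2M_MAX") %in% vars)
  base_vars <- c(vars,
                 if (has_temp && !"GDD" %in% vars) "GDD",
                 if (has_temp && !"T2M_RANGE" %in% vars) "T2M_RANGE")
  cols <- as.vector(outer(base_vars, calendar$stage, paste, sep = "_"))
  out <- matrix(NA_real_, length(locs), length(cols),
                dimnames = list(locs, cols))
  for (l in locs) {
    w <- by_loc[[l]]
    wide <- stats::reshape(w[, c("day", "variable", "value")],
                           direction = "wide", idvar = "day",
                           timevar = "variable")
    names(wide) <- sub("^value\\.", "", names(wide))
    wide <- wide[order(wide$day), , drop = FALSE]
    missing <- setdiff(need_days, wide$day)
    if (length(missing) > 0) {
      stop("summarize_stage: location ", l, " is missing days inside the ",
           "calendar (first missing day ", min(missing), ")")
    }
    for (i in seq_len(nrow(calendar))) {
      sel <- wide$day >= calendar$start[i] & wide$day <= calendar$end[i]
      st <- calendar$stage[i]
      for (v in vars) {
        out[l, paste(v, st, sep = "_")] <- mean(wide[[v]][sel])
      }
      if (has_temp && !"GDD" %in% vars) {
        out[l, paste("GDD", st, sep = "_")] <-
          sum(gdd_daily(wide$T2M_MIN[sel], wide$T2M_MAX[sel], cardinal))
      }
      if (has_temp && !"T2M_RANGE" %in% vars) {
        out[l, paste("T2M_RANGE", st, sep = "_")] <-
          mean(wide$T2M_MAX[sel] - wide$T2M_MIN[sel])
      }
    }
  }
  prov <- data.frame(
    id = cols,
    source = "weather",
    variable = rep(base_vars, times = nrow(calendar)),
    stage = rep(calendar$stage, each = length(base_vars)),
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- prov
  out
}

#' Build the centered and scaled environment covariate matrix W
#'
#' Joins stage-windowed weather summaries with soil covariates on the common
#' environment set, drops environments lacking soil (with a warning), removes
#' zero-variance columns, and centers/scales every column to mean 0, SD 1.
#' The per-column means and SDs are stored so the standardization can be
#' inverted, and applied to new profiles (e.g. county profiles for TPE
#' assignment).
#'
#' @param weather_summary matrix from [summarize_stage()] (rows = locations)
#' @param soil data frame with a `location` column plus numeric soil
#'   covariates; `NULL` for a weather-only W
#' @return A `covariate_matrix`: numeric matrix with attributes `scaling`
#'   (list of `center`, `scale`), `provenance`, and `dropped` (zero-variance
#'   column ids).
#' @export
build_W <- function(weather_summary, soil = NULL) {
  W <- as.matrix(weather_summary)
  prov <- attr(weather_summary, "provenance")
  if (is.null(prov)) {
    prov <- data.frame(id = colnames(W), source = "weather",
                       variable = colnames(W), stage = NA_character_,
                       stringsAsFactors = FALSE)
  }
  if (!is.null(soil)) {
    stopifnot("location" %in% names(soil))
    common <- intersect(rownames(W), soil$location)
    if (length(common) == 0) {
      stop("build_W: no common environments between weather and soil")
    }
    lost <- setdiff(rownames(W), common)
    if (length(lost) > 0) {
      warning("build_W: dropping ", length(lost),
              " environment(s) without soil data: ",
              paste(lost, collapse = ", "))
    }
    W <- W[common, , drop = FALSE]
    soil_m <- as.matrix(soil[match(common, soil$location),
                             setdiff(names(soil), "location"), drop = FALSE])
    rownames(soil_m) <- common
    W <- cbind(W, soil_m)
    prov <- rbind(prov, data.frame(id = colnames(soil_m), source = "soil",
                                   variable = colnames(soil_m),
                                   stage = NA_character_,
                                   stringsAsFactors = FALSE))
  }
  if (anyNA(W)) stop("build_W: missing values in the joined covariate matrix")
  ctr <- colMeans(W)
  sds <- apply(W, 2, stats::sd)
  drop <- colnames(W)[sds == 0 | !is.finite(sds)]
  if (length(drop) > 0) {
    message("build_W: dropping ", length(drop), " zero-variance column(s): ",
            paste(drop, collapse = ", "))
    keep <- setdiff(colnames(W), drop)
    W <- W[, keep, drop = FALSE]
    ctr <- ctr[keep]; sds <- sds[keep]
    prov <- prov[prov$id %in% keep, , drop = FALSE]
  }
  Ws <- sweep(sweep(W, 2, ctr), 2, sds, `/`)
  structure(Ws,
            scaling = list(center = ctr, scale = sds),
            provenance = prov, dropped = drop,
            class = c("covariate_matrix", class(Ws)))
}

#' Invert the standardization of a covariate matrix
#'
#' @param W a `covariate_matrix` from [build_W()]
#' @return Matrix on the raw covariate scale.
#' @export
unscale_W <- function(W) {
  sc <- attr(W, "scaling")
  stopifnot(!is.null(sc))
  sweep(sweep(unclass(W), 2, sc$scale, `*`), 2, sc$center, `+`)
}

#' Greedy collinearity filter
#'
#' Repeatedly finds column pairs whose absolute Pearson correlation reaches
#' `threshold` and drops, among the columns involved in such a pair, the one
#' with the largest mean absolute correlation to all remaining columns (ties
#' broken by dropping the later column). Stops when no pair remains at or
#' above the threshold; the post-condition is asserted on every run.
#'
#' @param W numeric matrix (>= 2 columns), typically a `covariate_matrix`
#' @param threshold correlation threshold in (0, 1]
#' @return The filtered matrix; attribute `removed` lists dropped column ids.
#' @export
filter_collinear <- function(W, threshold = 0.95) {
  if (!(threshold > 0 && threshold <= 1)) {
    stop("filter_collinear: threshold must be in (0, 1]")
  }
  if (ncol(W) < 2) stop("filter_collinear: W must have >= 2 columns")
  attrs <- attributes(W)
  M <- unclass(W)
  removed <- character(0)
  repeat {
    cm <- abs(stats::cor(M))
    diag(cm) <- 0
    if (max(cm) < threshold) break
    offending <- which(apply(cm >= threshold, 2, any))
    mean_abs <- (colSums(abs(stats::cor(M))[, offending, drop = FALSE]) - 1) /
      (ncol(M) - 1)
    # largest mean |r|; ties -> later column
    worst <- offending[max(which(mean_abs == max(mean_abs)))]
    removed <- c(removed, colnames(M)[worst])
    M <- M[, -worst, drop = FALSE]
    if (ncol(M) < 2) break
  }
  if (ncol(M) >= 2) {
    audit <- abs(stats::cor(M)); diag(audit) <- 0
    stopifnot(max(audit) < threshold)
  }
  for (a in setdiff(names(attrs), c("dim", "dimnames", "class"))) {
    if (a == "scaling") {
      attr(M, a) <- lapply(attrs[[a]], function(x) x[colnames(M)])
    } else if (a == "provenance") {
      attr(M, a) <- attrs[[a]][attrs[[a]]$id %in% colnames(M), , drop = FALSE]
    } else {
      attr(M, a) <- attrs[[a]]
    }
  }
  attr(M, "removed") <- removed
  class(M) <- attrs$class
  M
}
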