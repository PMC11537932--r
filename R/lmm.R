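# Linear mixed model engine: dense average-information REML with optional
# covariance kernels on random terms, BLUEs with standard errors, BLUPs with
# prediction error variances, Cullis heritability.
#
# Model: y = X b + sum_k Z_k u_k + e,  u_k ~ N(0, s2_k K_k),  e ~ N(0, s2_e R)
# so V = sum_k s2_k G_k + s2_e R with G_k = Z_k K_k Z_k'. All algebra is dense;
# the engine targets trial-network sizes (hundreds to a few thousand rows).

# ---- internal core ---------------------------------------------------------

.reml_loglik <- function(theta, y, Xr, Gs) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (k in seq_along(Gs)) V <- V + theta[k] * Gs[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% Xr
  XtVX <- crossprod(Xr, VinvX)
  ch2 <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch2)) return(NULL)
  P <- Vinv - VinvX %*% chol2inv(ch2) %*% t(VinvX)
  Py <- P %*% y
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(ch2))) +
                  sum(y * Py))
  list(ll = as.numeric(ll), P = P, Py = Py, Vinv = Vinv)
}

# AI-REML with step halving, multiplicative fallback, and projection of
# variance components onto [floor, Inf); components stuck at the floor with a
# negative score are treated as boundary (zero) estimates.
.reml_core <- function(y, X, Gs, maxit = 300, tol = 1e-10) {
  n <- length(y)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    message("fit_reml: dropping aliased fixed-effect column(s): ",
            paste(dropped, collapse = ", "))
  }
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xr <- X[, keep, drop = FALSE]
  if (n - ncol(Xr) < 1) stop("fit_reml: no residual degrees of freedom")

  m <- length(Gs)
  vy <- max(stats::var(y), 1e-12)
  # floor and cap keep V's condition number within what dense double-precision
  # algebra can evaluate reliably; components at the floor report as zero
  floor_ <- 1e-6 * vy
  cap_ <- 1e4 * vy
  theta <- rep(vy / m, m)
  cur <- .reml_loglik(theta, y, Xr, Gs)
  if (is.null(cur)) {
    theta <- rep(vy, m)
    cur <- .reml_loglik(theta, y, Xr, Gs)
    if (is.null(cur)) stop("fit_reml: initial variance matrix is singular")
  }
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(maxit)) {
    P <- cur$P; Py <- cur$Py
    Tk <- lapply(Gs, function(G) G %*% Py)
    score <- numeric(m)
    for (k in seq_len(m)) {
      score[k] <- -0.5 * (sum(P * Gs[[k]]) - sum(Py * Tk[[k]]))
    }
    free <- !(theta <= floor_ * 1.000001 & score < 0)
    if (all(abs(score[free]) < 1e-8 * n) || !any(free)) {
      converged <- TRUE; break
    }
    PT <- lapply(Tk, function(t) P %*% t)
    AI <- matrix(0, m, m)
    for (k in seq_len(m)) for (l in k:m) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(Tk[[k]] * PT[[l]])
    }
    # boundary components with negative score stay pinned at the floor
    delta <- numeric(m)
    AIf <- AI[free, free, drop = FALSE]
    delta[free] <- tryCatch(
      solve(AIf + diag(1e-10 * max(diag(AIf)) + 1e-300, sum(free)),
            score[free]),
      error = function(e) score[free] / max(diag(AIf), 1))
    improved <- FALSE
    step <- 1
    for (h in seq_len(30)) {
      cand <- pmin(pmax(theta + step * delta, floor_), cap_)
      nxt <- .reml_loglik(cand, y, Xr, Gs)
      if (!is.null(nxt) && nxt$ll >= cur$ll - 1e-12) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) {
      # multiplicative fixed-point fallback
      num <- vapply(Tk, function(t) sum(Py * t), numeric(1))
      den <- vapply(Gs, function(G) sum(P * G), numeric(1))
      ratio <- sqrt(pmax(num, 0) / pmax(den, 1e-300))
      cand <- pmin(pmax(theta * ratio, floor_), cap_)
      nxt <- .reml_loglik(cand, y, Xr, Gs)
      if (is.null(nxt) || nxt$ll < cur$ll - 1e-12) { converged <- TRUE; break }
    }
    reldiff <- abs(nxt$ll - cur$ll) / (1 + abs(cur$ll))
    theta <- cand
    cur <- nxt
    if (reldiff < tol) { converged <- TRUE; break }
  }
  boundary <- theta <= floor_ * 1.000001
  theta_out <- ifelse(boundary, 0, theta)
  list(theta = theta, theta_out = theta_out, boundary = boundary,
       loglik = cur$ll, P = cur$P, Py = cur$Py, Vinv = cur$Vinv,
       Xr = Xr, keep = keep, converged = converged, iterations = iter,
       floor = floor_)
}

# ---- model specification ---------------------------------------------------

# normalize a random-term spec into list(factors=chr, kernel=matrix|NULL)
.norm_term <- function(spec) {
  if (is.character(spec)) return(list(factors = spec, kernel = NULL))
  stopifnot(is.list(spec), !is.null(spec$factors))
  if (length(spec$factors) > 2) stop("fit_reml: at most two factors per term")
  list(factors = spec$factors, kernel = spec$kernel)
}

# build Z (n x q) and K (q x q or NULL) for one random term
.term_design <- function(data, spec) {
  f1 <- factor(data[[spec$factors[1]]])
  if (length(spec$factors) == 1) {
    Z <- stats::model.matrix(~ 0 + f1)
    colnames(Z) <- levels(f1)
    K <- spec$kernel
    if (!is.null(K)) {
      if (is.null(rownames(K)) || !all(levels(f1) %in% rownames(K))) {
        stop("fit_reml: kernel levels do not match factor '",
             spec$factors[1], "'")
      }
      K <- K[levels(f1), levels(f1)]
    }
    return(list(Z = Z, K = K, levels = levels(f1)))
  }
  # two factors: Hadamard interaction [Z1 Z1'] (*) [Z2 K Z2']
  f2 <- factor(data[[spec$factors[2]]])
  combo <- interaction(f1, f2, drop = TRUE, sep = ":", lex.order = TRUE)
  Z <- stats::model.matrix(~ 0 + combo)
  colnames(Z) <- levels(combo)
  parts <- strsplit(levels(combo), ":", fixed = TRUE)
  a <- vapply(parts, `[`, character(1), 1)
  b <- vapply(parts, function(p) paste(p[-1], collapse = ":"), character(1))
  K <- NULL
  if (!is.null(spec$kernel)) {
    K2 <- spec$kernel
    if (is.null(rownames(K2)) || !all(unique(b) %in% rownames(K2))) {
      stop("fit_reml: kernel levels do not match factor '",
           spec$factors[2], "'")
    }
    same_g <- outer(a, a, `==`)
    K <- same_g * K2[b, b]
    dimnames(K) <- list(levels(combo), levels(combo))
  }
  list(Z = Z, K = K, levels = levels(combo))
}

#' Fit a linear mixed model by REML
#'
#' Dense average-information REML with non-negativity constraints on the
#' variance components, supporting identity or user-supplied covariance
#' kernels on random terms, including Hadamard-structured interaction terms
#' `[Z_g Z_g'] (x) [Z_e K Z_e']` for genotype-by-environment effects.
#'
#' @param data data frame
#' @param response name of the response column
#' @param fixed one-sided formula for the fixed effects (e.g. `~ year + env`
#'   or `~ 0 + genotype` for cell-means BLUEs); aliased columns are dropped
#' @param random named list of random-term specs. Each element is either a
#'   factor name (identity covariance), or a list with `factors` (one factor,
#'   or two for a Hadamard interaction) and optional `kernel` (covariance
#'   matrix with dimnames over the levels of the — for interactions, second —
#'   factor)
#' @param resid_weights optional positive weights; the residual covariance is
#'   `s2_e * diag(resid_weights)` (used for weighted second-stage fits)
#' @param maxit,tol iteration cap and relative log-likelihood tolerance
#' @return An `lmm_fit`: `varcomp` (named, residual last), `loglik`, `beta`,
#'   `beta_se`, `beta_vcov`, per-term `blups` (level, blup, pev; the full PEV
#'   matrix is kept as an attribute), `converged`, `iterations`, `boundary`.
#' @export
fit_reml <- function(data, response, fixed = ~1, random = list(),
                     resid_weights = NULL, maxit = 300, tol = 1e-10) {
  stopifnot(is.data.frame(data), response %in% names(data))
  y <- as.numeric(data[[response]])
  if (anyNA(y)) stop("fit_reml: missing response values")
  X <- stats::model.matrix(fixed, data)
  terms <- lapply(random, .norm_term)
  designs <- lapply(terms, function(t) .term_design(data, t))
  Gs <- lapply(designs, function(d) {
    if (is.null(d$K)) tcrossprod(d$Z) else d$Z %*% d$K %*% t(d$Z)
  })
  n <- length(y)
  R <- if (is.null(resid_weights)) diag(n) else {
    stopifnot(length(resid_weights) == n, all(resid_weights > 0))
    diag(resid_weights)
  }
  Gs <- c(Gs, list(R))
  names(Gs) <- c(names(random), "residual")

  core <- .reml_core(y, X, Gs, maxit = maxit, tol = tol)
  if (!core$converged) {
    warning("fit_reml: REML did not converge in ", core$iterations,
            " iterations")
  }
  # BLUEs at the optimum
  Vinv <- core$Vinv
  Xr <- core$Xr
  VinvX <- Vinv %*% Xr
  XtVXi <- chol2inv(chol(crossprod(Xr, VinvX)))
  beta <- as.numeric(XtVXi %*% crossprod(VinvX, y))
  names(beta) <- colnames(Xr)
  beta_se <- sqrt(pmax(diag(XtVXi), 0))
  names(beta_se) <- colnames(Xr)

  # BLUPs and PEV per random term
  P <- core$P
  Py <- core$Py
  blups <- list()
  for (k in seq_along(designs)) {
    th <- core$theta[k]
    d <- designs[[k]]
    KZt <- if (is.null(d$K)) t(d$Z) else d$K %*% t(d$Z)
    u <- as.numeric(th * KZt %*% Py)
    Kfull <- if (is.null(d$K)) diag(length(d$levels)) else d$K
    PZK <- P %*% t(KZt)
    pev <- th * Kfull - th^2 * (KZt %*% PZK)
    pev <- (pev + t(pev)) / 2
    dimnames(pev) <- list(d$levels, d$levels)
    tab <- data.frame(level = d$levels, blup = u, pev = pmax(diag(pev), 0),
                      stringsAsFactors = FALSE)
    attr(tab, "pev_matrix") <- pev
    blups[[names(random)[k]]] <- tab
  }
  varcomp <- stats::setNames(core$theta_out, names(Gs))
  structure(list(
    varcomp = varcomp, loglik = core$loglik,
    beta = beta, beta_se = beta_se, beta_vcov = XtVXi,
    blups = blups, converged = core$converged,
    iterations = core$iterations,
    boundary = stats::setNames(core$boundary, names(Gs)),
    n = n, rank_X = ncol(Xr)
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (REML), n =", x$n, "\n")
  cat("  log-likelihood:", format(x$loglik), "| converged:", x$converged,
      "in", x$iterations, "iterations\n")
  cat("  variance components:\n")
  print(round(x$varcomp, 4))
  invisible(x)
}

# ---- pipeline-facing model fits -------------------------------------------

#' Stage-1 genotype BLUEs for a single trial
#'
#' Fits the single-trial model: genotype fixed (cell means), replicate, field
#' row, and field column as independent random effects, plus residual.
#' Returns the genotype BLUEs and their standard errors. Spatial trend is
#' absorbed by the row and column effects; no 2-D spline surface is fitted.
#'
#' @param plots plot records for one trial (one location-year): columns
#'   `genotype`, `location`, `year`, `replicate`, `row`, `column`, `yield`
#' @return data frame: `location`, `year`, `env`, `genotype`, `blue`, `se`.
#' @export
stage1_blues <- function(plots) {
  need <- c("genotype", "location", "year", "replicate", "row", "column",
            "yield")
  stopifnot(all(need %in% names(plots)))
  if (length(unique(plots$location)) != 1 || length(unique(plots$year)) != 1) {
    stop("stage1_blues: expected a single trial (one location-year)")
  }
  if (length(unique(plots$replicate)) < 2) {
    stop("stage1_blues: need >= 2 replicates")
  }
  tab <- table(plots$genotype)
  if (any(tab == 0)) stop("stage1_blues: genotype with zero plots")
  d <- data.frame(
    yield = plots$yield,
    genotype = factor(plots$genotype),
    replicate = factor(plots$replicate),
    frow = factor(plots$row),
    fcol = factor(plots$column)
  )
  fit <- fit_reml(d, "yield", fixed = ~ 0 + genotype,
                  random = list(replicate = "replicate", row = "frow",
                                col = "fcol"))
  data.frame(
    location = plots$location[1], year = plots$year[1],
    env = paste(plots$location[1], plots$year[1], sep = ":"),
    genotype = sub("^genotype", "", names(fit$beta)),
    blue = as.numeric(fit$beta), se = as.numeric(fit$beta_se),
    stringsAsFactors = FALSE
  )
}

#' Stage-1 BLUEs for every trial in a network
#'
#' @param plots plot records for the whole network
#' @return Row-bound [stage1_blues()] tables, one block per location-year.
#' @export
network_blues <- function(plots) {
  key <- interaction(plots$location, plots$year, drop = TRUE)
  out <- do.call(rbind, lapply(split(plots, key), stage1_blues))
  rownames(out) <- NULL
  out
}

#' Stage-2 multi-trial mixed model
#'
#' Fits the joint model on stage-1 BLUEs: year and environment (location
#' nested in year) fixed, genotype random, genotype-by-environment random
#' with identity (`MET`, `WC`, `OPT`), enviromic-kernel (`MET_EC`), or
#' genotype-by-cluster (`CLUSTER`) covariance, plus residual. The second
#' stage is unweighted by default; pass `weighted = TRUE` to weight residuals
#' by the stage-1 squared standard errors.
#'
#' The genotype-by-environment term is indexed by location: the enviromic
#' kernel is a location-level similarity (climate and soil do not carry a
#' year subscript), and with more than one year of trials per location the
#' interaction variance is then separable from the residual, which a
#' location-by-year indexing would not allow with a single BLUE per cell.
#' Location-by-year main effects remain fixed, as in the joint model.
#'
#' @param blues BLUE table ([stage1_blues()] format)
#' @param variant one of `"MET"`, `"MET_EC"`, `"WC"`, `"OPT"`, `"CLUSTER"`
#' @param kernel environment relationship matrix (required for `MET_EC`)
#' @param subset locations to keep (required for `WC` and `OPT`)
#' @param assignments named cluster assignment per location (required for
#'   `CLUSTER`)
#' @param weighted use stage-1 SE weights in the residual
#' @return An `lmm_fit` (for `CLUSTER`, `beta` holds the cluster adjusted
#'   means).
#' @export
stage2_fit <- function(blues, variant = c("MET", "MET_EC", "WC", "OPT",
                                          "CLUSTER"),
                       kernel = NULL, subset = NULL, assignments = NULL,
                       weighted = FALSE) {
  variant <- match.arg(variant)
  need <- c("location", "year", "genotype", "blue")
  stopifnot(all(need %in% names(blues)))
  if (variant %in% c("WC", "OPT")) {
    if (is.null(subset)) stop("stage2_fit: subset required for WC/OPT")
    blues <- blues[blues$location %in% subset, , drop = FALSE]
  }
  d <- data.frame(
    blue = blues$blue,
    year = factor(blues$year),
    genotype = factor(blues$genotype),
    env = factor(paste(blues$location, blues$year, sep = ":")),
    location = blues$location,
    stringsAsFactors = FALSE
  )
  if (nlevels(d$env) < 2) stop("stage2_fit: need BLUEs from >= 2 environments")
  w <- if (weighted) {
    stopifnot("se" %in% names(blues))
    se2 <- blues$se^2
    se2 / mean(se2)
  } else NULL

  if (variant == "CLUSTER") {
    if (is.null(assignments)) stop("stage2_fit: assignments required")
    if (!all(d$location %in% names(assignments))) {
      stop("stage2_fit: unassigned locations present")
    }
    d$cluster <- factor(paste0("cluster", assignments[d$location]))
    fit <- fit_reml(d, "blue", fixed = ~ 0 + cluster,
                    random = list(
                      genotype = "genotype",
                      gxc = list(factors = c("genotype", "cluster"))),
                    resid_weights = w)
    return(fit)
  }
  gxe <- if (variant == "MET_EC") {
    if (is.null(kernel)) stop("stage2_fit: kernel required for MET_EC")
    K <- unclass(kernel)
    if (is.null(rownames(K)) || !all(unique(d$location) %in% rownames(K))) {
      stop("stage2_fit: kernel environments do not match BLUE environments")
    }
    list(factors = c("genotype", "location"), kernel = K)
  } else {
    list(factors = c("genotype", "location"))
  }
  fit_reml(d, "blue", fixed = ~ year + env,
           random = list(genotype = "genotype", gxe = gxe),
           resid_weights = w)
}

#' Cullis broad-sense heritability
#'
#' `H2 = 1 - mean_vd / (2 * s2_g)` where `mean_vd` is the mean variance of a
#' difference between genotype BLUPs, computed from the full prediction-error
#' variance matrix. Values are clipped to \[0, 1\] (with a message when
#' clipping occurs). `method = "mean_pev"` instead uses the mean PEV of the
#' BLUPs themselves (`1 - mean_pev / s2_g`), an alternative reading found in
#' some texts; the pairwise-difference form is the default and the standard.
#'
#' @param fit an `lmm_fit` with a genotype random term
#' @param term name of the genotype term
#' @param method `"mvd"` (mean variance of a difference) or `"mean_pev"`
#' @return Heritability in \[0, 1\].
#' @export
cullis_h2 <- function(fit, term = "genotype", method = c("mvd", "mean_pev")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "lmm_fit"), term %in% names(fit$blups))
  s2g <- fit$varcomp[[term]]
  if (s2g <= 0) {
    warning("cullis_h2: genotype variance is zero; H2 defined as 0")
    return(0)
  }
  pev <- attr(fit$blups[[term]], "pev_matrix")
  q <- nrow(pev)
  h2 <- if (method == "mvd") {
    d <- diag(pev)
    vd <- outer(d, d, `+`) - 2 * pev
    mean_vd <- mean(vd[upper.tri(vd)])
    1 - mean_vd / (2 * s2g)
  } else {
    1 - mean(diag(pev)) / s2g
  }
  if (h2 < 0 || h2 > 1) {
    message("cullis_h2: clipping H2 = ", format(h2), " to [0, 1]")
    h2 <- min(max(h2, 0), 1)
  }
  h2
}

#' Variance partitioning of the multi-trial model
#'
#' Refits the stage-2 model with every term random (year, environment,
#' genotype, genotype-by-environment, residual) and reports the estimated
#' variance components and their proportions of the total.
#'
#' @param blues BLUE table ([stage1_blues()] format)
#' @return data frame: `component`, `variance`, `proportion` (sums to 1).
#' @export
variance_partition <- function(blues) {
  d <- data.frame(
    blue = blues$blue,
    year = factor(blues$year),
    genotype = factor(blues$genotype),
    env = factor(paste(blues$location, blues$year, sep = ":")),
    location = blues$location
  )
  fit <- fit_reml(d, "blue", fixed = ~1,
                  random = list(
                    year = "year", env = "env", genotype = "genotype",
                    gxe = list(factors = c("genotype", "location"))))
  v <- fit$varcomp
  data.frame(component = names(v), variance = as.numeric(v),
             proportion = as.numeric(v) / sum(v), row.names = NULL,
             stringsAsFactors = FALSE)
}
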