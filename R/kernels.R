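# Enviromic relationship kernels: trace-normalized environment similarity
# matrices from covariates (Omega) or from yield BLUEs (Omega_yield).

.make_kernel <- function(M, provenance) {
  M <- as.matrix(M)
  G <- tcrossprod(M)
  tr <- sum(diag(G))
  if (tr <= 0) stop("env_kernel: all-zero covariate matrix (trace 0)")
  Om <- G / (tr / nrow(M))
  Om <- (Om + t(Om)) / 2
  structure(Om, provenance = provenance,
            class = c("env_kernel", class(Om)))
}

#' Enviromic relationship kernel
#'
#' `Omega = W W' / (tr(W W') / nrow(W))`: the cross-product of the centered
#' and scaled environment covariate matrix, normalized so that the trace of
#' the kernel equals the number of environments.
#'
#' @param W covariate matrix (rows = environments), e.g. a `covariate_matrix`
#' @return An `env_kernel` matrix with `provenance = "enviromic"`;
#'   symmetric, positive semidefinite, `tr(Omega) = nrow(W)`.
#' @export
env_kernel <- function(W) {
  if (is.null(dim(W)) || nrow(W) == 0 || ncol(W) == 0) {
    stop("env_kernel: W must be a non-empty matrix")
  }
  if (anyNA(W)) stop("env_kernel: missing values in W")
  .make_kernel(unclass(W), "enviromic")
}

#' Yield-based environment kernel
#'
#' Builds the conventional yield-based counterpart of the enviromic kernel:
#' an environment x genotype matrix of stage-1 BLUEs (averaged over years
#' within location so the kernel is conformable with a per-location enviromic
#' kernel), with missing genotype-by-environment cells imputed by the
#' genotype's mean BLUE (reported via a message), columns centered and scaled
#' over environments, then the same trace normalization as [env_kernel()].
#'
#' @param blues BLUE table ([stage1_blues()] format)
#' @return An `env_kernel` with `provenance = "yield"`; attribute `W_yield`
#'   holds the underlying environment x genotype matrix.
#' @export
yield_kernel <- function(blues) {
  stopifnot(all(c("location", "genotype", "blue") %in% names(blues)))
  locs <- sort(unique(blues$location))
  gens <- sort(unique(blues$genotype))
  if (length(locs) < 2) stop("yield_kernel: need >= 2 environments")
  M <- tapply(blues$blue, list(factor(blues$location, locs),
                               factor(blues$genotype, gens)), mean)
  # genotypes observed in >= 2 environments anchor the kernel
  obs_per_gen <- colSums(!is.na(M))
  if (!any(obs_per_gen >= 2)) stop("yield_kernel: no common genotypes")
  n_missing <- sum(is.na(M))
  if (n_missing > 0) {
    message("yield_kernel: imputing ", n_missing,
            " missing genotype-by-environment cell(s) by genotype means")
    gm <- colMeans(M, na.rm = TRUE)
    for (j in seq_along(gens)) M[is.na(M[, j]), j] <- gm[j]
  }
  sds <- apply(M, 2, stats::sd)
  keep <- sds > 0
  M <- scale(M[, keep, drop = FALSE])
  K <- .make_kernel(M, "yield")
  attr(K, "W_yield") <- M
  K
}

#' Compare two environment kernels
#'
#' Pearson correlation over the strict upper-triangle (off-diagonal) entries,
#' plus a per-kernel density summary of those entries: mean, SD, and the
#' location of the density peak from a Gaussian kernel-density estimate
#' (Silverman's rule-of-thumb bandwidth, 512-point grid over the data range
#' extended by 3 bandwidths).
#'
#' @param a,b `env_kernel` objects over the same environments, same order
#' @return A `kernel_comparison` list: `r`, and `density` (data frame with
#'   one row per kernel: peak, mean, sd).
#' @export
compare_kernels <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("compare_kernels: dimension mismatch")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    stop("compare_kernels: environment sets differ")
  }
  ut <- upper.tri(a)
  x <- unclass(a)[ut]
  y <- unclass(b)[ut]
  r <- stats::cor(x, y)
  dens_summary <- function(v, label) {
    d <- stats::density(v, bw = "nrd0", n = 512, cut = 3)
    data.frame(kernel = label, peak = d$x[which.max(d$y)], mean = mean(v),
               sd = stats::sd(v), stringsAsFactors = FALSE)
  }
  lab_a <- attr(a, "provenance"); if (is.null(lab_a)) lab_a <- "a"
  lab_b <- attr(b, "provenance"); if (is.null(lab_b)) lab_b <- "b"
  structure(list(r = r,
                 density = rbind(dens_summary(x, lab_a), dens_summary(y, lab_b))),
            class = "kernel_comparison")
}

#' @export
print.kernel_comparison <- function(x, ...) {
  cat("Kernel comparison: Pearson r (off-diagonal) =", round(x$r, 4), "\n")
  print(x$density, row.names = FALSE)
  invisible(x)
}
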