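# shared helpers for the test suite

# adjusted Rand index between two partitions
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sri <- sum(choose(rowSums(tab), 2))
  scj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  ex <- sri * scj / choose(n, 2)
  denom <- (sri + scj) / 2 - ex
  if (denom == 0) return(1)
  (sij - ex) / denom
}

# a small, fast synthetic network for unit tests
tiny_config <- function(seed = 11, ...) {
  sim_config(n_genotypes = 8, n_genotypes_year1 = 4, n_locations = 6,
             n_years = 2, n_blocks = 3, n_clusters = 2, n_counties = 12,
             seed = seed, ...)
}

# long-format weather with constant series, for window arithmetic tests
constant_weather <- function(value = 18, vars = c("T2M_MIN", "T2M_MAX",
                                                  "T2MDEW"),
                             location = "L01", n_days = 149) {
  do.call(rbind, lapply(vars, function(v) {
    data.frame(location = location, day = 0:(n_days - 1), variable = v,
               value = value, stringsAsFactors = FALSE)
  }))
}

# dense GLS oracle: BLUEs by direct matrix inversion for a given V
gls_oracle <- function(y, X, V) {
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  solve(XtVi %*% X, XtVi %*% y)
}

# brute-force REML log-likelihood (up to the usual constant) for given
# variance components; independent of the engine's internals
reml_loglik_oracle <- function(theta, y, X, Gs) {
  n <- length(y)
  V <- Reduce(`+`, Map(function(t, G) t * G, theta, Gs))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi <- chol2inv(ch)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
            as.numeric(t(y) %*% P %*% y))
}
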