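# Shared fixture builders: small group-LASSO instances and spline-generated
# SIVCM data where the true coefficient functions are exactly representable
# in the basis.

# random small grouped instance: n rows, J predictor groups (plus the
# intercept group), basis of dimension L built on random index values
make_gl_instance <- function(seed, n = 50, J = 3, n_interior = 1, degree = 2) {
  set.seed(seed)
  X <- cbind(`(Intercept)` = 1, matrix(rnorm(n * J), n, J))
  u <- rnorm(n)
  basis <- build_basis(u, n_interior = n_interior, degree = degree)
  y <- rnorm(n)
  list(y = y, X = X, u = u, basis = basis, n = n)
}

# data generated exactly from the spline model: y = sum_j (B gamma_j) x_j,
# so the fitted model can reproduce it with zero residual
make_spline_truth_data <- function(seed, n = 300, p = 3,
                                   theta = normalize_direction(c(2, -1, 0.5)),
                                   n_interior = 8, degree = 3,
                                   noise_sd = 0) {
  set.seed(seed)
  theta <- as.numeric(theta)
  Z <- matrix(rnorm(n * length(theta)), n, length(theta))
  u <- drop(Z %*% theta)
  basis <- build_basis(u, n_interior, degree)
  L <- basis$L
  gamma <- matrix(rnorm(L * (p + 1), sd = 0.5), L, p + 1)
  X <- cbind(`(Intercept)` = 1, matrix(rnorm(n * p), n, p))
  B <- eval_basis(basis, u)
  y <- rowSums((B %*% gamma) * X) + rnorm(n, sd = noise_sd)
  list(y = y, X = X, Z = Z, u = u, basis = basis, gamma = gamma,
       theta = theta)
}

# brute-force VIF backward elimination used as the independent oracle:
# recomputes every VIF from scratch each round via lm()
oracle_vif_eliminate <- function(X, threshold = 5) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  removed <- character(0)
  repeat {
    if (ncol(X) < 2) break
    vifs <- vapply(seq_len(ncol(X)), function(i) {
      if (sd(X[, i]) == 0) return(NA_real_)
      r2 <- summary(lm(X[, i] ~ X[, -i, drop = FALSE]))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    vv <- ifelse(is.na(vifs), -Inf, vifs)
    if (!(max(vv) > threshold)) break
    drop_i <- max(which(vv == max(vv)))
    removed <- c(removed, colnames(X)[drop_i])
    X <- X[, -drop_i, drop = FALSE]
  }
  list(removed = removed, retained = colnames(X))
}

fast_control <- function(...) {
  sivcm_control(n_restarts = 1, ...)
}
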