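# LSSGLASSO estimation of the single-index varying coefficient model
#   y_i = sum_j g_j(theta' Z_i) x_ij + eps_i
# by alternating (i) a group-LASSO fit of the spline coefficient blocks at
# fixed index direction and (ii) damped Gauss-Newton updates of the index
# direction at fixed blocks, tuned over a penalty path by a BIC-type
# criterion, with selected coefficient functions re-estimated by local
# linear regression.

#' Control parameters for the LSSGLASSO fit
#'
#' @param n_interior number of interior spline knots (default 8).
#' @param degree spline degree (default 3).
#' @param n_lambda number of penalty levels on the log-spaced path.
#' @param lambda_min_ratio smallest penalty as a fraction of `lambda_max`.
#' @param min_rows smallest number of observations accepted by
#'   [lssglasso_fit()]; fits on fewer rows are rejected (this drives the
#'   per-year skip logic in [run_yearly_selection()]).
#' @param outer_tol relative residual-sum-of-squares change declaring the
#'   alternation converged.
#' @param outer_maxit maximum alternation iterations per penalty level.
#' @param n_restarts number of index-direction starts: the first is the
#'   least-squares start, the rest are axis-aligned unit vectors; the start
#'   reaching the lowest BIC is kept.
#' @param bcd_tol,bcd_kkt_tol,bcd_maxit block-coordinate-descent tolerances.
#' @param standardize center/scale `y`, the non-intercept columns of `X`,
#'   and `Z` before fitting (the scale the refit is reported on).
#' @param refit_grid_size grid size for the local-linear re-estimates.
#' @param bandwidth local-linear bandwidth; `NULL` means the rule of thumb
#'   `1.06 sd(u) n^{-1/5}`.
#' @return a list of class `sivcm_control`.
#' @export
sivcm_control <- function(n_interior = 8, degree = 3,
                          n_lambda = 50, lambda_min_ratio = 1e-3,
                          min_rows = 30,
                          outer_tol = 1e-6, outer_maxit = 200,
                          n_restarts = 3,
                          bcd_tol = 1e-8, bcd_kkt_tol = 1e-7,
                          bcd_maxit = 20000L,
                          standardize = TRUE,
                          refit_grid_size = 100,
                          bandwidth = NULL) {
  structure(as.list(environment()), class = "sivcm_control")
}

# Least-squares start for the index direction: slopes of y ~ Z, normalized.
init_direction <- function(y, Z) {
  cf <- tryCatch(coef(lm.fit(cbind(1, Z), y))[-1], error = function(e) NULL)
  if (is.null(cf) || !all(is.finite(cf)) || all(abs(cf) < 1e-12)) {
    cf <- c(1, rep(0, ncol(Z) - 1L))
  }
  as.numeric(normalize_direction(cf))
}

# RSS of the spline model at direction th with blocks gamma fixed.
rss_at_theta <- function(y, X, Z, basis, gamma, th) {
  u <- drop(Z %*% th)
  C <- eval_basis(basis, u) %*% gamma
  sum((y - rowSums(C * X))^2)
}

#' One damped Gauss-Newton update of the index direction
#'
#' Takes a single Gauss-Newton step on the direction minimizing the residual
#' sum of squares with the spline blocks held fixed, using the analytic
#' derivative of the basis with respect to the index; the step is halved
#' (at most 10 times) until the RSS does not increase, and the result is
#' renormalized to the unit-norm, positive-leading-component convention.
#' Index values pushed outside the basis boundary are clamped there (their
#' derivative contribution is zero).
#'
#' @param y response; `X` predictor matrix with ones column; `Z` index
#'   covariate matrix.
#' @param basis a `sivcm_basis`.
#' @param gamma `L x (p+1)` spline coefficient matrix.
#' @param theta_current current unit direction.
#' @return list with `theta`, `rss`, `accepted`, `halvings`, `singular`.
#' @export
update_direction <- function(y, X, Z, basis, gamma, theta_current) {
  th0 <- as.numeric(theta_current)
  d <- ncol(Z)
  rss0 <- rss_at_theta(y, X, Z, basis, gamma, th0)
  u <- drop(Z %*% th0)
  inside <- u >= basis$boundary[1] & u <= basis$boundary[2]
  Bd <- eval_basis(basis, u, deriv = 1)
  Bd[!inside, ] <- 0    # clamped points are locally flat in theta
  mprime <- rowSums((Bd %*% gamma) * X)
  J <- mprime * Z
  r <- y - {
    C <- eval_basis(basis, u) %*% gamma
    rowSums(C * X)
  }
  JtJ <- crossprod(J)
  delta <- tryCatch(
    solve(JtJ + 1e-10 * mean(diag(JtJ) + 1e-12) * diag(d), crossprod(J, r)),
    error = function(e) NULL
  )
  if (is.null(delta) || !all(is.finite(delta))) {
    return(list(theta = th0, rss = rss0, accepted = FALSE, halvings = 0L,
                singular = TRUE))
  }
  h <- 1
  for (k in 0:10) {
    cand <- th0 + h * drop(delta)
    if (sqrt(sum(cand^2)) < 1e-12) { h <- h / 2; next }
    thc <- as.numeric(normalize_direction(cand))
    rssc <- rss_at_theta(y, X, Z, basis, gamma, thc)
    if (rssc <= rss0) {
      return(list(theta = thc, rss = rssc, accepted = TRUE, halvings = k,
                  singular = FALSE))
    }
    h <- h / 2
  }
  list(theta = th0, rss = rss0, accepted = FALSE, halvings = 10L,
       singular = FALSE)
}

# Alternate group-LASSO block fits and direction updates at one penalty
# level until the relative RSS change is below outer_tol.
fit_at_lambda <- function(y, X, Z, lambda, theta_init, gamma_init = NULL,
                          control = sivcm_control()) {
  th <- as.numeric(theta_init)
  gamma <- gamma_init
  rss_prev <- Inf
  basis <- NULL; gl <- NULL
  iters <- 0L
  for (it in seq_len(control$outer_maxit)) {
    iters <- it
    u <- drop(Z %*% th)
    basis <- build_basis(u, control$n_interior, control$degree)
    gl <- group_lasso_coefficients(y, X, basis, u, lambda,
                                   gamma_init = gamma,
                                   tol = control$bcd_tol,
                                   kkt_tol = control$bcd_kkt_tol,
                                   maxit = control$bcd_maxit)
    gamma <- gl$gamma
    if (ncol(Z) > 1L) {
      st <- update_direction(y, X, Z, basis, gamma, th)
      th <- st$theta
      rss <- st$rss
    } else {
      th <- 1
      rss <- gl$rss
    }
    if (is.finite(rss_prev) &&
        abs(rss_prev - rss) <= control$outer_tol * max(rss_prev, 1e-12)) {
      rss_prev <- rss
      break
    }
    rss_prev <- rss
  }
  list(theta = th, gamma = gamma, basis = basis, group_fit = gl,
       rss = rss_prev, selected = gl$selected, iterations = iters,
       converged = gl$converged)
}

#' Tune the penalty level by a BIC-type criterion
#'
#' Runs the alternating fit over a decreasing log-spaced penalty path with
#' warm starts and scores each level by
#' `BIC(lambda) = n log(RSS/n) + df log(n)` with `df = L (|S|+1)` counting
#' one full spline block per retained function (intercept included). Ties
#' are resolved toward the larger penalty (the sparser model).
#'
#' @inheritParams update_direction
#' @param lambda_grid optional decreasing penalty grid; by default 50
#'   log-spaced points from `lambda_max` down to `lambda_max * 1e-3`.
#' @param theta_init starting direction (default: least-squares start).
#' @param control a [sivcm_control()] list.
#' @return list with `lambda_star`, `best` (the winning fit), and `path`
#'   (data frame of lambda, rss, n_selected, df, bic, convergence).
#' @export
bic_select_lambda <- function(y, X, Z, lambda_grid = NULL,
                              theta_init = NULL,
                              control = sivcm_control()) {
  n <- length(y)
  L <- control$n_interior + control$degree + 1
  if (is.null(theta_init)) theta_init <- init_direction(y, Z)
  if (is.null(lambda_grid)) {
    u0 <- drop(Z %*% theta_init)
    b0 <- build_basis(u0, control$n_interior, control$degree)
    lmax <- lambda_max(y, X, b0, u0)
    lambda_grid <- exp(seq(log(lmax), log(lmax * control$lambda_min_ratio),
                           length.out = control$n_lambda))
  }
  lambda_grid <- sort(as.numeric(lambda_grid), decreasing = TRUE)
  th <- theta_init
  gamma <- NULL
  fits <- vector("list", length(lambda_grid))
  path <- data.frame(lambda = lambda_grid, rss = NA_real_,
                     n_selected = NA_integer_, df = NA_real_,
                     bic = NA_real_, converged = NA)
  for (k in seq_along(lambda_grid)) {
    f <- fit_at_lambda(y, X, Z, lambda_grid[k], th, gamma, control)
    th <- f$theta
    gamma <- f$gamma
    df <- L * (length(f$selected) + 1)
    path$rss[k] <- f$rss
    path$n_selected[k] <- length(f$selected)
    path$df[k] <- df
    path$bic[k] <- n * log(max(f$rss, 1e-300) / n) + df * log(n)
    path$converged[k] <- f$converged
    fits[[k]] <- f
  }
  if (!any(path$converged)) stop("no penalty level produced a converged fit")
  k_star <- which.min(path$bic)   # first minimum = largest lambda on ties
  list(lambda_star = lambda_grid[k_star], best = fits[[k_star]], path = path)
}

#' Fit and select a single-index varying coefficient model
#'
#' The full estimation procedure: standardize the inputs, drop constant
#' index covariates (a constant coordinate is unidentifiable in the index),
#' alternate spline-block and direction updates over a BIC-tuned group-LASSO
#' penalty path from several direction starts, and re-estimate the selected
#' coefficient functions by local linear regression on a grid.
#'
#' @param y response vector.
#' @param X predictor matrix **without** the intercept column (one column
#'   per candidate variable), or with a leading all-ones column named
#'   `"(Intercept)"`; an intercept block is always included and never
#'   penalized away.
#' @param Z index covariate matrix (longitude, latitude, year).
#' @param control a [sivcm_control()] list.
#' @return an object of class `sivcm_fit` with elements `theta` (unit
#'   direction over the retained index covariates), `z_kept`, `selected`
#'   (names of selected variables), `gamma`, `basis`, `lambda_star`,
#'   `path`, `rss`, `refit` (local-linear grid estimates), `scales`, and
#'   iteration diagnostics.
#' @export
lssglasso_fit <- function(y, X, Z, control = sivcm_control()) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  Z <- as.matrix(Z)
  n <- length(y)
  if (n < control$min_rows) {
    stop(sprintf("fit rejected: %d rows is fewer than the minimum of %d",
                 n, control$min_rows))
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (colnames(X)[1] == "(Intercept)" ||
      all(X[, 1] == 1)) {
    X <- X[, -1, drop = FALSE]
  }
  var_names <- colnames(X)
  # standardization (the scale the refit is reported on)
  scales <- list()
  if (control$standardize) {
    ys <- sd(y); if (!is.finite(ys) || ys == 0) ys <- 1
    scales$y <- c(center = mean(y), scale = ys)
    y <- (y - mean(y)) / ys
    xs <- apply(X, 2, sd); xs[!is.finite(xs) | xs == 0] <- 1
    xc <- colMeans(X)
    scales$x <- rbind(center = xc, scale = xs)
    X <- sweep(sweep(X, 2, xc), 2, xs, "/")
  }
  z_sd <- apply(Z, 2, sd)
  z_kept <- which(is.finite(z_sd) & z_sd > 1e-12)
  if (length(z_kept) == 0L) stop("all index covariates are constant")
  Zu <- Z[, z_kept, drop = FALSE]
  if (control$standardize) {
    zc <- colMeans(Zu); zs <- apply(Zu, 2, sd)
    scales$z <- rbind(center = zc, scale = zs)
    Zu <- sweep(sweep(Zu, 2, zc), 2, zs, "/")
  }
  Xf <- cbind(`(Intercept)` = 1, X)

  # direction starts: least-squares start, then axis-aligned units
  d <- ncol(Zu)
  starts <- list(init_direction(y, Zu))
  if (control$n_restarts > 1L && d > 1L) {
    for (k in seq_len(min(control$n_restarts - 1L, d))) {
      e <- rep(0, d); e[k] <- 1
      starts[[length(starts) + 1L]] <- e
    }
  }
  best <- NULL; best_bic <- Inf; best_path <- NULL; best_lambda <- NA_real_
  for (s in starts) {
    sel <- bic_select_lambda(y, Xf, Zu, theta_init = s, control = control)
    bic_s <- min(sel$path$bic)
    if (bic_s < best_bic) {
      best_bic <- bic_s
      best <- sel$best
      best_path <- sel$path
      best_lambda <- sel$lambda_star
    }
  }

  u_hat <- drop(Zu %*% best$theta)
  refit <- local_linear_refit(y, Xf, u_hat, selected = best$selected,
                              bandwidth = control$bandwidth,
                              n_grid = control$refit_grid_size)
  theta <- normalize_direction(best$theta)
  structure(
    list(theta = theta, z_kept = z_kept,
         selected = var_names[best$selected],
         selected_idx = best$selected,
         gamma = best$gamma, basis = best$basis,
         lambda_star = best_lambda, path = best_path, bic = best_bic,
         rss = best$rss, refit = refit, u = u_hat,
         iterations = best$iterations, converged = best$converged,
         scales = scales, n = n, var_names = var_names,
         control = control),
    class = "sivcm_fit"
  )
}

#' @export
print.sivcm_fit <- function(x, ...) {
  cat("Single-index varying coefficient model (LSSGLASSO)\n")
  cat(sprintf("  n = %d, candidate variables = %d\n", x$n, length(x$var_names)))
  cat("  index direction: (", paste(sprintf("%.4f", unclass(x$theta)),
                                    collapse = ", "), ")\n", sep = "")
  cat(sprintf("  lambda* = %.5g (BIC = %.2f), RSS = %.4f\n",
              x$lambda_star, x$bic, x$rss))
  if (length(x$selected)) {
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  } else {
    cat("  selected: (none)\n")
  }
  invisible(x)
}

#' Local linear re-estimation of selected coefficient functions
#'
#' Re-estimates each retained coefficient function by a local linear kernel
#' varying-coefficient fit (Epanechnikov kernel) against the index, cycling
#' over functions via backfitting on partial residuals (5 cycles or relative
#' change below `tol`). A grid point whose bandwidth window holds fewer than
#' `nn_floor` observations has its window widened to the `nn_floor` nearest
#' neighbours.
#'
#' @param y response (on the fitting scale).
#' @param X predictor matrix with leading ones column.
#' @param u index values.
#' @param selected indices (`j >= 1`) of selected variables; the intercept
#'   function is always re-estimated.
#' @param bandwidth kernel bandwidth; `NULL` uses `1.06 sd(u) n^{-1/5}`.
#' @param grid evaluation grid; default `n_grid` equispaced points over the
#'   observed index range.
#' @param n_grid grid size when `grid` is `NULL`.
#' @param cycles maximum backfitting cycles.
#' @param tol relative-change convergence tolerance for backfitting.
#' @param nn_floor minimum number of observations per local fit.
#' @return list with `grid`, `estimates` (matrix, one column per retained
#'   function, intercept first), `fitted_at_data`, `bandwidth`, `groups`.
#' @export
local_linear_refit <- function(y, X, u, selected = integer(0),
                               bandwidth = NULL, grid = NULL, n_grid = 100,
                               cycles = 5, tol = 1e-5, nn_floor = 10) {
  n <- length(y)
  if (is.null(bandwidth)) bandwidth <- 1.06 * sd(u) * n^(-1/5)
  stopifnot(bandwidth > 0)
  if (is.null(grid)) grid <- seq(min(u), max(u), length.out = n_grid)
  groups <- c(1L, as.integer(selected) + 1L)  # columns of X (intercept first)
  J <- length(groups)
  ghat <- matrix(0, n, J)
  for (cyc in seq_len(cycles)) {
    delta <- 0
    for (jj in seq_len(J)) {
      other <- if (J > 1L) {
        rowSums(ghat[, -jj, drop = FALSE] * X[, groups[-jj], drop = FALSE])
      } else rep(0, n)
      e <- y - other
      new_g <- loclin_vc(e, X[, groups[jj]], u, u, bandwidth, nn_floor)
      delta <- max(delta, max(abs(new_g - ghat[, jj])) /
                     max(1, max(abs(new_g))))
      ghat[, jj] <- new_g
    }
    if (delta < tol) break
  }
  est <- matrix(NA_real_, length(grid), J)
  for (jj in seq_len(J)) {
    other <- if (J > 1L) {
      rowSums(ghat[, -jj, drop = FALSE] * X[, groups[-jj], drop = FALSE])
    } else rep(0, n)
    est[, jj] <- loclin_vc(y - other, X[, groups[jj]], u, grid,
                           bandwidth, nn_floor)
  }
  colnames(est) <- c("g0",
                     if (length(selected)) paste0("g", selected))
  list(grid = grid, estimates = est, fitted_at_data = ghat,
       bandwidth = bandwidth, groups = groups)
}

# Local linear varying-coefficient smoother: at each u0 solve the weighted
# least squares of e on (x, x*(u-u0)) with Epanechnikov weights and return
# the local level a(u0).
loclin_vc <- function(e, x, u, eval_points, h, nn_floor) {
  n <- length(u)
  nn_floor <- min(nn_floor, n)
  out <- numeric(length(eval_points))
  for (k in seq_along(eval_points)) {
    d <- u - eval_points[k]
    hk <- h
    w <- pmax(0, 1 - (d / hk)^2)
    if (sum(w > 0) < nn_floor) {
      hk <- sort(abs(d))[nn_floor] * (1 + 1e-8)
      w <- pmax(0, 1 - (d / hk)^2)
    }
    x1 <- x * w
    a11 <- sum(x1 * x); a12 <- sum(x1 * x * d)
    a22 <- sum(x1 * x * d * d)
    b1 <- sum(x1 * e); b2 <- sum(x1 * d * e)
    det <- a11 * a22 - a12 * a12
    if (abs(det) < 1e-12 * max(a11 * a22, 1)) {
      out[k] <- if (a11 > 0) b1 / a11 else 0   # fall back to local constant
    } else {
      out[k] <- (a22 * b1 - a12 * b2) / det
    }
  }
  out
}
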