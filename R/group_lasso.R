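# Spline-expanded grouped design and the group-LASSO coefficient step.
#
# The expanded design has one block of L columns per predictor j = 0..p,
# D_j[i, l] = x_ij * B_l(u_i); the group-LASSO penalty acts on whole blocks,
# zeroing entire coefficient functions. The intercept function block (j = 0)
# is never penalized.

#' Build the spline-expanded grouped design matrix
#'
#' @param X predictor matrix including the leading all-ones column.
#' @param B basis matrix (rows = observations, columns = L basis functions).
#' @return an `n x (p+1)L` matrix whose j-th block is `X[, j] * B`.
#' @keywords internal
expand_design <- function(X, B) {
  p1 <- ncol(X)
  L <- ncol(B)
  X[, rep(seq_len(p1), each = L), drop = FALSE] *
    B[, rep(seq_len(L), p1), drop = FALSE]
}

#' Group-LASSO estimate of the spline coefficient blocks
#'
#' Minimizes `(1/2n)||y - sum_j (x_j o B gamma_j)||^2 + lambda sum_{j>=1} w_j
#' ||gamma_j||_2` with group weights `w_j = sqrt(L)` and the intercept block
#' unpenalized, by block coordinate descent with exact blockwise minimization.
#' The returned solution satisfies the group Karush-Kuhn-Tucker conditions
#' within `kkt_tol`; at `lambda = 0` it coincides with ordinary least squares
#' on the expanded design.
#'
#' @param y response vector.
#' @param X predictor matrix with leading all-ones column.
#' @param basis a `sivcm_basis` object (see [build_basis()]).
#' @param u index values, one per row of `X`.
#' @param lambda nonnegative penalty level.
#' @param gamma_init optional warm-start coefficient matrix (`L x (p+1)`).
#' @param tol coordinate-change convergence tolerance.
#' @param kkt_tol required Karush-Kuhn-Tucker residual at the solution.
#' @param maxit maximum number of full block sweeps.
#' @return an object of class `group_coefficients`: list with `gamma`
#'   (`L x (p+1)` matrix), `selected` (indices `j >= 1` with nonzero
#'   blocks), `rss`, `kkt`, `converged`, `iterations`, `lambda`.
#' @export
group_lasso_coefficients <- function(y, X, basis, u, lambda,
                                     gamma_init = NULL,
                                     tol = 1e-8, kkt_tol = 1e-7,
                                     maxit = 50000L) {
  stopifnot(lambda >= 0, length(y) == nrow(X), length(u) == length(y))
  n <- length(y)
  p1 <- ncol(X)
  L <- basis$L
  B <- eval_basis(basis, u)
  D <- expand_design(X, B)
  G <- crossprod(D) / n
  cvec <- drop(crossprod(D, y)) / n
  yy <- sum(y^2) / n
  gstart <- as.integer((seq_len(p1) - 1L) * L)
  gend <- as.integer(gstart + L - 1L)
  w <- c(0, rep(sqrt(L), p1 - 1L))     # intercept block unpenalized
  pen <- lambda * w
  g0 <- if (is.null(gamma_init)) rep(0, p1 * L) else as.numeric(gamma_init)
  sol <- .bcd_group_lasso(G, cvec, yy, gstart, gend, pen, g0,
                          tol, kkt_tol, as.integer(maxit))
  if (lambda == 0) {
    # unpenalized limit: finish with the exact least-squares solution when
    # the expanded design has full column rank
    qd <- qr(D)
    if (qd$rank == ncol(D)) {
      sol$gamma <- qr.coef(qd, y)
      sol$converged <- TRUE
      grad <- drop(G %*% sol$gamma) - cvec
      sol$kkt <- max(abs(grad))
    }
  }
  gamma <- matrix(sol$gamma, nrow = L, ncol = p1)
  norms <- sqrt(colSums(gamma^2))
  fitted <- drop(D %*% sol$gamma)
  structure(
    list(gamma = gamma, group_norms = norms,
         selected = which(norms[-1] > 0),
         fitted = fitted, rss = sum((y - fitted)^2),
         kkt = sol$kkt, converged = sol$converged,
         iterations = sol$iterations, lambda = lambda, weights = w),
    class = "group_coefficients"
  )
}

#' Smallest penalty level at which all penalized blocks are zero
#'
#' Computed from the residual after fitting the unpenalized intercept block
#' alone: `lambda_max = max_j ||D_j' r0||_2 / (n w_j)`.
#'
#' @inheritParams group_lasso_coefficients
#' @return scalar penalty level.
#' @export
lambda_max <- function(y, X, basis, u) {
  n <- length(y)
  L <- basis$L
  B <- eval_basis(basis, u)
  # intercept-block-only least squares fit
  q0 <- qr(B * X[, 1])
  r0 <- y - qr.fitted(q0, y)
  w <- sqrt(L)
  vals <- vapply(seq_len(ncol(X) - 1L), function(j) {
    Dj <- X[, j + 1L] * B
    sqrt(sum(drop(crossprod(Dj, r0))^2)) / (n * w)
  }, numeric(1))
  max(vals)
}

#' Verify the group Karush-Kuhn-Tucker certificate of a solution
#'
#' Active blocks must satisfy `grad_j + lambda w_j gamma_j/||gamma_j|| = 0`;
#' inactive blocks must satisfy `||grad_j|| <= lambda w_j`, both within
#' `tol`. The gradient is taken on the `1/2n` least-squares scale.
#'
#' @param fit a `group_coefficients` object.
#' @inheritParams group_lasso_coefficients
#' @param tol certificate tolerance.
#' @return list with `ok` (logical), `worst` (largest violation), and the
#'   per-block residuals.
#' @export
check_group_kkt <- function(fit, y, X, basis, u, tol = 1e-6) {
  n <- length(y)
  B <- eval_basis(basis, u)
  D <- expand_design(X, B)
  L <- basis$L
  p1 <- ncol(X)
  resid <- y - drop(D %*% as.numeric(fit$gamma))
  grad <- -drop(crossprod(D, resid)) / n
  pen <- fit$lambda * fit$weights
  per_block <- vapply(seq_len(p1), function(j) {
    idx <- ((j - 1L) * L + 1L):(j * L)
    gj <- fit$gamma[, j]
    if (sqrt(sum(gj^2)) > 0) {
      sqrt(sum((grad[idx] + pen[j] * gj / sqrt(sum(gj^2)))^2))
    } else {
      max(0, sqrt(sum(grad[idx]^2)) - pen[j])
    }
  }, numeric(1))
  list(ok = max(per_block) <= tol, worst = max(per_block),
       per_block = per_block)
}
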