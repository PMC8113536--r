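#' Build a B-spline basis on observed index values
#'
#' Interior knots are placed at empirical quantiles of the index values, with
#' boundary knots at the observed range, giving a basis of dimension
#' `L = n_interior + degree + 1` (L = 12 at the defaults of eight interior
#' knots and cubic degree). Index values that fall outside the boundary
#' knots at evaluation time are clamped to the boundary, so evaluation never
#' produces NaN during direction updates.
#'
#' @param u numeric vector of index values the basis is anchored on.
#' @param n_interior number of interior knots (default 8).
#' @param degree spline degree (default 3, cubic).
#' @return an object of class `sivcm_basis` with elements `knots` (full knot
#'   vector), `interior`, `boundary`, `degree` and `L`.
#' @export
build_basis <- function(u, n_interior = 8, degree = 3) {
  u <- as.numeric(u)
  L <- n_interior + degree + 1
  if (length(unique(u)) < L) {
    stop(sprintf("need at least %d distinct index values for a basis of dimension %d",
                 L, L))
  }
  boundary <- range(u)
  probs <- seq_len(n_interior) / (n_interior + 1)
  interior <- as.numeric(quantile(u, probs, type = 7, names = FALSE))
  knots <- c(rep(boundary[1], degree + 1), interior, rep(boundary[2], degree + 1))
  structure(
    list(knots = knots, interior = interior, boundary = boundary,
         degree = degree, L = L),
    class = "sivcm_basis"
  )
}

#' Evaluate a spline basis (or a derivative) at index values
#'
#' @param basis a `sivcm_basis` object.
#' @param u numeric vector of evaluation points; points outside the boundary
#'   knots are clamped to the boundary.
#' @param deriv derivative order (0 = function values).
#' @return an `length(u) x L` matrix of basis values.
#' @export
eval_basis <- function(basis, u, deriv = 0) {
  stopifnot(inherits(basis, "sivcm_basis"))
  u <- pmin(pmax(as.numeric(u), basis$boundary[1]), basis$boundary[2])
  splines::splineDesign(basis$knots, u, ord = basis$degree + 1,
                        derivs = rep(deriv, length(u)))
}
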