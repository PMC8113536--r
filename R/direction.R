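#' Normalize a single-index direction vector
#'
#' The single-index direction of an SIVCM is identifiable only up to sign and
#' scale, so estimates are reported under the convention of unit Euclidean
#' norm with a strictly positive leading component. If the leading component
#' is exactly zero the sign is fixed by the next nonzero component (negated
#' when that component is negative).
#'
#' @param raw numeric vector, the unnormalized direction; must be nonzero.
#' @return a unit-norm numeric vector of class `index_direction` with the
#'   sign convention applied.
#' @examples
#' normalize_direction(c(-1, 0, 0))   # -> c(1, 0, 0)
#' normalize_direction(c(3, 4, 0))    # -> c(0.6, 0.8, 0)
#' @export
normalize_direction <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) < 1L || !all(is.finite(raw))) {
    stop("direction must be a finite numeric vector")
  }
  nrm <- sqrt(sum(raw^2))
  if (nrm == 0) stop("cannot normalize a zero direction vector")
  theta <- raw / nrm
  # sign convention: first nonzero component positive, cascading through ties
  for (k in seq_along(theta)) {
    if (theta[k] > 0) break
    if (theta[k] < 0) {
      theta <- -theta
      break
    }
  }
  structure(theta, class = "index_direction")
}

#' Angle between two direction vectors, in degrees
#'
#' Directions are compared up to sign, matching the identifiability of the
#' single-index model: the reported angle is the smaller of the angles to
#' `b` and to `-b`.
#'
#' @param a,b numeric vectors of equal length.
#' @return angle in degrees in `[0, 90]`.
#' @export
direction_angle <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  ca <- abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  acos(min(1, max(-1, ca))) * 180 / pi
}
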