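#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline basis in the Harrell parameterisation:
#' piecewise cubic between the knots, constrained to be linear beyond the
#' boundary knots. With `k` knots the basis has `k - 1` columns, the first
#' being the identity (linear) term, so an intercept is *not* included.
#'
#' The nonlinear columns are scaled by the squared knot range, which keeps the
#' coefficients on a scale comparable to the linear term. All nonlinear
#' columns are exactly zero for `x` at or below the first knot.
#'
#' @param x numeric vector of evaluation points.
#' @param knots strictly increasing numeric vector of at least 3 knots.
#' @return numeric matrix with `length(x)` rows and `length(knots) - 1`
#'   columns; attribute `"knots"` carries the knot vector.
#' @examples
#' b <- rcs_basis(seq(2002, 2018, by = 0.5), knots = c(2002, 2006, 2010, 2016))
#' @export
rcs_basis <- function(x, knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 3L) stop("rcs_basis needs at least 3 knots")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  k <- length(knots)
  t1 <- knots[1L]; tk1 <- knots[k - 1L]; tk <- knots[k]
  scale2 <- (tk - t1)^2
  cub <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (cub(x - tj) -
      cub(x - tk1) * (tk - tj) / (tk - tk1) +
      cub(x - tk) * (tk1 - tj) / (tk - tk1)) / scale2
  }
  colnames(out) <- c("lin", paste0("nl", seq_len(k - 2L)))
  attr(out, "knots") <- knots
  out
}
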