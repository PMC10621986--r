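#' @keywords internal
"_PACKAGE"

## Elementary rotation matrices (right-handed, active rotations of column
## vectors). Angles in radians throughout the package.

rot_x <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3L, 3L)
}

rot_y <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3L, 3L)
}

rot_z <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3L, 3L)
}

## Head-orientation rotation: yaw about z, then inclination about y, then roll
## about the (already rotated) body axis -- applied in Z-Y-X order.
head_rotation <- function(theta0, phi0, gamma0) {
  rot_z(theta0) %*% rot_y(phi0) %*% rot_x(gamma0)
}

#' Wrap angles to (-pi, pi]
#'
#' @param a numeric vector of angles (rad).
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

## Unwrap a time series of angles so that jumps never exceed pi.
unwrap_angle <- function(a) {
  if (length(a) < 2L) return(a)
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  a[1L] + c(0, cumsum(d))
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

## logsumexp along rows of a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

stopifnot_finite <- function(x, what = deparse(substitute(x))) {
  if (!all(is.finite(x))) stop(sprintf("'%s' must be finite", what), call. = FALSE)
  invisible(x)
}
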