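## Bout-level swim kinematics, statistics and bending modes.

#' Kinematic summary of a swim bout
#'
#' Extracts the time series of the head Euler angles, the average lateral
#' and dorso-ventral bending angles, and the centroid, and summarizes each
#' angle by its maximum change (the signed extremum of the deviation from
#' the first frame; optionally the max-minus-min range) and its total change
#' (final minus initial). Angle series are unwrapped before differencing.
#'
#' @param bout a \code{swim_bout}.
#' @param convention \code{"extremum"} (signed extremum of the deviation
#'   from the first frame, the default) or \code{"range"} (max - min).
#' @return an object of class \code{bout_kinematics}: \code{series}
#'   (data.frame with time, theta0, phi0, gamma0, mean_dtheta, mean_dphi,
#'   x0, y0, z0), \code{max_change} and \code{total_change} (named vectors,
#'   rad), and \code{z_range} (mm).
#' @export
bout_kinematics <- function(bout, convention = c("extremum", "range")) {
  convention <- match.arg(convention)
  stopifnot(inherits(bout, "swim_bout"), length(bout$poses) >= 2L)
  series <- data.frame(
    time = bout$times,
    theta0 = unwrap_angle(vapply(bout$poses, `[[`, numeric(1L), "theta0")),
    phi0 = unwrap_angle(vapply(bout$poses, `[[`, numeric(1L), "phi0")),
    gamma0 = unwrap_angle(vapply(bout$poses, `[[`, numeric(1L), "gamma0")),
    mean_dtheta = vapply(bout$poses, function(p) mean(p$dtheta), numeric(1L)),
    mean_dphi = vapply(bout$poses, function(p) mean(p$dphi), numeric(1L)),
    x0 = vapply(bout$poses, `[[`, numeric(1L), "x0"),
    y0 = vapply(bout$poses, `[[`, numeric(1L), "y0"),
    z0 = vapply(bout$poses, `[[`, numeric(1L), "z0"))
  vars <- c("theta0", "phi0", "gamma0", "mean_dtheta", "mean_dphi")
  max_change <- vapply(vars, function(v) {
    dev <- series[[v]] - series[[v]][1L]
    if (convention == "range") diff(range(dev))
    else dev[which.max(abs(dev))]
  }, numeric(1L))
  total_change <- vapply(vars, function(v)
    series[[v]][nrow(series)] - series[[v]][1L], numeric(1L))
  structure(list(series = series, max_change = max_change,
                 total_change = total_change,
                 z_range = diff(range(series$z0 - series$z0[1L])),
                 convention = convention),
            class = "bout_kinematics")
}

#' @export
print.bout_kinematics <- function(x, ...) {
  cat(sprintf("<bout_kinematics> %d frames; max dYaw %.1f deg, max dInc %.1f deg, max dRoll %.1f deg, z range %.2f mm\n",
              nrow(x$series), x$max_change["theta0"] * 180 / pi,
              x$max_change["phi0"] * 180 / pi,
              x$max_change["gamma0"] * 180 / pi, x$z_range))
  invisible(x)
}

#' Quartile summary
#'
#' Linear-interpolation quartiles (R quantile type 7).
#'
#' @param values numeric vector (n >= 4).
#' @return named numeric: Q1, Q3, IQR.
#' @export
quartile_summary <- function(values) {
  stopifnot(length(values) >= 4L)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  c(Q1 = q[1L], Q3 = q[2L], IQR = q[2L] - q[1L])
}

#' Bootstrap test for a difference of means
#'
#' Pools both samples under the null that they come from one distribution,
#' repeatedly draws two resamples of the original sizes, and computes the
#' one-sided p-value Pr(D >= mu1 - mu2) where mu1 > mu2 by convention (the
#' samples are swapped internally if needed). The same machinery applies to
#' quartile differences via \code{statistic}.
#'
#' @param a,b numeric samples. Unequal sizes are supported (flagged via a
#'   message suppressible with \code{warn_unequal = FALSE}).
#' @param n_resamples number of bootstrap draws (default 10000).
#' @param statistic function of a sample (default \code{mean}; use e.g. a
#'   quartile for quartile tests).
#' @param order_by_mean relabel the samples so the larger statistic comes
#'   first (the reporting convention; default). Disable to test a
#'   pre-specified direction -- the signed one-sided p-value is then uniform
#'   under the null, whereas the relabelled one is folded onto (0, 0.5].
#' @param warn_unequal message when sample sizes differ.
#' @return list with \code{p}, \code{observed}, \code{null} (the resampled
#'   differences).
#' @export
bootstrap_mean_difference_test <- function(a, b, n_resamples = 10000L,
                                           statistic = mean,
                                           order_by_mean = TRUE,
                                           warn_unequal = TRUE) {
  if (length(a) != length(b) && warn_unequal)
    message("sample sizes differ; resampling preserves the original sizes")
  if (order_by_mean && statistic(a) < statistic(b)) {
    tmp <- a; a <- b; b <- tmp
  }
  obs <- statistic(a) - statistic(b)
  pool <- c(a, b)
  na <- length(a); nb <- length(b)
  d <- vapply(seq_len(n_resamples), function(i) {
    s1 <- sample(pool, na, replace = TRUE)
    s2 <- sample(pool, nb, replace = TRUE)
    statistic(s1) - statistic(s2)
  }, numeric(1L))
  list(p = mean(d >= obs), observed = obs, null = d)
}

#' Exact binomial asymmetry test
#'
#' Upper-tail probability P(X >= k) under Binomial(n, p0): the probability
#' of observing at least the given count under the symmetric (p0 = 0.5) or
#' quadrant (p0 = 0.25) null.
#'
#' @param k observed count (0 <= k <= n).
#' @param n number of trials.
#' @param p0 null success probability.
#' @return p-value.
#' @export
binomial_asymmetry_test <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n)
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Bending eigenshapes by singular value decomposition
#'
#' SVD of the (optionally mean-centred) frames x 16 matrix of bending
#' angles (dtheta1..8, dphi1..8) stacked over swim bouts. Modes are ordered
#' by decreasing singular value and labelled lateral- or dorsal-dominant by
#' the energy split between their dtheta and dphi halves.
#'
#' @param theta_matrix frames x 16 matrix (columns dtheta1..8, dphi1..8),
#'   rad.
#' @param center subtract the column means first (default TRUE).
#' @return list with \code{modes} (16 x 16, columns are eigenshapes),
#'   \code{variance_fraction}, \code{cumulative}, \code{label} ("lateral" /
#'   "dorsal"), \code{singular_values}.
#' @export
eigenshapes <- function(theta_matrix, center = TRUE) {
  stopifnot(ncol(theta_matrix) == 16L, nrow(theta_matrix) >= 2L)
  m <- if (center) scale(theta_matrix, center = TRUE, scale = FALSE)
       else theta_matrix
  sv <- svd(m)
  frac <- sv$d^2 / sum(sv$d^2)
  label <- apply(sv$v, 2L, function(v)
    if (sum(v[1:8]^2) >= sum(v[9:16]^2)) "lateral" else "dorsal")
  list(modes = sv$v, variance_fraction = frac, cumulative = cumsum(frac),
       label = label, singular_values = sv$d)
}

#' Write a per-frame pose table for a bout
#'
#' CSV with frame index, time, the 22 parameters, length, and score.
#'
#' @param bout a \code{swim_bout}.
#' @param path output CSV path.
#' @export
write_bout_csv <- function(bout, path) {
  m <- t(vapply(bout$poses, function(p) c(pose_to_vector(p), p$length),
                numeric(23L)))
  colnames(m) <- c("x0", "y0", "z0", "theta0", paste0("dtheta", 1:8),
                   "phi0", paste0("dphi", 1:8), "gamma0", "L")
  d <- data.frame(frame = seq_along(bout$poses), time = bout$times, m,
                  score = if (is.null(bout$scores)) NA_real_ else bout$scores)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
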