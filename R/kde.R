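#' Multivariate Gaussian kernel density estimate
#'
#' Isotropic Gaussian kernel with a single scalar bandwidth shared across all
#' dimensions (radians for angle spaces). Used both in the 2-D curvature
#' space (uniform resampling of pose ensembles) and in the 18-D bending-angle
#' space (generation of synthetic pose ensembles).
#'
#' @param x n x d matrix of samples.
#' @param bandwidth kernel standard deviation (> 0).
#' @return an object of class \code{gaussian_kde}.
#' @export
gaussian_kde <- function(x, bandwidth) {
  x <- as.matrix(x)
  stopifnot(bandwidth > 0, nrow(x) >= 1L)
  structure(list(x = x, bandwidth = bandwidth, d = ncol(x), n = nrow(x)),
            class = "gaussian_kde")
}

#' @rdname gaussian_kde
#' @param kde a \code{gaussian_kde}.
#' @param y m x d matrix of evaluation points.
#' @return \code{kde_log_density} returns the log density at each row of y.
#' @export
kde_log_density <- function(kde, y) {
  y <- as.matrix(y)
  stopifnot(ncol(y) == kde$d)
  h2 <- kde$bandwidth^2
  d2 <- outer(rowSums(y^2), rowSums(kde$x^2), "+") - 2 * tcrossprod(y, kde$x)
  d2[d2 < 0] <- 0
  row_logsumexp(-d2 / (2 * h2)) - log(kde$n) -
    kde$d / 2 * log(2 * pi * h2)
}

#' @rdname gaussian_kde
#' @export
kde_density <- function(kde, y) exp(kde_log_density(kde, y))

#' @rdname gaussian_kde
#' @param n number of draws.
#' @return \code{kde_sample} returns an n x d matrix: a resampled data point
#'   plus isotropic Gaussian jitter of sd = bandwidth per draw.
#' @export
kde_sample <- function(kde, n) {
  idx <- sample.int(kde$n, n, replace = TRUE)
  kde$x[idx, , drop = FALSE] +
    matrix(stats::rnorm(n * kde$d, sd = kde$bandwidth), n, kde$d)
}

#' Cross-validated bandwidth selection
#'
#' Grid search over candidate bandwidths by repeated random-split
#' cross-validation: in each of \code{folds} iterations the sample is split
#' into a held-out test set and a training set in a 1:9 ratio, the KDE is
#' fitted on the training part, and the candidate maximizing the mean
#' held-out log-likelihood across folds is returned.
#'
#' @param x n x d sample matrix.
#' @param candidates bandwidth grid; default 50 values uniformly spanning
#'   [0.01, 0.1] rad.
#' @param folds number of cross-validation splits (default 20).
#' @return the selected bandwidth (scalar). With degenerate (all identical)
#'   samples the smallest candidate is returned with a warning.
#' @export
select_bandwidth <- function(x, candidates = seq(0.01, 0.1, length.out = 50L),
                             folds = 20L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < folds) stop("need at least as many samples as folds")
  if (max(apply(x, 2L, function(col) diff(range(col)))) == 0) {
    warning("degenerate sample (all points identical); smallest bandwidth returned")
    return(min(candidates))
  }
  n_test <- max(1L, round(n / 10))
  ll <- matrix(NA_real_, folds, length(candidates))
  sx <- rowSums(x^2)
  for (f in seq_len(folds)) {
    test <- sample.int(n, n_test)
    d2 <- outer(sx[test], sx[-test], "+") -
      2 * tcrossprod(x[test, , drop = FALSE], x[-test, , drop = FALSE])
    d2[d2 < 0] <- 0
    n_train <- n - n_test
    for (ci in seq_along(candidates)) {
      h2 <- candidates[ci]^2
      ll[f, ci] <- mean(row_logsumexp(-d2 / (2 * h2))) - log(n_train) -
        ncol(x) / 2 * log(2 * pi * h2)
    }
  }
  candidates[which.max(colMeans(ll))]
}
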