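## Video preprocessing: background model, segmentation, cropping, tracking.

#' Background image by per-pixel 90th percentile
#'
#' @param frames list of equally sized matrices, or a 3-D array with frames
#'   along the third dimension; at least 10 frames recommended.
#' @param prob percentile level (default 0.9). Linear-interpolation
#'   percentile (R quantile type 7).
#' @return matrix of per-pixel percentile intensities.
#' @export
compute_background <- function(frames, prob = 0.9) {
  if (is.list(frames)) frames <- simplify2array(frames)
  stopifnot(length(dim(frames)) == 3L)
  if (dim(frames)[3L] < 10L)
    warning("fewer than 10 frames: background estimate will be unstable")
  apply(frames, c(1L, 2L), stats::quantile, probs = prob, names = FALSE)
}

gaussian_kernel_5x5 <- function(sigma = 1) {
  g <- stats::dnorm(-2:2, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

#' Preprocess a raw frame
#'
#' Subtracts the frame from the background (fish become bright on dark),
#' smooths with a 5 x 5 Gaussian filter (sigma = 1), thresholds at Otsu's
#' level times a scale factor, keeps connected components above a minimum
#' area, and crops a fixed-size window around each detection. Cropped
#' windows extending past the frame are padded with values sampled from the
#' 5-pixel border of the detection region, excluding border pixels brighter
#' than the border mean + 3 sd (so another larva in the border does not
#' contaminate the fill).
#'
#' @param frame raw image matrix (0..255).
#' @param background matrix from [compute_background()], same shape.
#' @param otsu_scale scale factor applied to the Otsu threshold.
#' @param min_area minimum component area, px.
#' @param size crop side, px (default 141).
#' @param sigma Gaussian filter standard deviation.
#' @return list of detections; each has \code{image} (size x size, 0..255),
#'   \code{origin} (full-frame px of crop pixel (0,0)), \code{bbox}
#'   (x0, x1, y0, y1 full-frame px), \code{mask} (binary matrix, crop),
#'   \code{centroid} (full-frame px). Empty list when nothing is detected.
#' @export
preprocess_frame <- function(frame, background, otsu_scale = 0.8,
                             min_area = 20L, size = 141L, sigma = 1) {
  stopifnot(all(dim(frame) == dim(background)))
  sub <- pmax(background - frame, 0)
  sm <- EBImage::filter2(sub / 255, gaussian_kernel_5x5(sigma)) * 255
  sm[sm < 0] <- 0
  if (max(sm) == 0) return(list())
  thr <- EBImage::otsu(EBImage::Image(sm / 255), range = c(0, 1)) *
    otsu_scale * 255
  bin <- sm > thr
  lab <- EBImage::bwlabel(EBImage::Image(bin))
  lab <- EBImage::imageData(lab)
  n_comp <- max(lab)
  if (n_comp == 0) return(list())
  out <- list()
  for (comp in seq_len(n_comp)) {
    idx <- which(lab == comp, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    xs <- idx[, 1L] - 1L; ys <- idx[, 2L] - 1L   # 0-based full-frame px
    w <- sm[idx]
    centroid <- c(sum(xs * w), sum(ys * w)) / sum(w)
    bbox <- c(min(xs), max(xs), min(ys), max(ys))
    origin <- round(centroid) - (size - 1) / 2
    crop <- matrix(0, size, size)
    fx <- (origin[1L]):(origin[1L] + size - 1L)
    fy <- (origin[2L]):(origin[2L] + size - 1L)
    okx <- fx >= 0 & fx < nrow(sm)
    oky <- fy >= 0 & fy < ncol(sm)
    crop[okx, oky] <- sm[fx[okx] + 1L, fy[oky] + 1L]
    if (!all(okx) || !all(oky)) {
      border <- border_fill_values(sm, bbox)
      n_fill <- sum(!okx) * size + sum(okx) * sum(!oky)
      if (length(border) > 0 && n_fill > 0) {
        fill <- sample(border, n_fill, replace = TRUE)
        m <- matrix(TRUE, size, size)
        m[okx, oky] <- FALSE
        crop[m] <- fill[seq_len(sum(m))]
      }
    }
    mask_crop <- matrix(FALSE, size, size)
    inx <- xs - origin[1L]; iny <- ys - origin[2L]
    keep <- inx >= 0 & inx < size & iny >= 0 & iny < size
    mask_crop[cbind(inx[keep] + 1L, iny[keep] + 1L)] <- TRUE
    out[[length(out) + 1L]] <- list(image = crop, origin = origin,
                                    bbox = bbox, mask = mask_crop,
                                    centroid = centroid)
  }
  out
}

## Pixel values of the 5-px border around a bbox, excluding bright outliers
## (> mean + 3 sd of the border values).
border_fill_values <- function(img, bbox, width = 5L) {
  x0 <- max(0L, bbox[1L] - width); x1 <- min(nrow(img) - 1L, bbox[2L] + width)
  y0 <- max(0L, bbox[3L] - width); y1 <- min(ncol(img) - 1L, bbox[4L] + width)
  block <- img[(x0:x1) + 1L, (y0:y1) + 1L]
  inner <- matrix(FALSE, nrow(block), ncol(block))
  ix0 <- bbox[1L] - x0; ix1 <- bbox[2L] - x0
  iy0 <- bbox[3L] - y0; iy1 <- bbox[4L] - y0
  inner[(ix0:ix1) + 1L, (iy0:iy1) + 1L] <- TRUE
  vals <- block[!inner]
  if (length(vals) == 0) return(numeric(0))
  vals[vals <= mean(vals) + 3 * stats::sd(vals)]
}

#' Track a larva across frames by 3-D nearest neighbour
#'
#' For each frame, matches per-camera centroids across views
#' ([match_larvae_across_views()]) to get candidate 3-D positions, then
#' associates detections frame-to-frame by nearest 3-D neighbour to the
#' previous tracked position.
#'
#' @param centroid_frames list (per frame) of lists of three n_i x 2 pixel
#'   matrices (per camera).
#' @param proj a \code{refractive_projection}.
#' @param eps cross-view match threshold, mm.
#' @param max_gap track is terminated after this many frames without a match.
#' @return data.frame with columns frame, x, y, z, matched (logical) and an
#'   attribute \code{status} ("complete" or "lost").
#' @export
track_larva <- function(centroid_frames, proj, eps = 1.0, max_gap = 5L) {
  n <- length(centroid_frames)
  out <- data.frame(frame = seq_len(n), x = NA_real_, y = NA_real_,
                    z = NA_real_, matched = FALSE)
  last <- NULL
  gap <- 0L
  status <- "complete"
  for (f in seq_len(n)) {
    m <- match_larvae_across_views(centroid_frames[[f]], proj, eps)
    if (nrow(m) == 0L) {
      gap <- gap + 1L
      if (!is.null(last) && gap > max_gap) { status <- "lost"; break }
      next
    }
    pos <- as.matrix(m[, c("x", "y", "z")])
    pick <- if (is.null(last)) which.min(m$delta)
      else which.min(colSums((t(pos) - last)^2))
    last <- pos[pick, ]
    out[f, c("x", "y", "z")] <- last
    out$matched[f] <- TRUE
    gap <- 0L
  }
  attr(out, "status") <- status
  out
}
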