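## Calibration and dot-observation file formats.

#' Write / read a calibration file
#'
#' JSON with the per-camera cubic projection coefficients, the coordinate
#' centring/scaling, the valid domain, and the fit residuals. Pixels are
#' 0-based with centres on integer coordinates, x right, y down (recorded in
#' the file as \code{pixel_convention}).
#'
#' @param proj a \code{refractive_projection}.
#' @param path file path.
#' @return \code{read_calibration} returns a \code{refractive_projection}.
#' @export
write_calibration <- function(proj, path) {
  jsonlite::write_json(list(
    pixel_convention = "0-based, integer pixel centres, x right, y down",
    n_cam = proj$n_cam,
    centre = proj$centre, scale = proj$scale, domain = proj$domain,
    rms_px = proj$rms_px,
    cams = lapply(proj$cams, function(cc)
      list(coef_u = as.numeric(cc$coef_u), coef_v = as.numeric(cc$coef_v),
           rms = as.numeric(cc$rms)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cams <- lapply(seq_len(j$n_cam), function(k) {
    cc <- if (is.data.frame(j$cams)) {
      list(coef_u = j$cams$coef_u[[k]], coef_v = j$cams$coef_v[[k]],
           rms = j$cams$rms[[k]])
    } else j$cams[[k]]
    list(coef_u = matrix(as.numeric(cc$coef_u), 10L, 1L),
         coef_v = matrix(as.numeric(cc$coef_v), 10L, 1L),
         rms = as.numeric(cc$rms))
  })
  structure(list(cams = cams, n_cam = j$n_cam,
                 centre = as.numeric(j$centre), scale = as.numeric(j$scale),
                 domain = matrix(as.numeric(unlist(j$domain)), 3L, 2L),
                 rms_px = as.numeric(j$rms_px)),
            class = "refractive_projection")
}

#' Write / read dot-grid observations
#'
#' CSV with columns dot_id, camera, medium (air / water), x_px, y_px.
#'
#' @param grid result of [simulate_dot_grid()] (or an equivalent list).
#' @param path file path.
#' @return \code{read_dot_csv} returns a list with \code{pixels_air} and
#'   \code{pixels_water} (lists of n x 2 matrices per camera).
#' @export
write_dot_csv <- function(grid, path) {
  rows <- list()
  n <- nrow(grid$dots)
  for (k in seq_along(grid$pixels_water)) {
    rows[[length(rows) + 1L]] <- data.frame(
      dot_id = seq_len(n), camera = k, medium = "water",
      x_px = grid$pixels_water[[k]][, 1L], y_px = grid$pixels_water[[k]][, 2L])
    rows[[length(rows) + 1L]] <- data.frame(
      dot_id = seq_len(n), camera = k, medium = "air",
      x_px = grid$pixels_air[[k]][, 1L], y_px = grid$pixels_air[[k]][, 2L])
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dot_csv
#' @export
read_dot_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("dot_id", "camera", "medium", "x_px", "y_px") %in%
                  names(d)))
  cams <- sort(unique(d$camera))
  ids <- sort(unique(d$dot_id))
  get <- function(medium) lapply(cams, function(k) {
    sub <- d[d$camera == k & d$medium == medium, ]
    sub <- sub[match(ids, sub$dot_id), ]
    cbind(sub$x_px, sub$y_px)
  })
  list(dot_id = ids, pixels_air = get("air"), pixels_water = get("water"))
}
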