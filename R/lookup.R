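## Lookup Table P: precomputed 2-D sprites used by the fast renderer during
## coarse optimization.
##
## Tail entries are indexed by segment number, projected orientation (5
## degree bins), projected segment length (binned), and the subpixel offset
## of the segment start (0.2 px bins in x and y). Anterior entries are
## orthographic voxel projections along the camera principal axis, indexed
## by the three binned head Euler angles (5 degree bins) and the projected
## scale (magnification bins). Entries are generated lazily and memoised, so
## only the part of the table an optimization actually visits is built.

#' Build a sprite lookup table for fast rendering
#'
#' @param fixed a \code{fish_body_params}.
#' @param length body length L the table is built for, mm.
#' @param orient_step orientation bin width, degrees (default 5).
#' @param offset_step subpixel offset bin width for tail entries, px
#'   (default 0.2).
#' @param len_step tail segment projected-length bin width, px.
#' @param mag_step relative magnification bin width for the anterior scale.
#' @param ant_pitch voxel pitch for anterior sprite generation, mm.
#' @return an object of class \code{lookup_table_p}.
#' @export
build_lookup_table_p <- function(fixed = fish_body_params(), length = 4.0,
                                 orient_step = 5, offset_step = 0.2,
                                 len_step = 0.25, mag_step = 0.02,
                                 ant_pitch = 0.04) {
  stopifnot(orient_step > 0, offset_step > 0, len_step > 0, mag_step > 0)
  structure(list(fixed = fixed, length = length,
                 orient_step = orient_step, offset_step = offset_step,
                 len_step = len_step, mag_step = mag_step,
                 ant_pitch = ant_pitch,
                 tail_cache = new.env(parent = emptyenv()),
                 ant_cache = new.env(parent = emptyenv())),
            class = "lookup_table_p")
}

#' @export
print.lookup_table_p <- function(x, ...) {
  cat(sprintf(
    "<lookup_table_p> L = %.2f mm; %g deg orientation bins, %g px offsets, %d tail / %d anterior entries cached\n",
    x$length, x$orient_step, x$offset_step,
    length(ls(x$tail_cache)), length(ls(x$ant_cache))))
  invisible(x)
}

## Quantize a value to a bin centre.
qbin <- function(x, step) round(x / step) * step

## Trim a sprite to the bounding box of its non-negligible pixels, keeping
## the anchor consistent. Cuts paste cost roughly threefold for thin
## diagonal capsules.
trim_sprite <- function(spr, centre, floor = 4e-3) {
  nz <- which(spr > floor, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(list(sprite = spr[1L, 1L, drop = FALSE],
                                  centre = centre))
  x0 <- min(nz[, 1L]); x1 <- max(nz[, 1L])
  y0 <- min(nz[, 2L]); y1 <- max(nz[, 2L])
  list(sprite = spr[x0:x1, y0:y1, drop = FALSE],
       centre = c(centre[1L] - (x0 - 1L), centre[2L] - (y0 - 1L)))
}

#' Tail-segment sprite for given (binned) projection parameters
#'
#' Renders (or retrieves) the sprite of tail segment \code{seg} (1..8) whose
#' projected start point sits at the sprite centre plus the subpixel offset,
#' with the given projected orientation and length. Adjacent orientation
#' entries differ by one orientation step; adjacent offset entries by one
#' subpixel step.
#'
#' @param table a \code{lookup_table_p}.
#' @param seg tail segment index, 1..8 (segment 1 starts at backbone point 2).
#' @param angle_deg projected orientation, degrees (quantized internally).
#' @param len_px projected segment length, px (quantized internally).
#' @param off_x,off_y subpixel offset of the start point, px in [0, 1)
#'   (quantized internally).
#' @return list with \code{sprite} (matrix), \code{centre} (0-based index of
#'   the anchor pixel in the sprite), and the quantized parameters.
#' @export
tail_sprite <- function(table, seg, angle_deg, len_px, off_x = 0, off_y = 0) {
  stopifnot(seg >= 1L, seg <= 8L)
  ai <- as.integer(round((angle_deg %% 360) / table$orient_step)) %%
    as.integer(round(360 / table$orient_step))
  li <- max(1L, as.integer(round(len_px / table$len_step)))
  oxi <- as.integer(round(off_x / table$offset_step))
  oyi <- as.integer(round(off_y / table$offset_step))
  tail_sprite_binned(table, seg, ai, li, oxi, oyi)
}

## Integer-bin fast path used by the renderer hot loop.
tail_sprite_binned <- function(table, seg, ai, li, oxi, oyi) {
  key <- as.character(oyi + 8L * (oxi + 8L * (li + 512L * (ai + 128L * seg))))
  hit <- table$tail_cache[[key]]
  if (!is.null(hit)) return(hit)
  a <- ai * table$orient_step
  l <- li * table$len_step
  ox <- oxi * table$offset_step
  oy <- oyi * table$offset_step
  prof <- tail_profile(table$fixed, table$length)
  mag <- l / (table$length / 9)               # px per mm implied by length
  sig_a <- prof$sigma_mm[seg] * mag
  sig_b <- prof$sigma_mm[seg + 1L] * mag
  half <- ceiling(l + 3 * max(sig_a, sig_b) + 2)
  n <- 2L * half + 1L
  p_a <- c(half + ox, half + oy)
  dir <- c(cos(a * pi / 180), sin(a * pi / 180))
  p_b <- p_a + l * dir
  spr <- draw_capsule(matrix(0, n, n), p_a, p_b, sig_a, sig_b,
                      prof$intensity[seg], prof$intensity[seg + 1L])
  tr <- trim_sprite(spr, c(half, half))
  out <- list(sprite = tr$sprite, centre = tr$centre,
              angle = a, len = l, off = c(ox, oy))
  table$tail_cache[[key]] <- out
  out
}

#' Anterior sprite for a (binned) head orientation and scale
#'
#' Orthographic projection of the anterior voxel cloud along the principal
#' axis of camera \code{k}, anchored at the head point, with the head Euler
#' angles quantized to the orientation bins and the magnification to the
#' scale bins. Normalized to peak 1.
#'
#' @param table a \code{lookup_table_p}.
#' @param k camera index (selects the projection axes).
#' @param theta0,phi0,gamma0 head Euler angles, rad.
#' @param mag magnification at the fish, px per mm.
#' @return list with \code{sprite}, \code{centre} (anchor pixel of the head
#'   point), and the quantized parameters.
#' @export
anterior_sprite <- function(table, k, theta0, phi0, gamma0, mag) {
  step <- table$orient_step * pi / 180
  thi <- as.integer(round(theta0 / step))
  phi_ <- as.integer(round(phi0 / step))
  gai <- as.integer(round(gamma0 / step))
  mgi <- as.integer(round(log(mag) / log1p(table$mag_step)))
  key <- sprintf("%d|%d|%d|%d|%d", k, thi, phi_, gai, mgi)
  hit <- table$ant_cache[[key]]
  if (!is.null(hit)) return(hit)
  th <- thi * step; ph <- phi_ * step; ga <- gai * step
  mg <- (1 + table$mag_step)^mgi
  cloud <- anterior_cloud(table$fixed, table$length, table$ant_pitch)
  R <- rot_z(th) %*% rot_y(-ph) %*% rot_x(ga)
  lab <- cloud$pts %*% t(R)
  ax <- CAMERA_AXES[[k]]
  u <- ax$u[2L] * lab[, ax$u[1L]] * mg
  v <- ax$v[2L] * lab[, ax$v[1L]] * mg
  half <- ceiling(max(abs(c(u, v)))) + 1L
  n <- 2L * half + 1L
  ix <- round(u) + half
  iy <- round(v) + half
  idx <- ix * n + iy
  acc <- rowsum(cloud$val, idx)
  spr <- matrix(0, n, n)
  pos <- as.integer(rownames(acc))
  spr[cbind(pos %/% n + 1L, pos %% n + 1L)] <- acc[, 1L]
  spr <- spr / max(spr)
  tr <- trim_sprite(spr, c(half, half))
  out <- list(sprite = tr$sprite, centre = tr$centre,
              angles = c(th, ph, ga), mag = mg)
  table$ant_cache[[key]] <- out
  out
}

## Paste a sprite into img (0-based anchor position `at`) by pixelwise max.
## Convenience wrapper; the renderer hot path inlines this to avoid matrix
## copies (see render_fast_view).
paste_sprite_max <- function(img, sprite, centre, at) {
  n <- nrow(img); m <- ncol(img)
  bx <- round(at[1L]) - centre[1L]           # 0-based position of sprite[1,1]
  by <- round(at[2L]) - centre[2L]
  sx <- nrow(sprite); sy <- ncol(sprite)
  x0 <- max(0L, bx); x1 <- min(n - 1L, bx + sx - 1L)
  y0 <- max(0L, by); y1 <- min(m - 1L, by + sy - 1L)
  if (x0 > x1 || y0 > y1) return(img)
  img[(x0:x1) + 1L, (y0:y1) + 1L] <-
    pmax(img[(x0:x1) + 1L, (y0:y1) + 1L],
         sprite[(x0:x1) - bx + 1L, (y0:y1) - by + 1L])
  img
}

## Render one complete fast-mode view into a fresh (nx x ny) buffer from the
## lookup table: anterior sprite anchored at the projected head point, then
## the 8 tail-segment sprites. The buffer is owned locally so all pastes are
## in-place subassignments.
render_fast_view <- function(table, k, pose, kc, mag, nx, ny) {
  img <- matrix(0, nx, ny)
  sp <- anterior_sprite(table, k, pose$theta0, pose$phi0, pose$gamma0, mag)
  ## bilinear subpixel shift of the anterior sprite: the head anchor moves
  ## continuously, so position localization is not quantized to whole pixels
  hx <- kc[1L, 1L]; hy <- kc[1L, 2L]
  fx <- hx - floor(hx); fy <- hy - floor(hy)
  s <- sp$sprite
  sn <- nrow(s); sm <- ncol(s)
  sh <- matrix(0, sn + 1L, sm + 1L)
  sh[1:sn, 1:sm] <- (1 - fx) * (1 - fy) * s
  sh[2:(sn + 1L), 1:sm] <- sh[2:(sn + 1L), 1:sm] + fx * (1 - fy) * s
  sh[1:sn, 2:(sm + 1L)] <- sh[1:sn, 2:(sm + 1L)] + (1 - fx) * fy * s
  sh[2:(sn + 1L), 2:(sm + 1L)] <- sh[2:(sn + 1L), 2:(sm + 1L)] + fx * fy * s
  bx <- as.integer(floor(hx)) - sp$centre[1L]
  by <- as.integer(floor(hy)) - sp$centre[2L]
  x0 <- max(0L, bx); x1 <- min(nx - 1L, bx + sn)
  y0 <- max(0L, by); y1 <- min(ny - 1L, by + sm)
  if (x0 <= x1 && y0 <= y1)
    img[(x0:x1) + 1L, (y0:y1) + 1L] <-
      pmax(img[(x0:x1) + 1L, (y0:y1) + 1L],
           sh[(x0:x1) - bx + 1L, (y0:y1) - by + 1L])
  tx <- kc[2:10, 1L]; ty <- kc[2:10, 2L]
  dx <- tx[2:9] - tx[1:8]; dy <- ty[2:9] - ty[1:8]
  len <- sqrt(dx * dx + dy * dy)
  ang <- atan2(dy, dx) * (180 / pi)
  n_ang <- as.integer(round(360 / table$orient_step))
  ai <- as.integer(round((ang %% 360) / table$orient_step)) %% n_ang
  li <- pmax(1L, as.integer(round(len / table$len_step)))
  fx <- floor(tx[1:8]); fy <- floor(ty[1:8])
  oxi <- as.integer(round((tx[1:8] - fx) / table$offset_step))
  oyi <- as.integer(round((ty[1:8] - fy) / table$offset_step))
  for (seg in 1:8) {
    sp <- tail_sprite_binned(table, seg, ai[seg], li[seg], oxi[seg],
                             oyi[seg])
    bx <- fx[seg] - sp$centre[1L]
    by <- fy[seg] - sp$centre[2L]
    x0 <- max(0L, bx); x1 <- min(nx - 1L, bx + nrow(sp$sprite) - 1L)
    y0 <- max(0L, by); y1 <- min(ny - 1L, by + ncol(sp$sprite) - 1L)
    if (x0 > x1 || y0 > y1) next
    img[(x0:x1) + 1L, (y0:y1) + 1L] <-
      pmax(img[(x0:x1) + 1L, (y0:y1) + 1L],
           sp$sprite[(x0:x1) - bx + 1L, (y0:y1) - by + 1L])
  }
  img
}
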