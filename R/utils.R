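# Internal geometry and raster helpers shared across modules.
#
# Coordinate conventions (documented in every output header):
#  - pixel indices are 0-based and pixel-centered: the pixel stored at
#    matrix position [r, c] (1-based in R) has its center at
#    x = (c - 0.5) * pixel_size_um, y = (r - 0.5) * pixel_size_um;
#  - x runs along matrix columns and is the mediolateral (ML) axis by
#    default, y runs along rows (anterior-posterior);
#  - regions are half-open boxes [origin, origin + size).

#' Region specification
#'
#' A rectangular analysis region, e.g. the 50 x 50 um boxes used for gap
#' counts or the 100 x 100 um boxes used for apical-area statistics. A point
#' belongs to the region iff it lies in the half-open box
#' `[origin, origin + size)`.
#'
#' @param origin_um numeric length-2, lower-left corner (x, y) in um.
#' @param size_um numeric length-1 or 2, box size in um.
#' @return an object of class `region_spec`.
#' @export
region_spec <- function(origin_um = c(0, 0), size_um) {
  if (length(size_um) == 1L) size_um <- rep(size_um, 2L)
  stopifnot(length(origin_um) == 2L, length(size_um) == 2L, all(size_um > 0))
  structure(list(origin_um = as.numeric(origin_um),
                 size_um = as.numeric(size_um)),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region %g x %g um at (%g, %g), half-open>\n",
              x$size_um[1], x$size_um[2], x$origin_um[1], x$origin_um[2]))
  invisible(x)
}

# half-open inclusion test for points (vectorised)
in_region <- function(x, y, region) {
  if (is.null(region)) return(rep(TRUE, length(x)))
  o <- region$origin_um; s <- region$size_um
  x >= o[1] & x < o[1] + s[1] & y >= o[2] & y < o[2] + s[2]
}

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# polygon area (shoelace), vertices as n x 2 matrix, not closed
polygon_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3L) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

polygon_centroid <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1L)
  cr <- p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((p[, 1] + p[i2, 1]) * cr), sum((p[, 2] + p[i2, 2]) * cr)) / (6 * a)
}

# clip polygon by half-plane {q : (q - pt) . n <= 0} (Sutherland-Hodgman)
clip_halfplane <- function(poly, pt, n) {
  if (is.null(nrow(poly)) || nrow(poly) < 3L) return(poly[0, , drop = FALSE])
  d <- (poly[, 1] - pt[1]) * n[1] + (poly[, 2] - pt[2]) * n[2]
  np <- nrow(poly)
  inside <- d <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(NA_real_, 2L * np, 2L)
  k <- 0L
  for (i in seq_len(np)) {
    j <- if (i == np) 1L else i + 1L
    if (inside[i]) { k <- k + 1L; out[k, ] <- poly[i, ] }
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      k <- k + 1L
      out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

# even-odd point-in-polygon, vectorised over points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# distance from points to a segment p-q, vectorised over points
dist_to_segment <- function(px, py, p, q) {
  vx <- q[1] - p[1]; vy <- q[2] - p[2]
  L2 <- vx * vx + vy * vy
  if (L2 < 1e-18) return(sqrt((px - p[1])^2 + (py - p[2])^2))
  t <- pmin(1, pmax(0, ((px - p[1]) * vx + (py - p[2]) * vy) / L2))
  sqrt((px - p[1] - t * vx)^2 + (py - p[2] - t * vy)^2)
}

# linear (matrix) indices of pixels whose center is within `halfwidth_um`
# of segment p-q; dims = c(nr, nc)
pixels_near_segment <- function(p, q, halfwidth_um, pixel_size_um, dims) {
  nr <- dims[1]; nc <- dims[2]
  xlo <- min(p[1], q[1]) - halfwidth_um; xhi <- max(p[1], q[1]) + halfwidth_um
  ylo <- min(p[2], q[2]) - halfwidth_um; yhi <- max(p[2], q[2]) + halfwidth_um
  c0 <- max(1L, floor(xlo / pixel_size_um + 0.5))
  c1 <- min(nc, ceiling(xhi / pixel_size_um + 0.5))
  r0 <- max(1L, floor(ylo / pixel_size_um + 0.5))
  r1 <- min(nr, ceiling(yhi / pixel_size_um + 0.5))
  if (c1 < c0 || r1 < r0) return(integer(0))
  cs <- c0:c1; rs <- r0:r1
  px <- (rep(cs, each = length(rs)) - 0.5) * pixel_size_um
  py <- (rep(rs, times = length(cs)) - 0.5) * pixel_size_um
  d <- dist_to_segment(px, py, p, q)
  keep <- d <= halfwidth_um
  idx <- rep(rs, times = length(cs)) + (rep(cs, each = length(rs)) - 1L) * nr
  idx[keep]
}

# linear indices of pixels whose center is within radius of (x, y)
pixels_in_disk <- function(x, y, radius_um, pixel_size_um, dims) {
  nr <- dims[1]; nc <- dims[2]
  c0 <- max(1L, floor((x - radius_um) / pixel_size_um + 0.5))
  c1 <- min(nc, ceiling((x + radius_um) / pixel_size_um + 0.5))
  r0 <- max(1L, floor((y - radius_um) / pixel_size_um + 0.5))
  r1 <- min(nr, ceiling((y + radius_um) / pixel_size_um + 0.5))
  if (c1 < c0 || r1 < r0) return(integer(0))
  cs <- c0:c1; rs <- r0:r1
  px <- (rep(cs, each = length(rs)) - 0.5) * pixel_size_um
  py <- (rep(rs, times = length(cs)) - 0.5) * pixel_size_um
  keep <- (px - x)^2 + (py - y)^2 <= radius_um^2
  idx <- rep(rs, times = length(cs)) + (rep(cs, each = length(rs)) - 1L) * nr
  idx[keep]
}

# bilinear sample of an image at micrometer coordinates (vectorised)
bilinear_sample <- function(image, x_um, y_um, pixel_size_um) {
  nr <- nrow(image); nc <- ncol(image)
  cc <- x_um / pixel_size_um + 0.5  # fractional 1-based column
  rr <- y_um / pixel_size_um + 0.5
  cc <- pmin(pmax(cc, 1), nc)
  rr <- pmin(pmax(rr, 1), nr)
  c0 <- pmin(floor(cc), nc - 1L); r0 <- pmin(floor(rr), nr - 1L)
  fc <- cc - c0; fr <- rr - r0
  i00 <- r0 + (c0 - 1) * nr
  image[i00] * (1 - fr) * (1 - fc) + image[i00 + 1] * fr * (1 - fc) +
    image[i00 + nr] * (1 - fr) * fc + image[i00 + nr + 1] * fr * fc
}

#' Fold an orientation into [0, 90] degrees relative to the ML axis
#'
#' The orientation of a chord (dx, dy) is measured relative to the
#' mediolateral axis (`ml_axis_deg`, default 0 = the x axis) and folded so
#' that an edge and its reverse share the same angle. 0 means mediolateral,
#' 90 means anterior-posterior.
#'
#' @param dx,dy chord components (um); vectorised.
#' @param ml_axis_deg orientation of the ML axis in degrees.
#' @return angles in degrees in [0, 90]; `NA` for zero-length chords.
#' @export
fold_angle <- function(dx, dy, ml_axis_deg = 0) {
  zero <- (dx == 0 & dy == 0)
  a <- atan2(dy, dx) * 180 / pi - ml_axis_deg
  a <- a %% 180
  a <- ifelse(a > 90, 180 - a, a)
  a[zero] <- NA_real_
  a
}

# truncated normal sampler (rejection; mean/sd/min in the same units)
rtruncnorm_min <- function(n, mean, sd, min) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < min)
  guard <- 0L
  while (length(bad) > 0L && guard < 100L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < min)
    guard <- guard + 1L
  }
  out[out < min] <- min
  out
}

# Rolling polynomial hash of a character string, as hex; used for
# provenance stamps on outputs (no cryptographic intent).
content_hash <- function(s) {
  bytes <- utf8ToInt(paste(s, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
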