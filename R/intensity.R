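# Intensity statistics on junction graphs: background estimation, planar
# polarity, tricellular-junction enrichment, line profiles, mitotic index,
# and the region -> embryo -> cohort aggregation used for all figures.

#' Estimate cytoplasmic background from interior ROIs
#'
#' Places 20-40 circular ROIs at cell-interior points (one per sampled cell,
#' at the cell centroid, falling back to the pixel farthest from the cell
#' boundary when the centroid disk is not fully interior) and returns the
#' average of the per-ROI mean pixel intensities.
#'
#' @param image intensity matrix (a.u.).
#' @param graph a `junction_graph` for the same field.
#' @param roi_radius_um ROI disk radius.
#' @param n_rois requested number of ROIs (clamped to [20, 40]; fewer
#'   eligible cells triggers a warning and is recorded).
#' @param seed seed for the cell sample.
#' @return object of class `background_estimate`: list with `value`,
#'   `n_rois`, `roi_radius_um`.
#' @export
estimate_background <- function(image, graph, roi_radius_um = 0.5,
                                n_rois = 30, seed = 1L) {
  n_rois <- max(20L, min(40L, as.integer(n_rois)))
  px <- graph$pixel_size_um
  dims <- dim(image)
  lab <- graph$label_image
  cells <- graph$cells[!graph$cells$border, , drop = FALSE]
  set.seed(seed)
  cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
  means <- numeric(0)
  for (i in seq_len(nrow(cells))) {
    if (length(means) >= n_rois) break
    ctr <- c(cells$x[i], cells$y[i])
    idx <- pixels_in_disk(ctr[1], ctr[2], roi_radius_um, px, dims)
    ok <- length(idx) > 0L &&
      (is.null(lab) || all(lab[idx] == cells$label[i]))
    if (!ok && !is.null(lab)) {
      # fall back to the cell pixel farthest from non-cell pixels
      pidx <- which(lab == cells$label[i])
      if (length(pidx) == 0L) next
      rr <- (pidx - 1L) %% dims[1] + 1L
      cc <- (pidx - 1L) %/% dims[1] + 1L
      nb_other <- matrix(FALSE, dims[1], dims[2])
      for (sh in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)))
        nb_other <- nb_other | shift_mat(lab, sh[1], sh[2], 0L) != lab
      bidx <- pidx[nb_other[pidx]]
      if (length(bidx) == 0L) bidx <- pidx
      br <- (bidx - 1L) %% dims[1] + 1L
      bc <- (bidx - 1L) %/% dims[1] + 1L
      dmin <- apply(outer(rr, br, "-")^2 + outer(cc, bc, "-")^2, 1, min)
      j <- which.max(dmin)
      ctr <- c((cc[j] - 0.5) * px, (rr[j] - 0.5) * px)
      idx <- pixels_in_disk(ctr[1], ctr[2], roi_radius_um, px, dims)
      ok <- length(idx) > 0L && all(lab[idx] == cells$label[i])
    }
    if (ok) means <- c(means, mean(image[idx]))
  }
  if (length(means) < 20L)
    warning(sprintf("only %d eligible background ROIs (20 requested)",
                    length(means)))
  structure(list(value = mean(means), n_rois = length(means),
                 roi_radius_um = roi_radius_um),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("<background %.3f a.u. from %d ROIs (r = %g um)>\n",
              x$value, x$n_rois, x$roi_radius_um))
  invisible(x)
}

# pixel indices of the measurement strip of an edge polyline, optionally
# excluding pixels near the chord endpoints (where tricellular enrichment
# would contaminate the bicellular mean)
edge_strip_pixels <- function(polyline, pixel_size_um, dims,
                              line_width_um = 0.5, exclude_endpoints_um = 0) {
  np <- nrow(polyline)
  step <- max(1L, floor(np / 12))
  keep <- unique(c(seq(1L, np, by = step), np))
  pts <- polyline[keep, , drop = FALSE]
  idx <- integer(0)
  for (i in seq_len(nrow(pts) - 1L)) {
    idx <- c(idx, pixels_near_segment(pts[i, ], pts[i + 1L, ],
                                      line_width_um / 2, pixel_size_um, dims))
  }
  if (np == 1L) idx <- pixels_in_disk(pts[1, 1], pts[1, 2], line_width_um / 2,
                                      pixel_size_um, dims)
  idx <- unique(idx)
  if (exclude_endpoints_um > 0 && length(idx)) {
    nr <- dims[1]
    pxx <- (((idx - 1L) %/% nr)) * pixel_size_um + 0.5 * pixel_size_um
    pyy <- (((idx - 1L) %% nr)) * pixel_size_um + 0.5 * pixel_size_um
    ends <- polyline[c(1L, np), , drop = FALSE]
    d1 <- sqrt((pxx - ends[1, 1])^2 + (pyy - ends[1, 2])^2)
    d2 <- sqrt((pxx - ends[2, 1])^2 + (pyy - ends[2, 2])^2)
    idx <- idx[d1 > exclude_endpoints_um & d2 > exclude_endpoints_um]
  }
  idx
}

#' Mean junctional intensity along an edge
#'
#' Mean of the pixels within `line_width_um / 2` of the edge polyline,
#' optionally excluding pixels within `exclude_endpoints_um` of the chord
#' endpoints. Invariant to the order of the polyline points.
#'
#' @param image intensity matrix.
#' @param polyline n x 2 matrix of um coordinates (an entry of
#'   `graph$polylines`).
#' @param pixel_size_um um/px.
#' @param line_width_um full strip width.
#' @param exclude_endpoints_um end-exclusion zone.
#' @return mean intensity (a.u.); errors if the strip has no pixels inside
#'   the image.
#' @export
edge_mean_intensity <- function(image, polyline, pixel_size_um,
                                line_width_um = 0.5,
                                exclude_endpoints_um = 0) {
  idx <- edge_strip_pixels(polyline, pixel_size_um, dim(image),
                           line_width_um, exclude_endpoints_um)
  if (length(idx) == 0L) stop("edge lies outside the image (empty strip)")
  mean(image[idx])
}

#' Planar polarity of junctional intensity
#'
#' Mean background-subtracted intensity of mediolateral edges (chord at
#' 0-15 degrees to the ML axis) divided by that of anterior-posterior edges
#' (75-90 degrees); edges in between are excluded. Per-edge means are
#' averaged within each bin before the ratio. Edge end zones are excluded
#' from the per-edge means so tricellular enrichment does not leak into the
#' bicellular signal.
#'
#' @param image intensity matrix.
#' @param graph a `junction_graph`.
#' @param background scalar background (a.u.) or a `background_estimate`.
#' @param region optional [region_spec()]; edges are selected by chord
#'   midpoint.
#' @param line_width_um,exclude_um per-edge measurement strip parameters.
#' @return object of class `polarity_result`: `ml_mean`, `ap_mean`
#'   (background-subtracted), `ratio`, `n_ml`, `n_ap`.
#' @export
planar_polarity <- function(image, graph, background, region = NULL,
                            line_width_um = 0.5, exclude_um = 1.0) {
  bg <- if (inherits(background, "background_estimate")) background$value else background
  ed <- graph$edges
  mid <- t(vapply(seq_len(nrow(ed)), function(i) {
    pl <- graph$polylines[[i]]
    (pl[1, ] + pl[nrow(pl), ]) / 2
  }, numeric(2)))
  sel <- in_region(mid[, 1], mid[, 2], region) & !is.na(ed$angle_deg) &
    ed$length_um > 2 * exclude_um + 2 * graph$pixel_size_um
  ml_idx <- which(sel & ed$angle_deg <= 15)
  ap_idx <- which(sel & ed$angle_deg >= 75)
  if (length(ml_idx) == 0L || length(ap_idx) == 0L)
    stop("planar polarity undefined: empty ML or AP bin in this region")
  emean <- function(i) edge_mean_intensity(image, graph$polylines[[i]],
                                           graph$pixel_size_um,
                                           line_width_um, exclude_um)
  ml <- mean(vapply(ml_idx, emean, numeric(1))) - bg
  ap <- mean(vapply(ap_idx, emean, numeric(1))) - bg
  structure(list(ml_mean = ml, ap_mean = ap, ratio = ml / ap,
                 n_ml = length(ml_idx), n_ap = length(ap_idx)),
            class = "polarity_result")
}

#' @export
print.polarity_result <- function(x, ...) {
  cat(sprintf("<planar polarity: ML/AP = %.3f (ML %.2f over %d edges, AP %.2f over %d)>\n",
              x$ratio, x$ml_mean, x$n_ml, x$ap_mean, x$n_ap))
  invisible(x)
}

#' Tricellular junction enrichment ratio
#'
#' Mean intensity of a disk centered on a tricellular vertex divided by the
#' average of the mean intensities of its three incident edges, both after
#' background subtraction. Edge means exclude `exclude_um` around each
#' endpoint so the TCJ signal itself does not contaminate them.
#'
#' @param image intensity matrix.
#' @param graph a `junction_graph`.
#' @param vertex_id id in `graph$vertices`; must have order 3.
#' @param background scalar or `background_estimate`.
#' @param disk_radius_um TCJ disk radius.
#' @param exclude_um,line_width_um edge measurement parameters.
#' @return object of class `tcj_measurement`: `vertex_id`, `tcj_mean`,
#'   `edge_means` (length 3), `ratio`.
#' @export
tcj_ratio <- function(image, graph, vertex_id, background,
                      disk_radius_um = 0.35, exclude_um = 1.0,
                      line_width_um = 0.5) {
  bg <- if (inherits(background, "background_estimate")) background$value else background
  v <- graph$vertices[match(vertex_id, graph$vertices$id), ]
  if (is.na(v$id[1])) stop("unknown vertex id")
  if (v$order != 3L)
    stop(sprintf("vertex %d has order %d; the TCJ ratio is defined for order 3",
                 vertex_id, v$order))
  inc <- which((!is.na(graph$edges$v1) & graph$edges$v1 == vertex_id) |
               (!is.na(graph$edges$v2) & graph$edges$v2 == vertex_id))
  if (length(inc) < 3L)
    stop(sprintf("vertex %d has %d resolvable incident edges (3 required)",
                 vertex_id, length(inc)))
  inc <- inc[order(-graph$edges$length_um[inc])][1:3]
  idx <- pixels_in_disk(v$x, v$y, disk_radius_um, graph$pixel_size_um,
                        dim(image))
  tcj_mean <- mean(image[idx])
  edge_means <- vapply(inc, function(i)
    edge_mean_intensity(image, graph$polylines[[i]], graph$pixel_size_um,
                        line_width_um, exclude_um), numeric(1))
  structure(list(vertex_id = vertex_id, tcj_mean = tcj_mean,
                 edge_means = edge_means,
                 ratio = (tcj_mean - bg) / mean(edge_means - bg)),
            class = "tcj_measurement")
}

#' @export
print.tcj_measurement <- function(x, ...) {
  cat(sprintf("<TCJ vertex %d: ratio %.3f (disk %.2f, edges %s)>\n",
              x$vertex_id, x$ratio, x$tcj_mean,
              paste(sprintf("%.2f", x$edge_means), collapse = "/")))
  invisible(x)
}

#' Normalized intensity profile along a line
#'
#' Samples the image by bilinear interpolation along a line of given length
#' centered on `anchor_um`, subtracts the background, and normalizes to the
#' maximum (the usual convention for junction cross-section profiles). If
#' the whole line is at or below background the profile is returned
#' unnormalized and flagged.
#'
#' @param image intensity matrix.
#' @param anchor_um center of the line, um.
#' @param direction_deg line direction.
#' @param length_um line length (3 um in the figures).
#' @param n_samples number of samples.
#' @param background scalar or `background_estimate`.
#' @param pixel_size_um um/px.
#' @return data frame `position_um`, `intensity`, with attribute
#'   `normalized` (logical).
#' @export
line_profile <- function(image, anchor_um, direction_deg, length_um = 3,
                         n_samples = 31L, background = 0, pixel_size_um) {
  bg <- if (inherits(background, "background_estimate")) background$value else background
  s <- seq(-length_um / 2, length_um / 2, length.out = n_samples)
  dx <- cos(direction_deg * pi / 180); dy <- sin(direction_deg * pi / 180)
  x <- anchor_um[1] + s * dx; y <- anchor_um[2] + s * dy
  nr <- nrow(image); nc <- ncol(image)
  if (any(x < 0 | y < 0 | x > nc * pixel_size_um | y > nr * pixel_size_um))
    stop("profile line extends outside the image")
  val <- bilinear_sample(image, x, y, pixel_size_um) - bg
  m <- max(val)
  # an all-background line has no peak to normalize to (numerical noise
  # from interpolation does not count)
  normalized <- m > 1e-8 * max(1, abs(bg))
  if (normalized) val <- val / m
  out <- data.frame(position_um = s, intensity = val)
  attr(out, "normalized") <- normalized
  out
}

#' Mitotic index in a region
#'
#' Fraction of cells in a region whose nucleus is marked mitotic
#' (phospho-histone H3-positive centroids are an input list); the cell count
#' comes from the graph.
#'
#' @param ph3_centroids n x 2 matrix of marker centroids (um); may be empty.
#' @param graph a `junction_graph`.
#' @param region a [region_spec()] or `NULL`.
#' @return fraction in [0, 1].
#' @export
mitotic_index <- function(ph3_centroids, graph, region = NULL) {
  cells <- graph$cells
  n_cells <- sum(in_region(cells$x, cells$y, region))
  if (n_cells == 0L) stop("no cells in region: mitotic index undefined")
  if (is.null(ph3_centroids) || NROW(ph3_centroids) == 0L) return(0)
  n_pos <- sum(in_region(ph3_centroids[, 1], ph3_centroids[, 2], region))
  min(1, n_pos / n_cells)
}

#' Two-level cohort aggregation
#'
#' Region-level values are first averaged within each embryo so that every
#' embryo contributes a single value, then summarized across embryos with
#' the selected dispersion (SEM or SD).
#'
#' @param values numeric vector of region-level values.
#' @param embryo grouping vector (one entry per value).
#' @param dispersion `"sem"` or `"sd"`.
#' @return list `per_embryo_means`, `cohort_mean`, `dispersion_value`,
#'   `dispersion`, `n_embryos`.
#' @export
cohort_summary <- function(values, embryo, dispersion = c("sem", "sd")) {
  dispersion <- match.arg(dispersion)
  keep <- !is.na(values)
  if (any(!keep)) warning("dropping NA region values")
  values <- values[keep]; embryo <- embryo[keep]
  if (length(values) == 0L) stop("no values to aggregate")
  per <- tapply(values, embryo, mean)
  empty <- is.na(per)
  if (any(empty)) {
    warning("excluding embryos with no values: ",
            paste(names(per)[empty], collapse = ", "))
    per <- per[!empty]
  }
  disp <- if (length(per) > 1L) {
    if (dispersion == "sem") stats::sd(per) / sqrt(length(per)) else stats::sd(per)
  } else NA_real_
  list(per_embryo_means = per, cohort_mean = mean(per),
       dispersion_value = disp, dispersion = dispersion,
       n_embryos = length(per))
}
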