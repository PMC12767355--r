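# Junction graph extraction from cell-label images, and geometric
# morphometrics (junction orders, edge angles, apical areas, spans).
#
# A `junction_graph` has three tables:
#   vertices: id, x, y (um), order (number of incident cells)
#   edges:    id, v1, v2 (vertex ids or NA at the field border), c1, c2
#             (cell labels), length_um, angle_deg in [0, 90] vs the ML axis
#   cells:    label, area_um2, x, y (centroid), border (touches field edge)
# plus per-edge polylines (um coordinates) used for intensity sampling.
# Graphs come either from a label image (extract_graph) or directly from
# generator ground truth (as_junction_graph).

new_junction_graph <- function(vertices, edges, cells, polylines,
                               pixel_size_um, dims, ml_axis_deg = 0,
                               field_um = NULL, source = "image",
                               label_image = NULL, filled = NULL) {
  structure(list(vertices = vertices, edges = edges, cells = cells,
                 polylines = polylines, pixel_size_um = pixel_size_um,
                 dims = dims, ml_axis_deg = ml_axis_deg,
                 field_um = field_um %||% (rev(dims) * pixel_size_um),
                 source = source, label_image = label_image, filled = filled),
            class = "junction_graph")
}

#' @export
print.junction_graph <- function(x, ...) {
  cat(sprintf("<junction_graph (%s): %d vertices, %d edges, %d cells, %g x %g um>\n",
              x$source, nrow(x$vertices), nrow(x$edges), nrow(x$cells),
              x$field_um[1], x$field_um[2]))
  invisible(x)
}

# Assign the 0-valued skeleton band to the nearest cell by exact Euclidean
# offset distance (offsets scanned in increasing-distance rings; ties within
# a ring resolved by a fixed direction order, so the result is deterministic
# and independent of the label values themselves).
fill_labels <- function(lab) {
  F <- lab
  if (!any(F == 0L)) return(F)
  rng <- 4L
  offs <- expand.grid(dr = -rng:rng, dc = -rng:rng)
  offs <- offs[!(offs$dr == 0L & offs$dc == 0L), ]
  offs <- offs[order(offs$dr^2 + offs$dc^2, atan2(offs$dr, offs$dc)), ]
  for (s in seq_len(nrow(offs))) {
    zero <- F == 0L
    if (!any(zero)) break
    nb <- shift_mat(lab, offs$dr[s], offs$dc[s], 0L)
    upd <- zero & nb > 0L
    F[upd] <- nb[upd]
  }
  # pathological leftovers (zero blobs wider than the scan ring)
  if (any(F == 0L)) {
    for (pass in 1:8) {
      zero <- F == 0L
      if (!any(zero)) break
      for (sh in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        nb <- shift_mat(F, sh[1], sh[2], 0L)
        upd <- (F == 0L) & nb > 0L
        F[upd] <- nb[upd]
      }
    }
  }
  F
}

#' Extract a junction graph from a cell-label image
#'
#' Vertices are found by a 2 x 2 pixel-corner scan on the (skeleton-filled)
#' label image: a corner where >= 3 distinct labels meet is a hit, and hits
#' are merged by single-linkage clustering within ~1.5 px. Edges are the
#' shared boundaries between label pairs, traced as ordered polylines.
#' Vertex order is the number of distinct cells seen within
#' `order_radius_um` of the vertex, united with the cells of all incident
#' edges (which makes the order robust to thin wedges at high-order
#' vertices).
#'
#' @param label_image integer matrix; labels >= 1 are cells, 0 is the
#'   junctional skeleton (a filled image without zeros also works).
#' @param pixel_size_um um per pixel.
#' @param ml_axis_deg orientation of the mediolateral axis (default 0 = x).
#' @param order_radius_um disk radius for the order count.
#' @param endpoint_assign_um max distance for attaching an edge endpoint to
#'   a vertex.
#' @param vertex_merge_um corner clusters closer than this are treated as one
#'   (higher-order) vertex; must stay below the smallest resolvable edge.
#' @return a `junction_graph`.
#' @export
extract_graph <- function(label_image, pixel_size_um, ml_axis_deg = 0,
                          order_radius_um = 0.6, endpoint_assign_um = 0.75,
                          vertex_merge_um = 0.85) {
  if (any(abs(label_image - round(label_image)) > 1e-9))
    stop("label image must be integer-valued")
  lab <- matrix(as.integer(round(label_image)),
                nrow(label_image), ncol(label_image))
  px <- pixel_size_um
  dims <- dim(lab)
  labs_present <- sort(unique(lab[lab > 0L]))
  if (length(labs_present) < 2L) {
    warning("fewer than 2 cells: returning an empty graph")
    return(new_junction_graph(
      data.frame(id = integer(0), x = numeric(0), y = numeric(0), order = integer(0)),
      data.frame(id = integer(0), v1 = integer(0), v2 = integer(0),
                 c1 = integer(0), c2 = integer(0),
                 length_um = numeric(0), angle_deg = numeric(0)),
      data.frame(label = integer(0), area_um2 = numeric(0),
                 x = numeric(0), y = numeric(0), border = logical(0)),
      list(), px, dims, ml_axis_deg, label_image = lab))
  }
  F <- fill_labels(lab)
  nr <- dims[1]; nc <- dims[2]

  # --- vertices: 2x2 corner scan -------------------------------------------
  a <- F[-nr, -nc]; b <- F[-1, -nc]; cc_ <- F[-nr, -1]; d <- F[-1, -1]
  ndist <- 1L + (b != a) + ((cc_ != a) & (cc_ != b)) +
    ((d != a) & (d != b) & (d != cc_))
  hit <- which(ndist >= 3L)
  hr <- (hit - 1L) %% (nr - 1L) + 1L
  hc <- (hit - 1L) %/% (nr - 1L) + 1L
  hx <- hc * px; hy <- hr * px  # corner coordinates in um
  if (length(hit) == 0L) {
    vertices <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                           order = integer(0))
  } else if (length(hit) == 1L) {
    vertices <- data.frame(id = 1L, x = hx, y = hy, order = 0L)
  } else {
    cl <- stats::cutree(stats::hclust(stats::dist(cbind(hx, hy) / px),
                                      method = "single"), h = 1.5)
    vx <- as.numeric(tapply(hx, cl, mean))
    vy <- as.numeric(tapply(hy, cl, mean))
    # second stage: a discrete >= 4-fold point can rasterise as separate
    # 3-fold corners connected by a spurious 1-2 px contact; re-merge
    # cluster centroids closer than `vertex_merge_um`
    if (length(vx) > 1L) {
      cl2 <- stats::cutree(stats::hclust(stats::dist(cbind(vx, vy)),
                                         method = "single"),
                           h = vertex_merge_um)
      n <- as.numeric(tapply(tabulate(cl), cl2, sum))
      vx <- as.numeric(tapply(vx * tabulate(cl), cl2, sum)) / n
      vy <- as.numeric(tapply(vy * tabulate(cl), cl2, sum)) / n
    }
    vertices <- data.frame(id = seq_along(vx), x = vx, y = vy, order = 0L)
  }

  # --- edges: label-pair boundaries ----------------------------------------
  Lh <- F[, -nc]; Rh <- F[, -1]
  ih <- which(Lh != Rh & Lh > 0L & Rh > 0L)
  rh <- (ih - 1L) %% nr + 1L; ch <- (ih - 1L) %/% nr + 1L
  Lv <- F[-nr, ]; Rv <- F[-1, ]
  iv <- which(Lv != Rv & Lv > 0L & Rv > 0L)
  rv <- (iv - 1L) %% (nr - 1L) + 1L; cv <- (iv - 1L) %/% (nr - 1L) + 1L
  bx <- c(ch * px, (cv - 0.5) * px)
  by <- c((rh - 0.5) * px, rv * px)
  l1 <- c(pmin(Lh[ih], Rh[ih]), pmin(Lv[iv], Rv[iv]))
  l2 <- c(pmax(Lh[ih], Rh[ih]), pmax(Lv[iv], Rv[iv]))
  key <- paste(l1, l2)
  groups <- split(seq_along(key), key)

  ne <- length(groups)
  e_c1 <- integer(ne); e_c2 <- integer(ne)
  e_x1 <- numeric(ne); e_y1 <- numeric(ne); e_x2 <- numeric(ne); e_y2 <- numeric(ne)
  polylines <- vector("list", ne)
  for (g in seq_len(ne)) {
    ii <- groups[[g]]
    e_c1[g] <- l1[ii[1]]; e_c2[g] <- l2[ii[1]]
    xs <- bx[ii]; ys <- by[ii]
    if (length(ii) > 1L) {
      vx <- stats::var(xs); vy <- stats::var(ys); vxy <- stats::cov(xs, ys)
      th <- 0.5 * atan2(2 * vxy, vx - vy)
      pr <- xs * cos(th) + ys * sin(th)
      o <- order(pr)
      xs <- xs[o]; ys <- ys[o]
    }
    polylines[[g]] <- cbind(x = xs, y = ys)
    e_x1[g] <- xs[1]; e_y1[g] <- ys[1]
    e_x2[g] <- xs[length(xs)]; e_y2[g] <- ys[length(ys)]
  }

  # attach edge endpoints to nearest vertices
  nearest_vertex <- function(x, y) {
    if (nrow(vertices) == 0L) return(NA_integer_)
    d2 <- (vertices$x - x)^2 + (vertices$y - y)^2
    i <- which.min(d2)
    if (d2[i] <= endpoint_assign_um^2) vertices$id[i] else NA_integer_
  }
  e_v1 <- mapply(nearest_vertex, e_x1, e_y1)
  e_v2 <- mapply(nearest_vertex, e_x2, e_y2)

  edges <- data.frame(id = seq_len(ne), v1 = e_v1, v2 = e_v2,
                      c1 = e_c1, c2 = e_c2,
                      length_um = sqrt((e_x2 - e_x1)^2 + (e_y2 - e_y1)^2),
                      angle_deg = fold_angle(e_x2 - e_x1, e_y2 - e_y1,
                                             ml_axis_deg))

  # --- vertex orders --------------------------------------------------------
  if (nrow(vertices) > 0L) {
    inc_labels <- vector("list", nrow(vertices))
    for (g in seq_len(ne)) {
      for (v in c(edges$v1[g], edges$v2[g])) {
        if (!is.na(v)) inc_labels[[v]] <- c(inc_labels[[v]], e_c1[g], e_c2[g])
      }
    }
    ord <- integer(nrow(vertices))
    for (i in seq_len(nrow(vertices))) {
      idx <- pixels_in_disk(vertices$x[i], vertices$y[i], order_radius_um, px, dims)
      ord[i] <- length(unique(c(F[idx][F[idx] > 0L], inc_labels[[i]])))
    }
    vertices$order <- ord
    keep <- vertices$order >= 3L
    idmap <- rep(NA_integer_, nrow(vertices))
    idmap[keep] <- seq_len(sum(keep))
    edges$v1 <- idmap[edges$v1]
    edges$v2 <- idmap[edges$v2]
    vertices <- vertices[keep, , drop = FALSE]
    vertices$id <- seq_len(nrow(vertices))
    rownames(vertices) <- NULL
  }

  # --- cells ----------------------------------------------------------------
  idx_all <- which(F > 0L)
  labv <- F[idx_all]
  rr <- (idx_all - 1L) %% nr + 1L
  ccc <- (idx_all - 1L) %/% nr + 1L
  cnt <- tapply(rep(1L, length(labv)), labv, sum)
  cx <- tapply((ccc - 0.5) * px, labv, mean)
  cy <- tapply((rr - 0.5) * px, labv, mean)
  rmin <- tapply(rr, labv, min); rmax <- tapply(rr, labv, max)
  cmin <- tapply(ccc, labv, min); cmax <- tapply(ccc, labv, max)
  cells <- data.frame(label = as.integer(names(cnt)),
                      area_um2 = as.numeric(cnt) * px^2,
                      x = as.numeric(cx), y = as.numeric(cy),
                      border = rmin == 1L | cmin == 1L | rmax == nr | cmax == nc)
  rownames(cells) <- NULL

  new_junction_graph(vertices, edges, cells, polylines, px, dims, ml_axis_deg,
                     label_image = lab, filled = F)
}

#' Ground-truth junction graph of a synthetic mesh
#'
#' Builds the same `junction_graph` structure directly from the exact
#' polygon geometry of a [make_mesh()] result (positions, orders, chords and
#' areas are exact, with no raster quantisation).
#'
#' @param mesh a `cell_mesh`.
#' @return a `junction_graph` with `source = "mesh"`.
#' @export
as_junction_graph <- function(mesh) {
  vt <- mesh_vertices(mesh)
  int <- vt[!vt$border & vt$order >= 3L, , drop = FALSE]
  idmap <- rep(NA_integer_, max(vt$id))
  idmap[int$id] <- seq_len(nrow(int))
  vertices <- data.frame(id = seq_len(nrow(int)), x = int$x, y = int$y,
                         order = int$order)
  ed <- mesh_edges(mesh)
  ed <- ed[!is.na(ed$c2), , drop = FALSE]
  edges <- data.frame(id = seq_len(nrow(ed)),
                      v1 = idmap[ed$v1], v2 = idmap[ed$v2],
                      c1 = ed$c1, c2 = ed$c2,
                      length_um = ed$length_um, angle_deg = ed$angle_deg)
  polylines <- lapply(seq_len(nrow(ed)), function(i)
    cbind(x = c(ed$x1[i], ed$x2[i]), y = c(ed$y1[i], ed$y2[i])))
  border_v <- vertex_on_border(mesh$coords, mesh$field_um)
  cells <- data.frame(
    label = mesh$labels,
    area_um2 = vapply(mesh$polys, function(v)
      polygon_area(mesh$coords[v, , drop = FALSE]), numeric(1)),
    t(vapply(mesh$polys, function(v)
      polygon_centroid(mesh$coords[v, , drop = FALSE]), numeric(2))),
    border = vapply(mesh$polys, function(v) any(border_v[v]), logical(1)))
  names(cells)[3:4] <- c("x", "y")
  new_junction_graph(vertices, edges, cells, polylines,
                     mesh$pixel_size_um, dim(mesh$label_image),
                     mesh$ml_axis_deg, field_um = mesh$field_um,
                     source = "mesh", label_image = mesh$label_image)
}

#' Edge orientation relative to the ML axis
#'
#' Angle of the end-to-end chord of an edge polyline, folded into [0, 90]
#' degrees. Edges at 0-15 degrees belong to the mediolateral (ML) bin, edges
#' at 75-90 degrees to the anterior-posterior (AP) bin (closed bins; ties at
#' the boundary are bin members).
#'
#' @param edge either a polyline matrix (>= 2 points) or a row of a graph's
#'   edge table.
#' @param ml_axis_deg ML axis orientation.
#' @return angle in degrees, `NA` (with a warning) for a zero-length chord.
#' @export
edge_angle <- function(edge, ml_axis_deg = 0) {
  if (is.matrix(edge)) {
    stopifnot(nrow(edge) >= 2L)
    dx <- edge[nrow(edge), 1] - edge[1, 1]
    dy <- edge[nrow(edge), 2] - edge[1, 2]
  } else {
    stop("edge must be a polyline matrix")
  }
  a <- fold_angle(dx, dy, ml_axis_deg)
  if (is.na(a)) warning("zero-length chord: angle undefined")
  a
}

#' Junction census by order class
#'
#' Counts graph vertices inside a region, binned as 3-cell, 4-cell and
#' 5+-cell junctions (inclusion by vertex position, half-open box).
#'
#' @param graph a `junction_graph`.
#' @param region a [region_spec()] or `NULL` for the whole field.
#' @return named integer vector `c("3", "4", "5+")`.
#' @export
junction_census <- function(graph, region = NULL) {
  v <- graph$vertices
  v <- v[in_region(v$x, v$y, region), , drop = FALSE]
  cls <- pmin(v$order, 5L)
  c("3" = sum(cls == 3L), "4" = sum(cls == 4L), "5+" = sum(cls >= 5L))
}

#' Apical cell area statistics in a region
#'
#' Per-cell apical areas (um^2) for cells whose centroid lies in the region,
#' excluding cells that touch the image border (their areas are truncated by
#' the field of view).
#'
#' @param graph a `junction_graph`.
#' @param region a [region_spec()] or `NULL`.
#' @return list with `areas` (data frame label/area_um2), `mean_um2`, `n`.
#' @export
cell_area_stats <- function(graph, region = NULL) {
  cells <- graph$cells
  keep <- in_region(cells$x, cells$y, region) & !cells$border
  sel <- cells[keep, , drop = FALSE]
  list(areas = data.frame(label = sel$label, area_um2 = sel$area_um2),
       mean_um2 = mean(sel$area_um2), n = nrow(sel))
}

#' Apical/basal span and cell-height metrics from tissue profiles
#'
#' Given hand-drawn (or synthetic) polylines along the apical and basal
#' tissue borders, computes the arc-length spans, their ratio, and the
#' tissue height measured as the distance between the two polylines at a
#' given arc-length fraction (default halfway).
#'
#' @param apical_polyline,basal_polyline n x 2 matrices (um), >= 2 points.
#' @param height_fraction arc-length fraction at which height is measured.
#' @return list `apical_span`, `basal_span`, `span_ratio`, `cell_height`.
#' @export
tissue_profile_metrics <- function(apical_polyline, basal_polyline,
                                   height_fraction = 0.5) {
  stopifnot(nrow(apical_polyline) >= 2L, nrow(basal_polyline) >= 2L)
  arc <- function(p) {
    d <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
    c(0, cumsum(d))
  }
  point_at <- function(p, f) {
    s <- arc(p); target <- f * s[length(s)]
    i <- max(which(s <= target + 1e-12))
    if (i >= nrow(p)) return(p[nrow(p), ])
    t <- (target - s[i]) / (s[i + 1] - s[i])
    p[i, ] + t * (p[i + 1, ] - p[i, ])
  }
  sa <- arc(apical_polyline); sb <- arc(basal_polyline)
  pa <- point_at(apical_polyline, height_fraction)
  pb <- point_at(basal_polyline, height_fraction)
  list(apical_span = sa[length(sa)], basal_span = sb[length(sb)],
       span_ratio = sa[length(sa)] / sb[length(sb)],
       cell_height = sqrt(sum((pa - pb)^2)))
}
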