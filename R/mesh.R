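# Synthetic epithelial meshes.
#
# A `cell_mesh` is a polygonal tiling of a rectangular field standing in for
# a segmented apical surface: a Lloyd-relaxed Voronoi tessellation gives
# near-hexagonal packing, and a configurable number of short tessellation
# edges are contracted to create 4-cell and 5+-cell vertices (multicellular
# junctions / rosettes) at realistic frequencies. The mesh carries both the
# exact polygon geometry (ground truth) and a rasterised label image with a
# 2-px-wide zero-valued junctional skeleton.

# ---- Voronoi tessellation by half-plane clipping ---------------------------

# polygons of the Voronoi diagram of `pts` clipped to [0,w]x[0,h]
voronoi_polygons <- function(pts, field_um) {
  n <- nrow(pts)
  w <- field_um[1]; h <- field_um[2]
  rect <- matrix(c(0, 0, w, 0, w, h, 0, h), ncol = 2, byrow = TRUE)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    poly <- rect
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    ord <- order(d2)
    for (j in ord) {
      if (j == i) next
      # prune: a bisector at distance d/2 cannot cut the polygon if every
      # polygon vertex is closer to the seed than d/2
      rmax2 <- max((poly[, 1] - pts[i, 1])^2 + (poly[, 2] - pts[i, 2])^2)
      if (d2[j] > 4 * rmax2) break
      mid <- (pts[i, ] + pts[j, ]) / 2
      nrm <- pts[j, ] - pts[i, ]
      poly <- clip_halfplane(poly, mid, nrm)
      if (nrow(poly) < 3L) break
    }
    out[[i]] <- poly
  }
  out
}

# cluster near-coincident polygon corners into canonical vertex ids.
# Returns list(coords = V x 2 matrix, polys = list of id vectors).
canonicalize_vertices <- function(polys_xy, tol = 1e-5) {
  all_pts <- do.call(rbind, polys_xy)
  n <- nrow(all_pts)
  if (n > 1L) {
    cl <- stats::cutree(stats::hclust(stats::dist(all_pts), method = "single"),
                        h = tol)
  } else cl <- 1L
  coords <- cbind(tapply(all_pts[, 1], cl, mean), tapply(all_pts[, 2], cl, mean))
  ids <- split(cl, rep(seq_along(polys_xy), vapply(polys_xy, nrow, 1L)))
  ids <- lapply(ids, function(v) v[c(TRUE, v[-1] != v[-length(v)])])
  ids <- lapply(ids, function(v) if (length(v) > 1L && v[1] == v[length(v)]) v[-length(v)] else v)
  list(coords = coords, polys = unname(ids))
}

# edge table of a canonical tiling: one row per unordered vertex pair that is
# consecutive in at least one polygon, with the flanking cell labels.
tiling_edges <- function(coords, polys) {
  a <- integer(0); b <- integer(0); cell <- integer(0)
  for (k in seq_along(polys)) {
    v <- polys[[k]]
    nv <- length(v)
    if (nv < 2L) next
    a <- c(a, v); b <- c(b, v[c(2:nv, 1L)]); cell <- c(cell, rep(k, nv))
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi)
  first <- !duplicated(key)
  idx <- match(key, key[first])
  c1 <- cell[first]
  c2 <- rep(NA_integer_, sum(first))
  dup <- which(duplicated(key))
  c2[idx[dup]] <- cell[dup]
  data.frame(v1 = lo[first], v2 = hi[first], c1 = c1, c2 = c2)
}

vertex_on_border <- function(coords, field_um, tol = 1e-6) {
  coords[, 1] < tol | coords[, 2] < tol |
    coords[, 1] > field_um[1] - tol | coords[, 2] > field_um[2] - tol
}

# Would contracting `grp` to its centroid leave every incident cell with a
# resolvable wedge at the merged point? Sub-pixel wedges make a high-order
# vertex rasterise as a string of 3-cell corners, so candidate groups whose
# merged configuration has a wedge below `min_angle` (or an adjacent vertex
# closer than `min_adj_um`) are rejected.
contraction_resolvable <- function(coords, polys, grp,
                                   min_angle = 28 * pi / 180,
                                   min_adj_um = 0.8) {
  P <- colMeans(coords[grp, , drop = FALSE])
  for (v in polys) {
    m <- v %in% grp
    if (!any(m)) next
    if (all(m)) return(FALSE)
    nv <- length(v)
    s <- which(!m)[1]
    idx <- ((s:(s + nv - 1L) - 1L) %% nv) + 1L
    v2 <- v[idx]; m2 <- m[idx]
    out <- integer(0); i <- 1L
    while (i <= nv) {
      if (m2[i]) {
        out <- c(out, 0L)
        while (i <= nv && m2[i]) i <- i + 1L
      } else { out <- c(out, v2[i]); i <- i + 1L }
    }
    for (j in which(out == 0L)) {
      prev <- out[if (j == 1L) length(out) else j - 1L]
      nxt <- out[if (j == length(out)) 1L else j + 1L]
      a <- coords[prev, ] - P; b <- coords[nxt, ] - P
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na < min_adj_um || nb < min_adj_um) return(FALSE)
      ang <- acos(min(1, max(-1, sum(a * b) / (na * nb))))
      if (ang < min_angle) return(FALSE)
    }
  }
  TRUE
}

# contract groups of vertex ids to their centroid; polygons keep order,
# consecutive duplicates collapse (the contracted edge disappears)
contract_vertex_groups <- function(coords, polys, groups) {
  map <- seq_len(nrow(coords))
  for (g in groups) {
    keep <- g[1]
    coords[keep, ] <- colMeans(coords[g, , drop = FALSE])
    map[g] <- keep
  }
  polys <- lapply(polys, function(v) {
    v <- map[v]
    v <- v[c(TRUE, v[-1] != v[-length(v)])]
    if (length(v) > 1L && v[1] == v[length(v)]) v <- v[-length(v)]
    v
  })
  list(coords = coords, polys = polys)
}

# ---- mesh construction -----------------------------------------------------

#' Generate a synthetic epithelial cell mesh
#'
#' Builds a Lloyd-relaxed Voronoi tessellation of a rectangular field and
#' optionally contracts short tessellation edges to create vertices where 4
#' or 5+ cells meet (multicellular junctions and rosettes). The mesh carries
#' exact polygon ground truth plus a rasterised label image in which cell
#' interiors take the cell label and a ~2 px junctional skeleton is 0.
#'
#' @param n_cells number of cells (>= 3).
#' @param field_um field size in um (length 1 or 2).
#' @param seed integer seed; the mesh is deterministic given the seed.
#' @param relaxation_steps Lloyd iterations (default 3).
#' @param pixel_size_um raster sampling (default 0.25 um/px).
#' @param n_order4,n_order5 number of 4-cell and 5-cell vertices to create by
#'   edge contraction.
#' @param min_edge_um interior tessellation edges shorter than this are
#'   always contracted (they would be unresolvable in the raster); these
#'   count towards `n_order4`.
#' @param seeds optional matrix of initial seed points (overrides random
#'   placement; useful for constructing exact configurations).
#' @return an object of class `cell_mesh`.
#' @export
make_mesh <- function(n_cells, field_um, seed = 1L, relaxation_steps = 3L,
                      pixel_size_um = 0.25, n_order4 = 0L, n_order5 = 0L,
                      min_edge_um = 0.7, seeds = NULL) {
  if (length(field_um) == 1L) field_um <- rep(field_um, 2L)
  if (is.null(seeds) && n_cells < 3L) stop("n_cells must be >= 3")
  if (any(field_um < 3 * pixel_size_um)) stop("degenerate field: smaller than 3 px")
  if (is.null(seeds)) {
    mean_diam <- 2 * sqrt(prod(field_um) / n_cells / pi)
    if (min(field_um) < 3 * mean_diam)
      stop("field too small relative to cell size (must exceed 3x mean cell diameter)")
  }
  set.seed(seed)
  if (is.null(seeds)) {
    pts <- cbind(stats::runif(n_cells, 0, field_um[1]),
                 stats::runif(n_cells, 0, field_um[2]))
  } else {
    pts <- as.matrix(seeds)
    n_cells <- nrow(pts)
  }
  for (it in seq_len(relaxation_steps)) {
    vp <- voronoi_polygons(pts, field_um)
    pts <- t(vapply(vp, polygon_centroid, numeric(2)))
  }
  vp <- voronoi_polygons(pts, field_um)
  can <- canonicalize_vertices(vp)

  # elevate vertex orders by contracting short interior edges
  #
  # Pass 1 - proximity cleanup: iteratively contract the closest pair of
  # interior vertices until all are at least `min_edge_um` apart. Distinct
  # vertices closer than that are unresolvable at the raster sampling (they
  # would be read as one higher-order vertex anyway), so the truth keeps
  # them merged; contractions that produce 4- or 5-cell vertices count
  # towards the requested quotas.
  n4_left <- n_order4; n5_left <- n_order5
  repeat {
    active <- sort(unique(unlist(can$polys)))
    border <- vertex_on_border(can$coords, field_um)
    ids <- active[!border[active]]
    if (length(ids) < 2L) break
    dmat <- as.matrix(stats::dist(can$coords[ids, , drop = FALSE]))
    diag(dmat) <- Inf
    mn <- arrayInd(which.min(dmat), dim(dmat))
    if (dmat[mn] >= min_edge_um) break
    grp <- c(ids[mn[1]], ids[mn[2]])
    can <- contract_vertex_groups(can$coords, can$polys, list(grp))
    ord_after <- sum(vapply(can$polys, function(p) grp[1] %in% p, logical(1)))
    if (ord_after == 4L) n4_left <- n4_left - 1L
    if (ord_after >= 5L) n5_left <- n5_left - 1L
  }

  # Pass 2 - quota contractions, vetted so the merged point keeps clear of
  # every other vertex and every previously planned merged point
  ed <- tiling_edges(can$coords, can$polys)
  border <- vertex_on_border(can$coords, field_um)
  ord0 <- tabulate(unlist(lapply(can$polys, unique)), nbins = nrow(can$coords))
  len <- sqrt(rowSums((can$coords[ed$v1, , drop = FALSE] -
                       can$coords[ed$v2, , drop = FALSE])^2))
  interior_edge <- !is.na(ed$c2) & !border[ed$v1] & !border[ed$v2] &
    ord0[ed$v1] == 3L & ord0[ed$v2] == 3L
  used <- rep(FALSE, nrow(can$coords))
  groups <- list()
  midpoints <- matrix(numeric(0), 0, 2)
  active_ids <- sort(unique(unlist(can$polys)))
  group_ok <- function(grp) {
    if (!contraction_resolvable(can$coords, can$polys, grp)) return(FALSE)
    P <- colMeans(can$coords[grp, , drop = FALSE])
    others <- setdiff(active_ids, grp)
    if (min((can$coords[others, 1] - P[1])^2 +
            (can$coords[others, 2] - P[2])^2) < 0.9^2) return(FALSE)
    if (nrow(midpoints) > 0L &&
        min((midpoints[, 1] - P[1])^2 + (midpoints[, 2] - P[2])^2) < 0.9^2)
      return(FALSE)
    TRUE
  }
  take_group <- function(grp) {
    groups[[length(groups) + 1L]] <<- grp
    midpoints <<- rbind(midpoints, colMeans(can$coords[grp, , drop = FALSE]))
    used[grp] <<- TRUE
  }

  elig <- which(interior_edge & len < stats::quantile(len[interior_edge], 0.6))
  elig <- elig[sample.int(length(elig))]  # seeded shuffle

  # rosettes: contract two edges sharing a vertex (3 vertices -> 1, 5 cells)
  if (n5_left > 0L) {
    inc <- split(rep(elig, 2L), c(ed$v1[elig], ed$v2[elig]))
    for (v in sample(names(inc))) {
      if (n5_left <= 0L) break
      vi <- as.integer(v)
      if (used[vi]) next
      es <- inc[[v]]
      nbrs <- setdiff(unique(c(ed$v1[es], ed$v2[es])), vi)
      nbrs <- nbrs[!used[nbrs]]
      if (length(nbrs) < 2L) next
      for (pick in utils::combn(nbrs, 2L, simplify = FALSE)) {
        grp <- c(vi, pick)
        n_around <- sum(vapply(can$polys, function(p) any(p %in% grp), logical(1)))
        if (n_around != 5L) next
        if (!group_ok(grp)) next
        take_group(grp)
        n5_left <- n5_left - 1L
        break
      }
    }
  }
  # 4-cell vertices: contract single edges; a second pass over all interior
  # edges fills any remainder the clearance check left open
  for (pass_edges in list(elig, which(interior_edge))) {
    for (e in pass_edges) {
      if (n4_left <= 0L) break
      if (used[ed$v1[e]] || used[ed$v2[e]]) next
      grp <- c(ed$v1[e], ed$v2[e])
      if (!group_ok(grp)) next
      take_group(grp)
      n4_left <- n4_left - 1L
    }
    if (n4_left <= 0L) break
  }

  if (length(groups) > 0L) {
    can <- contract_vertex_groups(can$coords, can$polys, groups)
  }

  mesh <- structure(list(
    coords = can$coords,
    polys = can$polys,
    labels = seq_along(can$polys),
    field_um = field_um,
    pixel_size_um = pixel_size_um,
    seed = seed,
    ml_axis_deg = 0
  ), class = "cell_mesh")
  mesh$label_image <- rasterize_mesh(mesh)
  mesh
}

#' @export
print.cell_mesh <- function(x, ...) {
  vt <- mesh_vertices(x)
  cat(sprintf("<cell_mesh: %d cells, %g x %g um (%.2f um/px), %d interior vertices",
              length(x$polys), x$field_um[1], x$field_um[2], x$pixel_size_um,
              sum(!vt$border)))
  tab <- table(pmin(vt$order[!vt$border], 5L))
  cat(sprintf("; orders %s>\n",
              paste(sprintf("%s:%d", ifelse(names(tab) == "5", "5+", names(tab)),
                            as.integer(tab)), collapse = " ")))
  invisible(x)
}

# ground-truth vertex table: id, x, y, order (= #incident cells), border
mesh_vertices <- function(mesh) {
  ord <- tabulate(unlist(lapply(mesh$polys, unique)), nbins = nrow(mesh$coords))
  present <- ord > 0L
  border <- vertex_on_border(mesh$coords, mesh$field_um)
  data.frame(id = which(present),
             x = mesh$coords[present, 1], y = mesh$coords[present, 2],
             order = ord[present], border = border[present])
}

# ground-truth edge table (interior cell-cell edges plus border edges)
mesh_edges <- function(mesh) {
  ed <- tiling_edges(mesh$coords, mesh$polys)
  p1 <- mesh$coords[ed$v1, , drop = FALSE]
  p2 <- mesh$coords[ed$v2, , drop = FALSE]
  ed$x1 <- p1[, 1]; ed$y1 <- p1[, 2]; ed$x2 <- p2[, 1]; ed$y2 <- p2[, 2]
  ed$length_um <- sqrt((ed$x2 - ed$x1)^2 + (ed$y2 - ed$y1)^2)
  ed$angle_deg <- fold_angle(ed$x2 - ed$x1, ed$y2 - ed$y1, mesh$ml_axis_deg)
  ed
}

#' Euler characteristic of the mesh's planar partition
#'
#' Counts all tessellation vertices (including field corners), all edges
#' (interior and border) and all faces (cells plus the outer face). A valid
#' planar partition satisfies V - E + F = 2.
#'
#' @param mesh a `cell_mesh`.
#' @return integer V - E + F.
#' @export
mesh_euler_characteristic <- function(mesh) {
  ed <- tiling_edges(mesh$coords, mesh$polys)
  v_used <- length(unique(unlist(mesh$polys)))
  v_used - nrow(ed) + (length(mesh$polys) + 1L)
}

# total polygon area (conservation checks)
mesh_total_area <- function(mesh) {
  sum(vapply(mesh$polys, function(v)
    polygon_area(mesh$coords[v, , drop = FALSE]), numeric(1)))
}

# ---- rasterisation ---------------------------------------------------------

# label image with 0-valued ~2 px junctional skeleton between cells
rasterize_mesh <- function(mesh, skeleton = TRUE) {
  px <- mesh$pixel_size_um
  nc <- round(mesh$field_um[1] / px)
  nr <- round(mesh$field_um[2] / px)
  lab <- matrix(0L, nr, nc)
  for (k in seq_along(mesh$polys)) {
    poly <- mesh$coords[mesh$polys[[k]], , drop = FALSE]
    if (nrow(poly) < 3L) next
    c0 <- max(1L, floor(min(poly[, 1]) / px)); c1 <- min(nc, ceiling(max(poly[, 1]) / px) + 1L)
    r0 <- max(1L, floor(min(poly[, 2]) / px)); r1 <- min(nr, ceiling(max(poly[, 2]) / px) + 1L)
    if (c1 < c0 || r1 < r0) next
    cs <- c0:c1; rs <- r0:r1
    pxx <- (rep(cs, each = length(rs)) - 0.5) * px
    pyy <- (rep(rs, times = length(cs)) - 0.5) * px
    ins <- points_in_polygon(pxx, pyy, poly)
    idx <- (rep(rs, times = length(cs)) + (rep(cs, each = length(rs)) - 1L) * nr)[ins]
    lab[idx] <- mesh$labels[k]
  }
  if (!skeleton) return(lab)
  skeletonize_labels(lab)
}

# zero out pixels that touch a different positive label (8-neighbourhood),
# producing a ~2 px wide junctional band
skeletonize_labels <- function(lab) {
  band <- matrix(FALSE, nrow(lab), ncol(lab))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- shift_mat(lab, dr, dc, 0L)
    band <- band | (lab > 0L & nb > 0L & nb != lab)
  }
  lab[band] <- 0L
  lab
}
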