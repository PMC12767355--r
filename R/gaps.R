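# Detection, sizing, merging, stratification and cross-channel association
# of junctional gaps (circular regions of lost junctional signal).

#' Minimum enclosing circle of a set of circles
#'
#' Exact solver by candidate enumeration: the optimum is either one input
#' circle, determined by two circles (center on the connecting line), or by
#' three circles (solved in closed form from the tangency conditions).
#'
#' @param centers n x 2 matrix.
#' @param radii length-n vector.
#' @return list `center`, `radius`; every input circle is contained.
#' @export
min_enclosing_circle <- function(centers, radii) {
  n <- nrow(centers)
  eps <- 1e-9
  covers <- function(ctr, R) {
    all(sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2) + radii <= R + eps)
  }
  best <- list(center = NULL, radius = Inf)
  consider <- function(ctr, R) {
    if (R < best$radius - eps && covers(ctr, R)) best <<- list(center = ctr, radius = R)
  }
  for (i in seq_len(n)) consider(centers[i, ], radii[i])
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- sqrt(sum((centers[j, ] - centers[i, ])^2))
      R <- (d + radii[i] + radii[j]) / 2
      if (R >= max(radii[i], radii[j]) && d > eps) {
        ctr <- centers[i, ] + (R - radii[i]) * (centers[j, ] - centers[i, ]) / d
        consider(ctr, R)
      }
    }
  }
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
      ci <- centers[i, ]; cj <- centers[j, ]; ck <- centers[k, ]
      ri <- radii[i]; rj <- radii[j]; rk <- radii[k]
      # |x - c| = R - r for all three: subtract pairs -> x linear in R
      A <- 2 * rbind(cj - ci, ck - ci)
      if (abs(det(A)) < 1e-12) next
      b0 <- c(sum(cj^2) - sum(ci^2) + ri^2 - rj^2,
              sum(ck^2) - sum(ci^2) + ri^2 - rk^2)
      b1 <- 2 * c(rj - ri, rk - ri)
      Ainv <- solve(A)
      p <- Ainv %*% b0; q <- Ainv %*% b1
      u <- p - ci
      a2 <- sum(q^2) - 1
      b2 <- 2 * sum(u * q) + 2 * ri
      c2 <- sum(u^2) - ri^2
      roots <- if (abs(a2) < 1e-12) {
        if (abs(b2) < 1e-12) numeric(0) else -c2 / b2
      } else {
        disc <- b2^2 - 4 * a2 * c2
        if (disc < 0) numeric(0) else (-b2 + c(-1, 1) * sqrt(disc)) / (2 * a2)
      }
      for (R in roots) {
        if (is.finite(R) && R >= max(ri, rj, rk) - eps)
          consider(as.numeric(p + q * R), R)
      }
    }
  }
  best
}

#' Detect junctional gaps at graph vertices
#'
#' A vertex is scored as gapped when the lower quartile of the background-
#' subtracted junctional-band pixel intensities within `detect_radius_um`
#' of the vertex falls below `threshold_fraction` times the region's median
#' background-subtracted per-edge intensity (an algorithmic stand-in for
#' by-eye "clear loss of signal"; the threshold is exposed and recorded).
#' The gap radius is grown outward along the incident edges until signal
#' recovers. With `include_bicellular`, edge midpoints more than 1 um from
#' any vertex are scored the same way and classed `"bicellular"`.
#'
#' @param image intensity matrix.
#' @param graph a `junction_graph` (needs its label image for the band mask).
#' @param background scalar or `background_estimate`.
#' @param threshold_fraction detection threshold (default 0.3).
#' @param region optional [region_spec()] restricting the reference-edge
#'   median (vertices are always scored over the whole graph).
#' @param include_bicellular also scan edge midpoints.
#' @param detect_radius_um seed-disk radius.
#' @param max_radius_um growth cap.
#' @param channel channel name recorded on the table (`"AJ"` or `"TJ"`).
#' @param median_edge optional externally supplied reference junctional
#'   level (background-subtracted a.u.), e.g. from an intact sister image;
#'   by default it is estimated from this image's edges.
#' @return data frame of class `gap_table`: `id, x, y, radius_um, area_um2,
#'   order_class, vertex_id, score`; attributes `threshold`, `median_edge`,
#'   `channel`.
#' @export
detect_gaps <- function(image, graph, background, threshold_fraction = 0.3,
                        region = NULL, include_bicellular = FALSE,
                        detect_radius_um = 0.45, max_radius_um = 3,
                        channel = "AJ", median_edge = NULL) {
  bg <- if (inherits(background, "background_estimate")) background$value else background
  px <- graph$pixel_size_um
  dims <- dim(image)
  ed <- graph$edges
  if (nrow(ed) == 0L) stop("graph has no edges: gap detection undefined")
  measurable <- which(ed$length_um > 2.2)
  if (length(measurable) == 0L) measurable <- seq_len(nrow(ed))
  mid <- t(vapply(measurable, function(i) {
    pl <- graph$polylines[[i]]
    (pl[1, ] + pl[nrow(pl), ]) / 2
  }, numeric(2)))
  inreg <- in_region(mid[, 1], mid[, 2], region)
  ref_idx <- measurable[inreg]
  if (length(ref_idx) == 0L) ref_idx <- measurable
  med_edge <- if (!is.null(median_edge)) median_edge else {
    edge_means <- vapply(ref_idx, function(i)
      tryCatch(edge_mean_intensity(image, graph$polylines[[i]], px, 0.5, 1.0),
               error = function(e) NA_real_), numeric(1))
    stats::median(edge_means, na.rm = TRUE) - bg
  }
  thr <- threshold_fraction * med_edge

  lab <- graph$label_image
  v <- graph$vertices
  # incident edge chords per vertex, for radius growth
  inc_of <- lapply(v$id, function(id)
    which((!is.na(ed$v1) & ed$v1 == id) | (!is.na(ed$v2) & ed$v2 == id)))

  rows <- list()
  gid <- 0L
  for (i in seq_len(nrow(v))) {
    idx <- pixels_in_disk(v$x[i], v$y[i], detect_radius_um, px, dims)
    if (length(idx) == 0L) next
    if (!is.null(lab)) {
      band <- idx[lab[idx] == 0L]
      if (length(band) >= 2L) idx <- band
    }
    # lower quartile rather than the mean: robust to sub-pixel vertex
    # localisation error, which otherwise lets bright surround pixels mask
    # a gap at high-order vertices
    score <- stats::quantile(image[idx], 0.25, names = FALSE) - bg
    if (score < thr) {
      # grow the radius along incident edges until signal recovers
      r_est <- detect_radius_um
      for (e in inc_of[[i]]) {
        pl <- graph$polylines[[e]]
        far <- if (sqrt(sum((pl[1, ] - c(v$x[i], v$y[i]))^2)) >
                   sqrt(sum((pl[nrow(pl), ] - c(v$x[i], v$y[i]))^2)))
          pl[1, ] else pl[nrow(pl), ]
        dirv <- far - c(v$x[i], v$y[i])
        L <- sqrt(sum(dirv^2))
        if (L < px) next
        dirv <- dirv / L
        ss <- seq(px / 2, min(max_radius_um, L), by = px / 2)
        vals <- bilinear_sample(image, v$x[i] + ss * dirv[1],
                                v$y[i] + ss * dirv[2], px) - bg
        lowrun <- which(vals >= thr)
        ext <- if (length(lowrun) == 0L) ss[length(ss)] else
          if (lowrun[1] == 1L) 0 else ss[lowrun[1] - 1L]
        r_est <- max(r_est, ext)
      }
      gid <- gid + 1L
      rows[[gid]] <- data.frame(
        id = gid, x = v$x[i], y = v$y[i],
        radius_um = min(r_est, max_radius_um),
        order_class = if (v$order[i] >= 5L) "5+" else as.character(v$order[i]),
        vertex_id = v$id[i], score = score)
    }
  }

  if (include_bicellular) {
    for (e in seq_len(nrow(ed))) {
      pl <- graph$polylines[[e]]
      m <- (pl[1, ] + pl[nrow(pl), ]) / 2
      dv <- sqrt((v$x - m[1])^2 + (v$y - m[2])^2)
      if (length(dv) && min(dv) <= 1.0) next  # too close to a vertex
      idx <- pixels_in_disk(m[1], m[2], detect_radius_um, px, dims)
      if (!is.null(lab)) {
        band <- idx[lab[idx] == 0L]
        if (length(band) >= 2L) idx <- band
      }
      if (length(idx) == 0L) next
      score <- stats::quantile(image[idx], 0.25, names = FALSE) - bg
      if (score < thr) {
        gid <- gid + 1L
        rows[[gid]] <- data.frame(id = gid, x = m[1], y = m[2],
                                  radius_um = detect_radius_um,
                                  order_class = "bicellular",
                                  vertex_id = NA_integer_, score = score)
      }
    }
  }

  out <- if (gid > 0L) do.call(rbind, rows) else
    data.frame(id = integer(0), x = numeric(0), y = numeric(0),
               radius_um = numeric(0), order_class = character(0),
               vertex_id = integer(0), score = numeric(0))
  out$area_um2 <- pi * out$radius_um^2
  attr(out, "threshold_fraction") <- threshold_fraction
  attr(out, "median_edge") <- med_edge
  attr(out, "channel") <- channel
  class(out) <- c("gap_table", "data.frame")
  out
}

#' Merge overlapping gap circles
#'
#' Connected components of the circle-overlap graph are replaced by the
#' exact minimum enclosing circle of the component (the redrawn-ROI rule for
#' overlapping gaps), iterated to a fixed point so the result is idempotent.
#' `merged_from` records the constituent gap ids; the original (primitive)
#' table is kept as attribute `"constituents"` for per-junction statistics.
#'
#' @param gaps a `gap_table`.
#' @return a merged `gap_table` with list-column `merged_from`.
#' @export
merge_overlapping_gaps <- function(gaps) {
  prim <- attr(gaps, "constituents") %||% gaps
  g <- gaps
  if (!"merged_from" %in% names(g)) g$merged_from <- as.list(g$id)
  repeat {
    n <- nrow(g)
    if (n <= 1L) break
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    dx <- outer(g$x, g$x, "-"); dy <- outer(g$y, g$y, "-")
    dd <- sqrt(dx^2 + dy^2)
    rs <- outer(g$radius_um, g$radius_um, "+")
    ov <- which(dd <= rs & upper.tri(dd), arr.ind = TRUE)
    if (nrow(ov) == 0L) break
    for (k in seq_len(nrow(ov))) {
      a <- find(ov[k, 1]); b <- find(ov[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    comp <- vapply(seq_len(n), find, integer(1))
    newrows <- lapply(unique(comp), function(cid) {
      ii <- which(comp == cid)
      if (length(ii) == 1L) return(g[ii, , drop = FALSE])
      mec <- min_enclosing_circle(cbind(g$x[ii], g$y[ii]), g$radius_um[ii])
      nearest <- ii[which.min((g$x[ii] - mec$center[1])^2 +
                              (g$y[ii] - mec$center[2])^2)]
      row <- g[nearest, , drop = FALSE]
      row$x <- mec$center[1]; row$y <- mec$center[2]
      row$radius_um <- mec$radius
      row$merged_from <- list(sort(unique(unlist(g$merged_from[ii]))))
      row
    })
    g <- do.call(rbind, newrows)
  }
  g$area_um2 <- pi * g$radius_um^2
  g$id <- seq_len(nrow(g))
  rownames(g) <- NULL
  for (a in c("threshold_fraction", "median_edge", "channel"))
    attr(g, a) <- attr(gaps, a)
  attr(g, "constituents") <- prim
  class(g) <- c("gap_table", "data.frame")
  g
}

#' Fraction of junctions with a gap, stratified by junction order
#'
#' Number of gapped junctions of each order class divided by the total
#' number of junctions of that class in the region (denominators from
#' [junction_census()]). Merged gaps are expanded to their primitive
#' constituents so each junction is scored individually.
#'
#' @param gaps a `gap_table` (merged or not).
#' @param graph the `junction_graph` used for the census.
#' @param region a [region_spec()] or `NULL`.
#' @return named numeric vector `c("3", "4", "5+")` of fractions; `NA` where
#'   the region has no junctions of that class.
#' @export
stratify_gap_frequency <- function(gaps, graph, region = NULL) {
  prim <- attr(gaps, "constituents") %||% gaps
  cen <- junction_census(graph, region)
  sel <- prim$order_class %in% c("3", "4", "5+") &
    in_region(prim$x, prim$y, region)
  gv <- prim[sel & !is.na(prim$vertex_id), , drop = FALSE]
  gv <- gv[!duplicated(gv$vertex_id), , drop = FALSE]
  hits <- table(factor(gv$order_class, levels = c("3", "4", "5+")))
  out <- as.numeric(hits) / as.numeric(cen)
  out[cen == 0] <- NA_real_
  names(out) <- names(cen)
  out
}

#' Count gaps in a region
#'
#' Number of (merged) gaps whose center lies in the half-open region box;
#' bicellular-class gaps are excluded by default, matching the convention
#' that per-region totals count tricellular and multicellular gaps only.
#'
#' @param gaps a `gap_table`.
#' @param region a [region_spec()] or `NULL`.
#' @param exclude_bicellular drop `"bicellular"`-class gaps (default TRUE).
#' @return integer count.
#' @export
region_gap_count <- function(gaps, region = NULL, exclude_bicellular = TRUE) {
  sel <- in_region(gaps$x, gaps$y, region)
  if (exclude_bicellular) sel <- sel & gaps$order_class != "bicellular"
  sum(sel)
}

#' Associate tight-junction gaps with adherens-junction gaps
#'
#' Each TJ gap is assigned to the AJ gap whose circle contains its center
#' (nearest center on ties); every AJ gap gets a TJ area, scored 0 when no
#' TJ gap corresponds to it. TJ gaps matching no AJ circle are logged as
#' anomalies (within `match_radius_um` of an AJ circle they are noted but
#' still scored unassociated, reading "corresponding" strictly).
#'
#' @param aj_gaps,tj_gaps merged `gap_table`s.
#' @param match_radius_um fallback radius for the anomaly log.
#' @return list with `associations` (data frame `aj_gap_id, tj_area_um2,
#'   associated`), `summary` (`n_aj, n_associated, n_unassociated`), and
#'   `anomalies` (unmatched TJ gap ids).
#' @export
associate_aj_tj <- function(aj_gaps, tj_gaps, match_radius_um = 1.0) {
  n_aj <- nrow(aj_gaps)
  tj_area <- rep(0, n_aj)
  anomalies <- integer(0)
  if (nrow(tj_gaps) > 0L && n_aj > 0L) {
    for (t in seq_len(nrow(tj_gaps))) {
      d <- sqrt((aj_gaps$x - tj_gaps$x[t])^2 + (aj_gaps$y - tj_gaps$y[t])^2)
      inside <- which(d <= aj_gaps$radius_um)
      if (length(inside) == 0L) {
        near <- which(d - aj_gaps$radius_um <= match_radius_um)
        anomalies <- c(anomalies, tj_gaps$id[t])
        if (length(near) > 0L)
          message(sprintf(
            "TJ gap %d lies in no AJ circle (nearest within %.2g um); scored unassociated",
            tj_gaps$id[t], match_radius_um))
        next
      }
      j <- inside[which.min(d[inside])]
      tj_area[j] <- tj_area[j] + tj_gaps$area_um2[t]
    }
  } else if (nrow(tj_gaps) > 0L) {
    anomalies <- tj_gaps$id
  }
  associations <- data.frame(aj_gap_id = aj_gaps$id, tj_area_um2 = tj_area,
                             associated = tj_area > 0)
  list(associations = associations,
       summary = c(n_aj = n_aj,
                   n_associated = sum(associations$associated),
                   n_unassociated = n_aj - sum(associations$associated)),
       anomalies = anomalies)
}

#' Gap area distribution
#'
#' Per-gap areas with mean and SD. For tight junctions, pass the
#' `associations` table from [associate_aj_tj()] so the zero-scored entries
#' at unassociated AJ sites are included, as in the figure convention.
#'
#' @param gaps a `gap_table`, or the `associations` data frame (its
#'   `tj_area_um2` column is then used, zeros included).
#' @return list `areas_um2`, `mean_um2`, `sd_um2`, `n`.
#' @export
gap_area_distribution <- function(gaps) {
  areas <- if ("tj_area_um2" %in% names(gaps)) gaps$tj_area_um2 else gaps$area_um2
  list(areas_um2 = areas, mean_um2 = mean(areas),
       sd_um2 = if (length(areas) > 1L) stats::sd(areas) else NA_real_,
       n = length(areas))
}
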