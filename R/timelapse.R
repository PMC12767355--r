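# Synthetic time-lapse generator: junction-labeled movies with uniform
# apical constriction, scheduled cell divisions (furrow ingression,
# configurable new-interface failure and neighbor-contact gaps) and
# scheduled rosette formation by T1-like edge contraction with configurable
# central-gap fates.

# sample() protection for length-1 vectors
sample_from <- function(v, n = 1L, replace = FALSE) {
  if (length(v) == 1L) rep(v, n) else sample(v, n, replace = replace)
}

# area scale factor at time t (min) from the constriction checkpoints
# (piecewise-linear fractional area decrease through (0, 0))
area_factor_at <- function(constriction_fraction_at, t_min) {
  ts <- c(0, as.numeric(names(constriction_fraction_at)))
  fs <- c(0, as.numeric(constriction_fraction_at))
  o <- order(ts); ts <- ts[o]; fs <- fs[o]
  1 - stats::approx(ts, fs, xout = t_min, rule = 2)$y
}

# split a polygon by the line through `pt` with normal `nrm`
split_polygon <- function(poly, pt, nrm) {
  list(clip_halfplane(poly, pt, nrm), clip_halfplane(poly, pt, -nrm))
}

# intersection points of the line ctr + t*dir with the polygon boundary
line_polygon_hits <- function(poly, ctr, dirv) {
  n <- nrow(poly)
  hits <- numeric(0)
  nrm <- c(-dirv[2], dirv[1])
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- poly[i, ]; b <- poly[j, ]
    da <- sum((a - ctr) * nrm); db <- sum((b - ctr) * nrm)
    if ((da > 0) == (db > 0)) next
    t <- da / (da - db)
    p <- a + t * (b - a)
    hits <- c(hits, sum((p - ctr) * dirv))
  }
  hits
}

# Division chord: through the centroid, perpendicular to the long axis,
# rotated away if an endpoint would fall within `clear_um` of an existing
# polygon vertex (a cleavage plane landing on a junction would create an
# artificial high-order vertex).
division_chord <- function(poly, clear_um = 1.2) {
  ctr <- polygon_centroid(poly)
  cxx <- stats::var(poly[, 1]); cyy <- stats::var(poly[, 2])
  cxy <- stats::cov(poly[, 1], poly[, 2])
  th <- 0.5 * atan2(2 * cxy, cxx - cyy)  # long-axis direction
  best <- NULL
  for (off in c(0, 10, -10, 20, -20, 30, -30) * pi / 180) {
    long <- c(cos(th + off), sin(th + off))
    dirv <- c(-long[2], long[1])
    ts <- line_polygon_hits(poly, ctr, dirv)
    if (length(ts) < 2L) next
    ends <- rbind(ctr + min(ts) * dirv, ctr + max(ts) * dirv)
    dmin <- min(sqrt(outer(ends[, 1], poly[, 1], "-")^2 +
                     outer(ends[, 2], poly[, 2], "-")^2))
    cand <- list(center = ctr, normal = long, dir = dirv,
                 half_len = max(abs(ts)))
    if (is.null(best)) best <- cand
    if (dmin >= clear_um) { best <- cand; break }
  }
  best %||% list(center = ctr,
                 normal = c(cos(th), sin(th)),
                 dir = c(-sin(th), cos(th)),
                 half_len = sqrt(max((poly[, 1] - ctr[1])^2 +
                                     (poly[, 2] - ctr[2])^2)))
}

#' Generate a synthetic junction-labeled time-lapse movie
#'
#' Frames at `frame_interval_min` spacing over `duration_min`, rendering a
#' label movie plus an adherens-junction intensity channel. The tissue
#' constricts uniformly so that total apical area follows the configured
#' checkpoints. Scheduled divisions ingress a cleavage furrow (carved into
#' the label image), split into two new daughter labels after a sampled
#' delay, and with probability `p_no_new_interface` never receive junctional
#' signal at the new interface; with probability `p_neighbor_gap` one
#' neighbor contact loses signal from furrow onset. Scheduled rosettes form
#' by contracting two adjacent tessellation edges to a point (5-cell vertex)
#' and may carry a central gap whose fate (repaired / persistent /
#' expanding) follows `rosette_fate_probs`. Every event is logged with
#' frame indices in the returned truth tables.
#'
#' @param config a [generator_config()] (typically a movie preset).
#' @return object of class `timelapse`: `frames` (list of `list(label, AJ)`
#'   matrices), `truth` (`divisions`, `rosettes`, `area_factor`), `config`.
#' @export
make_timelapse <- function(config) {
  stopifnot(config$duration_min >= config$frame_interval_min)
  n_frames <- floor(config$duration_min / config$frame_interval_min) + 1L
  t_min <- (seq_len(n_frames) - 1L) * config$frame_interval_min
  px <- config$pixel_size_um
  mesh <- make_mesh(config$n_cells, config$field_um, seed = config$seed,
                    n_order4 = config$n_order4, n_order5 = config$n_order5,
                    min_edge_um = 1.1, pixel_size_um = px)
  set.seed(config$seed + 7L)
  ctr_field <- config$field_um / 2
  dims <- dim(mesh$label_image)

  # ---- schedule rosettes ---------------------------------------------------
  ed <- tiling_edges(mesh$coords, mesh$polys)
  border <- vertex_on_border(mesh$coords, mesh$field_um)
  ord0 <- tabulate(unlist(lapply(mesh$polys, unique)), nbins = nrow(mesh$coords))
  len <- sqrt(rowSums((mesh$coords[ed$v1, , drop = FALSE] -
                       mesh$coords[ed$v2, , drop = FALSE])^2))
  interior_edge <- !is.na(ed$c2) & !border[ed$v1] & !border[ed$v2] &
    ord0[ed$v1] == 3L & ord0[ed$v2] == 3L
  elig <- which(interior_edge & len < stats::quantile(len[interior_edge], 0.7))
  elig <- elig[sample.int(length(elig))]
  inc <- split(rep(elig, 2L), c(ed$v1[elig], ed$v2[elig]))
  used_v <- rep(FALSE, nrow(mesh$coords))
  rosette_cells <- integer(0)
  rosettes <- list()
  last_frame_90 <- floor(90 / config$frame_interval_min)  # events start early
  for (v in sample(names(inc))) {
    if (length(rosettes) >= config$rosette_count) break
    vi <- as.integer(v)
    if (used_v[vi]) next
    es <- inc[[v]]
    nbrs <- setdiff(unique(c(ed$v1[es], ed$v2[es])), vi)
    nbrs <- nbrs[!used_v[nbrs]]
    if (length(nbrs) < 2L) next
    found <- FALSE
    for (pick in utils::combn(nbrs, 2L, simplify = FALSE)) {
      grp <- c(vi, pick)
      cells_around <- which(vapply(mesh$polys, function(p) any(p %in% grp),
                                   logical(1)))
      if (length(cells_around) != 5L) next
      if (!contraction_resolvable(mesh$coords, mesh$polys, grp)) next
      if (any(cells_around %in% rosette_cells)) next
      found <- TRUE
      ctr <- colMeans(mesh$coords[grp, , drop = FALSE])
      gapped <- stats::runif(1) < config$p_rosette_gap
      fate <- if (gapped)
        sample(names(config$rosette_fate_probs), 1L,
               prob = config$rosette_fate_probs) else "no_gap"
      rosettes[[length(rosettes) + 1L]] <- list(
        id = length(rosettes) + 1L, grp = grp, cells = cells_around,
        form_frame = sample_from(seq(3L, max(3L, min(20L, n_frames - 4L)))),
        x = ctr[1], y = ctr[2], gapped = gapped, fate = fate,
        gap_radius = rtruncnorm_min(1, 0.7, 0.15, 0.5))
      used_v[grp] <- TRUE
      rosette_cells <- c(rosette_cells, cells_around)
      break
    }
  }
  if (length(rosettes) < config$rosette_count)
    warning(sprintf("scheduled %d of %d requested rosettes",
                    length(rosettes), config$rosette_count))

  # ---- schedule divisions --------------------------------------------------
  areas <- vapply(mesh$polys, function(v)
    polygon_area(mesh$coords[v, , drop = FALSE]), numeric(1))
  cell_border <- vapply(mesh$polys, function(v) any(border[v]), logical(1))
  eligible <- which(!cell_border & areas > 0.5 * stats::median(areas) &
                    !(seq_along(mesh$polys) %in% rosette_cells))
  n_div <- min(round(config$division_rate_per_hour * config$n_cells * 1.5),
               length(eligible))
  div_cells <- sample(eligible, n_div)
  divisions <- NULL
  if (n_div > 0L) {
    t0_max <- max(2L, min(last_frame_90, n_frames - 2L))
    t0_range <- seq(2L, t0_max)
    t0f <- sample_from(t0_range, n_div, replace = TRUE)
    delay <- sample(2:5, n_div, replace = TRUE)
    divisions <- data.frame(
      cell = div_cells, t0_frame = t0f, complete_frame = t0f + delay,
      failed = stats::runif(n_div) < config$p_no_new_interface,
      neighbor_gap = stats::runif(n_div) < config$p_neighbor_gap,
      neighbor = NA_integer_, d1 = NA_integer_, d2 = NA_integer_)
    drop <- divisions$complete_frame > n_frames
    if (any(drop)) {
      warning(sprintf("dropping %d divisions scheduled past movie end", sum(drop)))
      divisions <- divisions[!drop, , drop = FALSE]
    }
    # assign daughter labels and a neighbor for the contact gap
    next_label <- length(mesh$polys)
    ced <- tiling_edges(mesh$coords, mesh$polys)
    clen <- sqrt(rowSums((mesh$coords[ced$v1, , drop = FALSE] -
                          mesh$coords[ced$v2, , drop = FALSE])^2))
    for (i in seq_len(nrow(divisions))) {
      divisions$d1[i] <- next_label + 1L
      divisions$d2[i] <- next_label + 2L
      next_label <- next_label + 2L
      erow <- which(!is.na(ced$c2) &
                    (ced$c1 == divisions$cell[i] | ced$c2 == divisions$cell[i]))
      nb <- ifelse(ced$c1[erow] == divisions$cell[i], ced$c2[erow], ced$c1[erow])
      # the dimmed contact must be observable: prefer non-dividing neighbors
      # (one dimmed contact per tracked division) on contacts long enough not
      # to be swallowed by the flanking vertex disks
      ok <- !(nb %in% divisions$cell) & clen[erow] >= 3.5
      if (!any(ok)) ok <- !(nb %in% divisions$cell)
      if (!any(ok)) ok <- rep(TRUE, length(nb))
      cand <- nb[ok]
      if (length(cand))
        divisions$neighbor[i] <- cand[sample.int(length(cand), 1L)]
    }
  } else {
    divisions <- data.frame(cell = integer(0), t0_frame = integer(0),
                            complete_frame = integer(0), failed = logical(0),
                            neighbor_gap = logical(0), neighbor = integer(0),
                            d1 = integer(0), d2 = integer(0))
  }
  div_chords <- lapply(seq_len(nrow(divisions)), function(i)
    division_chord(mesh$coords[mesh$polys[[divisions$cell[i]]], , drop = FALSE]))

  # ---- frame loop ----------------------------------------------------------
  state_coords <- mesh$coords
  state_polys <- mesh$polys             # indexed by label
  state_labels <- seq_along(mesh$polys)
  # polygons are stored as coordinate matrices once topology starts changing
  poly_xy <- lapply(state_polys, function(v) state_coords[v, , drop = FALSE])
  dim_anc <- matrix(integer(0), 0, 2)   # ancestor-level dim pairs
  dim_raw <- matrix(integer(0), 0, 2)   # raw label pairs (failed interfaces)
  anc <- seq_len(max(c(state_labels, divisions$d2, 0L)))
  frames <- vector("list", n_frames)
  base <- config$edge_intensity_base

  rosette_form <- vapply(rosettes, `[[`, numeric(1), "form_frame")
  for (f in seq_len(n_frames)) {
    # topology updates due this frame
    for (ri in which(rosette_form == f)) {
      grp <- rosettes[[ri]]$grp
      P <- colMeans(mesh$coords[grp, , drop = FALSE])
      for (k in seq_along(poly_xy)) {
        pv <- state_polys[[k]]
        if (is.null(pv) || !any(pv %in% grp)) next
        m <- pv %in% grp
        xy <- poly_xy[[k]]
        xy[m, 1] <- P[1]; xy[m, 2] <- P[2]
        dup <- c(FALSE, xy[-1, 1] == xy[-nrow(xy), 1] &
                          xy[-1, 2] == xy[-nrow(xy), 2])
        xy <- xy[!dup, , drop = FALSE]
        if (nrow(xy) > 1L && all(xy[1, ] == xy[nrow(xy), ]))
          xy <- xy[-nrow(xy), , drop = FALSE]
        poly_xy[[k]] <- xy
        pv[m] <- grp[1]
        pv <- pv[c(TRUE, pv[-1] != pv[-length(pv)])]
        if (length(pv) > 1L && pv[1] == pv[length(pv)]) pv <- pv[-length(pv)]
        state_polys[[k]] <- pv
      }
    }
    for (di in which(divisions$complete_frame == f)) {
      cell <- divisions$cell[di]
      ch <- div_chords[[di]]
      halves <- split_polygon(poly_xy[[cell]], ch$center, ch$normal)
      if (nrow(halves[[1]]) < 3L || nrow(halves[[2]]) < 3L) next
      d1 <- divisions$d1[di]; d2 <- divisions$d2[di]
      poly_xy[[cell]] <- matrix(numeric(0), 0, 2)  # retire parent label
      state_polys[[cell]] <- integer(0)
      poly_xy[[d1]] <- halves[[1]]; poly_xy[[d2]] <- halves[[2]]
      state_polys[[d1]] <- integer(0); state_polys[[d2]] <- integer(0)
      anc[c(d1, d2)] <- anc[cell]
      if (divisions$failed[di]) dim_raw <- rbind(dim_raw, c(d1, d2))
    }
    for (di in which(divisions$t0_frame == f)) {
      if (divisions$neighbor_gap[di] && !is.na(divisions$neighbor[di]))
        dim_anc <- rbind(dim_anc, c(anc[divisions$cell[di]],
                                    anc[divisions$neighbor[di]]))
    }

    s <- sqrt(area_factor_at(config$constriction_fraction_at, t_min[f]))
    scale_xy <- function(xy)
      cbind(ctr_field[1] + s * (xy[, 1] - ctr_field[1]),
            ctr_field[2] + s * (xy[, 2] - ctr_field[2]))
    polys_f <- lapply(poly_xy, function(xy)
      if (!is.null(xy) && nrow(xy) >= 3L) scale_xy(xy) else NULL)

    # rasterise labels
    lab <- matrix(0L, dims[1], dims[2])
    for (k in seq_along(polys_f)) {
      poly <- polys_f[[k]]
      if (is.null(poly) || nrow(poly) < 3L) next
      c0 <- max(1L, floor(min(poly[, 1]) / px)); c1 <- min(dims[2], ceiling(max(poly[, 1]) / px) + 1L)
      r0 <- max(1L, floor(min(poly[, 2]) / px)); r1 <- min(dims[1], ceiling(max(poly[, 2]) / px) + 1L)
      if (c1 < c0 || r1 < r0) next
      cs <- c0:c1; rs <- r0:r1
      pxx <- (rep(cs, each = length(rs)) - 0.5) * px
      pyy <- (rep(rs, times = length(cs)) - 0.5) * px
      ins <- points_in_polygon(pxx, pyy, poly)
      idx <- (rep(rs, times = length(cs)) + (rep(cs, each = length(rs)) - 1L) * dims[1])[ins]
      lab[idx] <- k
    }
    filled_probe <- lab

    # junctional signal from polygon sides
    S <- matrix(0, dims[1], dims[2])
    dim_pair <- function(a, b) {
      (nrow(dim_raw) > 0L && any((dim_raw[, 1] == a & dim_raw[, 2] == b) |
                                 (dim_raw[, 1] == b & dim_raw[, 2] == a))) ||
      (nrow(dim_anc) > 0L && any((dim_anc[, 1] == anc[a] & dim_anc[, 2] == anc[b]) |
                                 (dim_anc[, 1] == anc[b] & dim_anc[, 2] == anc[a])))
    }
    for (k in seq_along(polys_f)) {
      poly <- polys_f[[k]]
      if (is.null(poly) || nrow(poly) < 3L) next
      np <- nrow(poly)
      for (i in seq_len(np)) {
        j <- if (i == np) 1L else i + 1L
        p <- poly[i, ]; q <- poly[j, ]
        L <- sqrt(sum((q - p)^2))
        if (L < px) next
        mid <- (p + q) / 2
        nrm <- c(q[2] - p[2], p[1] - q[1]) / L
        other <- 0L
        for (sgn in c(1, -1)) {
          pr <- mid + sgn * 2 * px * nrm
          rr <- floor(pr[2] / px) + 1L; ccq <- floor(pr[1] / px) + 1L
          if (rr >= 1L && rr <= dims[1] && ccq >= 1L && ccq <= dims[2]) {
            lv <- filled_probe[rr, ccq]
            if (lv > 0L && lv != k) { other <- lv; break }
          }
        }
        if (other == 0L) next  # field border or unresolved
        if (dim_pair(k, other)) next
        ang <- fold_angle(q[1] - p[1], q[2] - p[2], 0)
        fac <- if (!is.na(ang) && ang <= 15) config$polarity_factor else 1
        # strip slightly wider than the ~2 px skeleton band so every band
        # pixel carries junctional signal
        idx <- pixels_near_segment(p, q, 1.5 * px, px, dims)
        if (length(idx)) S[idx] <- pmax(S[idx], base * fac)
      }
    }

    # vertex disks at points shared by >= 3 polygons
    key_tab <- table(unlist(lapply(polys_f, function(xy)
      if (!is.null(xy) && nrow(xy) > 0L)
        unique(sprintf("%.4f_%.4f", xy[, 1], xy[, 2])))))
    vkeys <- names(key_tab)[key_tab >= 3L]
    if (length(vkeys)) {
      vc <- do.call(rbind, strsplit(vkeys, "_"))
      vxx <- as.numeric(vc[, 1]); vyy <- as.numeric(vc[, 2])
      for (i in seq_along(vxx)) {
        idx <- pixels_in_disk(vxx[i], vyy[i], 0.7, px, dims)
        if (length(idx)) S[idx] <- base * config$tcj_enrichment
      }
    }

    # rosette central gaps
    for (ri in seq_along(rosettes)) {
      ro <- rosettes[[ri]]
      if (!ro$gapped || f < ro$form_frame) next
      k <- f - ro$form_frame
      r_f <- switch(ro$fate,
        repaired = if (k <= 1L) ro$gap_radius else 0,
        persistent = ro$gap_radius,
        expanding = min(3, ro$gap_radius * 1.25^k),
        0)
      if (r_f <= 0) next
      ctr_s <- c(ctr_field[1] + s * (ro$x - ctr_field[1]),
                 ctr_field[2] + s * (ro$y - ctr_field[2]))
      idx <- pixels_in_disk(ctr_s[1], ctr_s[2], r_f, px, dims)
      if (length(idx)) S[idx] <- 0
    }

    lab_sk <- skeletonize_labels(lab)

    # furrow carving (figure-8 ingression) on the label image
    for (di in seq_len(nrow(divisions))) {
      t0 <- divisions$t0_frame[di]; cf <- divisions$complete_frame[di]
      if (f < t0 || f >= cf) next
      ch <- div_chords[[di]]
      depth <- (f - t0 + 1) / (cf - t0 + 1) * 0.45  # fraction per end
      ctr_s <- c(ctr_field[1] + s * (ch$center[1] - ctr_field[1]),
                 ctr_field[2] + s * (ch$center[2] - ctr_field[2]))
      hl <- s * ch$half_len
      for (sgn in c(1, -1)) {
        a <- ctr_s + sgn * hl * ch$dir
        b <- ctr_s + sgn * hl * (1 - 2 * depth) * ch$dir
        idx <- pixels_near_segment(a, b, px, px, dims)
        if (length(idx)) lab_sk[idx] <- 0L
      }
    }

    img <- config$background_level + S
    if (config$noise_sd > 0) {
      set.seed(config$seed + 97L * f)
      img <- img + matrix(stats::rnorm(length(img), 0, config$noise_sd),
                          dims[1], dims[2])
      img[img < 0] <- 0
    }
    frames[[f]] <- list(label = lab_sk, AJ = img)
  }

  truth_ros <- if (length(rosettes)) data.frame(
    id = vapply(rosettes, `[[`, numeric(1), "id"),
    form_frame = rosette_form,
    x = vapply(rosettes, `[[`, numeric(1), "x"),
    y = vapply(rosettes, `[[`, numeric(1), "y"),
    gapped = vapply(rosettes, `[[`, logical(1), "gapped"),
    fate = vapply(rosettes, `[[`, character(1), "fate")) else
    data.frame(id = integer(0), form_frame = integer(0), x = numeric(0),
               y = numeric(0), gapped = logical(0), fate = character(0))

  structure(list(
    frames = frames,
    truth = list(divisions = divisions, rosettes = truth_ros,
                 area_factor = data.frame(
                   frame = seq_len(n_frames), t_min = t_min,
                   factor = area_factor_at(config$constriction_fraction_at, t_min))),
    config = config, n_frames = n_frames, t_min = t_min,
    pixel_size_um = px, field_um = config$field_um),
    class = "timelapse")
}

#' @export
print.timelapse <- function(x, ...) {
  cat(sprintf("<timelapse '%s': %d frames @ %g min, %d divisions, %d rosettes>\n",
              x$config$preset_name, x$n_frames, x$config$frame_interval_min,
              nrow(x$truth$divisions), nrow(x$truth$rosettes)))
  invisible(x)
}
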