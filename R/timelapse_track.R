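# Scoring of dynamic behaviors in junction-labeled movies: rosette tracking
# and gap-fate classification, division adhesion outcomes, cumulative
# new-interface timing, and apical-area trajectories.

#' Extract a junction graph for every movie frame
#'
#' @param tl a `timelapse`.
#' @return list of `junction_graph`s, one per frame.
#' @export
movie_graphs <- function(tl) {
  lapply(tl$frames, function(fr) extract_graph(fr$label, tl$pixel_size_um))
}

# robust per-frame intensity reference: background from cell-interior pixels,
# junctional level from skeleton-band pixels
movie_threshold <- function(frame, threshold_fraction = 0.3) {
  bg <- stats::median(frame$AJ[frame$label > 0L])
  band <- stats::median(frame$AJ[frame$label == 0L])
  bg + threshold_fraction * (band - bg)
}

# Trim the ends of a boundary-pixel selection: drop pixel pairs within
# `trim_um` of the contact's extreme points (where tricellular signal from
# the flanking vertices would contaminate the contact mean). Falls back to
# the untrimmed selection for very short contacts.
trim_contact_ends <- function(p1, dims, px, trim_um = 0.8) {
  if (length(p1) < 4L) return(seq_along(p1))
  x <- ((p1 - 1L) %/% dims[1] - 0.5) * px + px
  y <- ((p1 - 1L) %% dims[1] - 0.5) * px + px
  vx <- stats::var(x); vy <- stats::var(y); vxy <- stats::cov(x, y)
  th <- 0.5 * atan2(2 * vxy, vx - vy)
  pr <- x * cos(th) + y * sin(th)
  # short contacts get a reduced trim so that a measurable middle remains
  t_eff <- min(trim_um, max(0, (max(pr) - min(pr) - 0.6) / 2))
  keep <- which(pr > min(pr) + t_eff & pr < max(pr) - t_eff)
  if (length(keep) >= 2L) keep else seq_along(p1)
}

# contact statistic: lower quartile of the boundary pixel-pair means, so a
# voided contact reads as background even when a few bright pixels from the
# flanking vertex disks survive the trim
contact_stat <- function(v) stats::quantile(v, 0.25, names = FALSE)

# boundary pixel-pair table of a filled label image:
# p1, p2 (linear indices), l1 < l2
boundary_pairs <- function(F) {
  nr <- nrow(F); nc <- ncol(F)
  Lh <- F[, -nc]; Rh <- F[, -1]
  ih <- which(Lh != Rh & Lh > 0L & Rh > 0L)
  rh <- (ih - 1L) %% nr + 1L; chh <- (ih - 1L) %/% nr + 1L
  p1h <- rh + (chh - 1L) * nr; p2h <- p1h + nr
  Lv <- F[-nr, ]; Rv <- F[-1, ]
  iv <- which(Lv != Rv & Lv > 0L & Rv > 0L)
  rv <- (iv - 1L) %% (nr - 1L) + 1L; cvv <- (iv - 1L) %/% (nr - 1L) + 1L
  p1v <- rv + (cvv - 1L) * nr; p2v <- p1v + 1L
  data.frame(p1 = c(p1h, p1v), p2 = c(p2h, p2v),
             l1 = c(pmin(Lh[ih], Rh[ih]), pmin(Lv[iv], Rv[iv])),
             l2 = c(pmax(Lh[ih], Rh[ih]), pmax(Lv[iv], Rv[iv])))
}

#' Track cell divisions and score adhesion outcomes
#'
#' For each supplied division event (cell label and furrow-onset frame,
#' normally the generator truth log), the cell lineage is followed by
#' frame-to-frame footprint overlap until the label splits into daughters.
#' The division is scored `completed` at the first frame the mean junctional
#' intensity along the daughter-daughter interface exceeds the gap
#' threshold; events with no junction-positive interface within 90 minutes
#' are right-censored and scored as new-interface failures. A neighbor-
#' contact gap is scored when the mean intensity along a contact between the
#' dividing lineage and a neighbor lineage stays below threshold for at
#' least two consecutive frames and is not restored by the end of the
#' 90-minute window.
#'
#' @param tl a `timelapse`.
#' @param events data frame with `cell`, `t0_frame` (defaults to the truth
#'   log).
#' @param threshold_fraction gap threshold as a fraction of the junctional
#'   level above background.
#' @param window_min scoring window after furrow onset (90 min).
#' @return data frame of class `division_tracks`: one row per event with
#'   `cell, t0_frame, censored, split_frame, completed, completion_time_min,
#'   censored_at_90, neighbor_gap`.
#' @export
track_divisions <- function(tl, events = NULL, threshold_fraction = 0.3,
                            window_min = 90) {
  if (is.null(events)) events <- tl$truth$divisions
  nF <- tl$n_frames
  dt <- tl$config$frame_interval_min
  win_frames <- floor(window_min / dt)
  filled <- lapply(tl$frames, function(fr) fill_labels(fr$label))
  pairs <- lapply(filled, boundary_pairs)
  thr <- movie_threshold(tl$frames[[1]], threshold_fraction)
  dims <- dim(tl$frames[[1]]$label)

  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    cell <- events$cell[i]; t0 <- events$t0_frame[i]
    fend <- min(t0 + win_frames, nF)
    fp <- which(filled[[t0]] == cell)
    if (length(fp) == 0L) next
    rr <- (fp - 1L) %% dims[1] + 1L; cc <- (fp - 1L) %/% dims[1] + 1L
    censored <- any(rr == 1L | cc == 1L | rr == dims[1] | cc == dims[2])
    pr <- pairs[[t0]]
    nbrs <- setdiff(unique(c(pr$l2[pr$l1 == cell], pr$l1[pr$l2 == cell])), cell)
    lineages <- c(list(cell), as.list(nbrs))
    fps <- c(list(fp), lapply(nbrs, function(n) which(filled[[t0]] == n)))
    contact <- matrix(NA_real_, length(nbrs), fend - t0 + 1L)
    measure_contacts <- function(f, col, labsC, labsN_list) {
      prf <- pairs[[f]]
      aj <- tl$frames[[f]]$AJ
      for (n in seq_along(labsN_list)) {
        sel <- which((prf$l1 %in% labsC & prf$l2 %in% labsN_list[[n]]) |
                     (prf$l1 %in% labsN_list[[n]] & prf$l2 %in% labsC))
        if (length(sel)) {
          keep <- sel[trim_contact_ends(prf$p1[sel], dims, tl$pixel_size_um)]
          contact[n, col] <<- contact_stat((aj[prf$p1[keep]] + aj[prf$p2[keep]]) / 2)
        }
      }
    }
    labs_by_lin <- lineages
    measure_contacts(t0, 1L, labs_by_lin[[1]], labs_by_lin[-1])
    split_frame <- NA_integer_; daughters <- NULL
    completed <- FALSE; completion_frame <- NA_integer_
    for (f in seq(t0 + 1L, fend)) {
      Ff <- filled[[f]]
      for (g in seq_along(labs_by_lin)) {
        occ <- table(Ff[fps[[g]]])
        occ <- occ[as.integer(names(occ)) > 0L]
        keep <- as.integer(names(occ))[occ >= max(5, 0.2 * length(fps[[g]]))]
        if (length(keep)) {
          labs_by_lin[[g]] <- keep
          fps[[g]] <- which(Ff %in% keep)
        }
      }
      if (is.na(split_frame) && length(labs_by_lin[[1]]) >= 2L &&
          !(cell %in% labs_by_lin[[1]])) {
        split_frame <- f
        daughters <- sort(labs_by_lin[[1]][1:2])
      }
      if (!is.na(split_frame) && !completed) {
        prf <- pairs[[f]]
        sel <- which(prf$l1 == daughters[1] & prf$l2 == daughters[2])
        if (length(sel)) {
          keep <- sel[trim_contact_ends(prf$p1[sel], dims, tl$pixel_size_um)]
          aj <- tl$frames[[f]]$AJ
          m <- contact_stat((aj[prf$p1[keep]] + aj[prf$p2[keep]]) / 2)
          if (m > thr) { completed <- TRUE; completion_frame <- f }
        }
      }
      measure_contacts(f, f - t0 + 1L, labs_by_lin[[1]], labs_by_lin[-1])
    }
    gapped_n <- apply(contact, 1, function(m) {
      v <- which(!is.na(m))
      if (length(v) < 2L) return(FALSE)
      below <- m[v] < thr
      run2 <- any(below[-1] & below[-length(below)])
      run2 && below[length(below)]
    })
    out[[i]] <- data.frame(
      cell = cell, t0_frame = t0, censored = censored,
      split_frame = split_frame, completed = completed,
      completion_time_min = if (completed) (completion_frame - t0) * dt else NA_real_,
      censored_at_90 = !completed,
      neighbor_gap = length(gapped_n) > 0 && any(gapped_n))
  }
  out <- do.call(rbind, out)
  class(out) <- c("division_tracks", "data.frame")
  attr(out, "threshold") <- thr
  out
}

#' Track rosettes (5+-cell vertices) across frames
#'
#' A rosette is born at the first frame a vertex of order >= 5 appears;
#' tracks are linked across frames by nearest-neighbor vertex matching
#' within `max_step_um` (ties go to the lower track id). Tracks seen in
#' fewer than `min_frames` frames are discarded as detection flicker.
#' Formation mode is `"preexisting"` when the track starts on the first
#' frame, otherwise `"rearrangement"` if the constituent cells were not all
#' mutually adjacent at movie start (and `"undetermined"` when adjacency
#' cannot be resolved).
#'
#' @param graphs per-frame graphs from [movie_graphs()].
#' @param max_step_um linking radius per frame.
#' @param min_frames minimum detections for a valid track. Tracks that are
#'   disjoint in time but spatially continuous (a vertex lost by the
#'   detector for a few frames) are re-joined before filtering.
#' @return data frame of class `rosette_tracks`: `id, first_frame,
#'   n_frames, x, y, max_order, formation_mode`, with per-frame positions in
#'   attribute `"positions"`.
#' @export
track_rosettes <- function(graphs, max_step_um = 3, min_frames = 2L) {
  tracks <- list()
  for (f in seq_along(graphs)) {
    v <- graphs[[f]]$vertices
    v <- v[v$order >= 5L, , drop = FALSE]
    if (nrow(v) == 0L) next
    taken <- rep(FALSE, nrow(v))
    for (ti in seq_along(tracks)) {
      tr <- tracks[[ti]]
      d <- sqrt((v$x - tr$x)^2 + (v$y - tr$y)^2)
      cand <- which(d <= max_step_um & !taken)
      if (length(cand)) {
        j <- cand[order(d[cand], v$id[cand])][1]
        if (length(cand) > 1L)
          message(sprintf("rosette linking tie at frame %d; nearest/lowest-id wins", f))
        tr$x <- v$x[j]; tr$y <- v$y[j]
        tr$frames <- c(tr$frames, f)
        tr$pos <- rbind(tr$pos, c(f, v$x[j], v$y[j]))
        tr$max_order <- max(tr$max_order, v$order[j])
        tracks[[ti]] <- tr
        taken[j] <- TRUE
      }
    }
    for (j in which(!taken)) {
      tracks[[length(tracks) + 1L]] <- list(
        id = length(tracks) + 1L, first_frame = f, vertex_id = v$id[j],
        x = v$x[j], y = v$y[j], frames = f,
        pos = matrix(c(f, v$x[j], v$y[j]), 1), max_order = v$order[j])
    }
  }
  # re-join fragmented tracks: disjoint in time, continuous in space
  if (length(tracks) > 1L) {
    repeat {
      joined <- FALSE
      for (a in seq_along(tracks)) {
        for (b in seq_along(tracks)) {
          if (a == b || is.null(tracks[[a]]) || is.null(tracks[[b]])) next
          ta <- tracks[[a]]; tb <- tracks[[b]]
          if (max(ta$frames) >= min(tb$frames)) next
          gap <- min(tb$frames) - max(ta$frames)
          dd <- sqrt((ta$pos[nrow(ta$pos), 2] - tb$pos[1, 2])^2 +
                     (ta$pos[nrow(ta$pos), 3] - tb$pos[1, 3])^2)
          if (gap <= 8L && dd <= max_step_um + 0.35 * gap) {
            ta$frames <- c(ta$frames, tb$frames)
            ta$pos <- rbind(ta$pos, tb$pos)
            ta$x <- tb$x; ta$y <- tb$y
            ta$max_order <- max(ta$max_order, tb$max_order)
            tracks[[a]] <- ta
            tracks[[b]] <- NULL
            joined <- TRUE
            break
          }
        }
        if (joined) break
      }
      if (!joined) break
    }
    tracks <- Filter(Negate(is.null), tracks)
    # absorb parallel duplicates (the same rosette split into two nearby
    # detections): tracks whose positions coincide within 1.5 um at nearby
    # frames are one structure
    repeat {
      joined <- FALSE
      for (a in seq_along(tracks)) {
        for (b in seq_along(tracks)) {
          if (b <= a || is.null(tracks[[a]]) || is.null(tracks[[b]])) next
          ta <- tracks[[a]]; tb <- tracks[[b]]
          fd <- abs(outer(ta$pos[, 1], tb$pos[, 1], "-"))
          dd <- sqrt(outer(ta$pos[, 2], tb$pos[, 2], "-")^2 +
                     outer(ta$pos[, 3], tb$pos[, 3], "-")^2)
          if (min(dd[fd <= 2]) < 1.5) {
            keep <- if (length(ta$frames) >= length(tb$frames)) a else b
            drop <- if (keep == a) b else a
            tk <- tracks[[keep]]
            tk$first_frame <- min(tk$first_frame, tracks[[drop]]$first_frame,
                                  tk$frames[1])
            extra <- !(tracks[[drop]]$frames %in% tk$frames)
            if (any(extra)) {
              tk$frames <- c(tk$frames, tracks[[drop]]$frames[extra])
              tk$pos <- rbind(tk$pos, tracks[[drop]]$pos[extra, , drop = FALSE])
              o <- order(tk$pos[, 1])
              tk$pos <- tk$pos[o, , drop = FALSE]
              tk$frames <- sort(tk$frames)
            }
            tracks[[keep]] <- tk
            tracks[[drop]] <- NULL
            joined <- TRUE
            break
          }
        }
        if (joined) break
      }
      if (!joined) break
    }
    tracks <- Filter(Negate(is.null), tracks)
  }
  tracks <- Filter(function(tr) length(tr$frames) >= min_frames, tracks)
  if (length(tracks) == 0L) {
    out <- data.frame(id = integer(0), first_frame = integer(0),
                      n_frames = integer(0), x = numeric(0), y = numeric(0),
                      max_order = integer(0), formation_mode = character(0))
    class(out) <- c("rosette_tracks", "data.frame")
    return(out)
  }
  # adjacency at movie start, for the formation mode
  e1 <- graphs[[1]]$edges
  adj1 <- paste(pmin(e1$c1, e1$c2), pmax(e1$c1, e1$c2))
  mode_of <- function(tr) {
    if (tr$first_frame == 1L) return("preexisting")
    g <- graphs[[tr$first_frame]]
    ed <- g$edges
    vid <- g$vertices$id[which.min((g$vertices$x - tr$pos[1, 2])^2 +
                                   (g$vertices$y - tr$pos[1, 3])^2)]
    inc <- which((!is.na(ed$v1) & ed$v1 == vid) | (!is.na(ed$v2) & ed$v2 == vid))
    cells <- unique(c(ed$c1[inc], ed$c2[inc]))
    if (length(cells) < 5L) return("undetermined")
    pairs <- utils::combn(sort(cells), 2L)
    all_adj <- all(paste(pairs[1, ], pairs[2, ]) %in% adj1)
    if (all_adj) "undetermined" else "rearrangement"
  }
  out <- data.frame(
    id = seq_along(tracks),
    first_frame = vapply(tracks, `[[`, integer(1), "first_frame"),
    n_frames = vapply(tracks, function(tr) length(tr$frames), integer(1)),
    x = vapply(tracks, function(tr) mean(tr$pos[, 2]), numeric(1)),
    y = vapply(tracks, function(tr) mean(tr$pos[, 3]), numeric(1)),
    max_order = vapply(tracks, function(tr) as.integer(tr$max_order), integer(1)),
    formation_mode = vapply(tracks, mode_of, character(1)))
  attr(out, "positions") <- lapply(tracks, `[[`, "pos")
  class(out) <- c("rosette_tracks", "data.frame")
  out
}

#' Classify the central-gap fate of a rosette track
#'
#' Measures, at every frame from rosette formation on, the area of voided
#' junctional-band pixels (intensity below the gap threshold) within
#' `window_um` of the tracked center. Fates: `no_gap` if a gap is never
#' present; `expanding` if the gap area strictly increases over at least two
#' consecutive frames; `repaired` if the gap disappears and stays absent for
#' the rest of the movie (>= 2 frames); otherwise `persistent`.
#'
#' @param track one row of [track_rosettes()] output (with its positions
#'   attribute entry passed as `positions`).
#' @param tl the `timelapse`.
#' @param positions per-frame position matrix for this track.
#' @param threshold_fraction gap threshold fraction.
#' @param window_um measurement radius around the center.
#' @param min_area_px minimum voided pixels for "gap present".
#' @param lookback_frames also inspect this many frames before the first
#'   detection: a rosette picked up a frame or two late would otherwise
#'   miss a short-lived (repaired) central gap.
#' @return list `gap_fate`, `areas_um2` (per frame from formation).
#' @export
classify_rosette_fate <- function(track, tl, positions = NULL,
                                  threshold_fraction = 0.3, window_um = 3.5,
                                  min_area_px = 2L, lookback_frames = 2L) {
  thr <- movie_threshold(tl$frames[[1]], threshold_fraction)
  px <- tl$pixel_size_um
  f0 <- max(1L, track$first_frame - as.integer(lookback_frames))
  nF <- tl$n_frames
  areas <- numeric(nF - f0 + 1L)
  dims <- dim(tl$frames[[1]]$label)
  for (f in f0:nF) {
    if (!is.null(positions)) {
      known <- positions[positions[, 1] <= f, , drop = FALSE]
      ctr <- if (nrow(known)) known[nrow(known), 2:3] else positions[1, 2:3]
    } else ctr <- c(track$x, track$y)
    fr <- tl$frames[[f]]
    idx <- pixels_in_disk(ctr[1], ctr[2], window_um, px, dims)
    voided <- idx[fr$label[idx] == 0L & fr$AJ[idx] < thr]
    # only the voided component connected to the rosette center counts as
    # the central gap (distant voids, e.g. at dividing cells, do not)
    seed <- intersect(voided, pixels_in_disk(ctr[1], ctr[2], 0.7, px, dims))
    if (length(seed) == 0L) { areas[f - f0 + 1L] <- 0; next }
    vset <- sort(voided)
    comp <- seed
    frontier <- seed
    nbr_off <- c(-1L, 1L, -dims[1], dims[1], -dims[1] - 1L, -dims[1] + 1L,
                 dims[1] - 1L, dims[1] + 1L)
    while (length(frontier)) {
      cand <- setdiff(intersect(as.vector(outer(frontier, nbr_off, "+")), vset),
                      comp)
      comp <- c(comp, cand)
      frontier <- cand
    }
    areas[f - f0 + 1L] <- length(comp) * px^2
  }
  present <- areas >= min_area_px * px^2
  fate <- if (!any(present)) "no_gap" else {
    # expansion must be multiplicative (>12%/frame for two consecutive
    # frames) so the slow apparent growth of a fixed-radius gap in a
    # constricting tissue does not count
    inc <- areas[-1] > 1.12 * areas[-length(areas)] & present[-1]
    expanding <- any(inc[-length(inc)] & inc[-1] &
                     present[seq_len(length(inc) - 1L)])
    if (expanding) "expanding" else {
      last_pres <- max(which(present))
      if (last_pres <= length(present) - 2L) "repaired" else "persistent"
    }
  }
  list(gap_fate = fate, areas_um2 = areas)
}

#' Score gap fates for all rosette tracks
#'
#' @param tracks a `rosette_tracks` table.
#' @param tl the `timelapse`.
#' @param ... passed to [classify_rosette_fate()].
#' @return `tracks` with a `gap_fate` column added.
#' @export
rosette_gap_fates <- function(tracks, tl, ...) {
  pos <- attr(tracks, "positions")
  tracks$gap_fate <- vapply(seq_len(nrow(tracks)), function(i)
    classify_rosette_fate(tracks[i, ], tl, positions = pos[[i]], ...)$gap_fate,
    character(1))
  tracks
}

#' Cumulative new-interface completion curve
#'
#' Cumulative fraction of divisions that have formed a junction-positive new
#' vertex or interface by each time point, on the movie's frame grid. The
#' denominator defaults to completed divisions (the figure convention);
#' `"all"` uses every tracked division.
#'
#' @param tracks a `division_tracks` table.
#' @param times_min evaluation grid (minutes after furrow onset).
#' @param denominator `"completed"` or `"all"`.
#' @return data frame `t_min`, `cumulative_fraction` (nondecreasing).
#' @export
cumulative_new_interface <- function(tracks, times_min = seq(0, 90, by = 6),
                                     denominator = c("completed", "all")) {
  denominator <- match.arg(denominator)
  tracks <- tracks[!tracks$censored, , drop = FALSE]
  if (nrow(tracks) == 0L) stop("no uncensored division tracks")
  den <- if (denominator == "completed") sum(tracks$completed) else nrow(tracks)
  ct <- tracks$completion_time_min[tracks$completed]
  frac <- vapply(times_min, function(t) sum(ct <= t) / den, numeric(1))
  data.frame(t_min = times_min, cumulative_fraction = frac)
}

#' Percent apical-area change of tracked cells at checkpoints
#'
#' Sums the apical areas of cells trackable from frame 1 to each checkpoint
#' frame (same label present at both frames, touching the image border at
#' neither; cells lost to division or field exit drop out pairwise) and
#' reports the percent decrease relative to frame 1.
#'
#' @param graphs per-frame graphs from [movie_graphs()].
#' @param region optional [region_spec()] applied to frame-1 centroids.
#' @param checkpoints_min times at which to report (default 90 and 180 min).
#' @param frame_interval_min frame spacing.
#' @return data frame `t_min, pct_decrease, n_tracked, unreliable` (flagged
#'   when fewer than half of the initial cells remain trackable).
#' @export
area_trajectory <- function(graphs, region = NULL,
                            checkpoints_min = c(90, 180),
                            frame_interval_min = 6) {
  g0 <- graphs[[1]]
  c0 <- g0$cells[!g0$cells$border, , drop = FALSE]
  c0 <- c0[in_region(c0$x, c0$y, region), , drop = FALSE]
  out <- lapply(checkpoints_min, function(tm) {
    fi <- round(tm / frame_interval_min) + 1L
    if (fi > length(graphs)) return(NULL)
    ck <- graphs[[fi]]$cells
    ck <- ck[!ck$border, , drop = FALSE]
    common <- intersect(c0$label, ck$label)
    a0 <- sum(c0$area_um2[match(common, c0$label)])
    ak <- sum(ck$area_um2[match(common, ck$label)])
    data.frame(t_min = tm, pct_decrease = 100 * (1 - ak / a0),
               n_tracked = length(common),
               unreliable = length(common) < 0.5 * nrow(c0))
  })
  out <- do.call(rbind, out)
  if (any(out$unreliable))
    warning("fewer than 50% of initial cells trackable at some checkpoint")
  out
}
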