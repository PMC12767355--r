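# Rendering of junctional intensity channels and gap injection.

# signal (above background) laid down by edges and vertex disks; shared by
# the static renderer and the movie renderer
render_signal <- function(mesh, config, dims,
                          edge_factors = NULL, vertex_disks = TRUE,
                          tcj_radius_um = 0.5, edge_halfwidth_px = 1.5) {
  px <- mesh$pixel_size_um
  base <- config$edge_intensity_base
  S <- matrix(0, dims[1], dims[2])
  ed <- mesh_edges(mesh)
  ed <- ed[!is.na(ed$c2), , drop = FALSE]  # cell-cell interfaces only
  ml <- !is.na(ed$angle_deg) & ed$angle_deg <= 15
  fac <- ifelse(ml, config$polarity_factor, 1)
  if (!is.null(edge_factors)) fac <- fac * edge_factors(ed)
  hw <- edge_halfwidth_px * px
  for (i in seq_len(nrow(ed))) {
    if (fac[i] == 0) next
    idx <- pixels_near_segment(c(ed$x1[i], ed$y1[i]), c(ed$x2[i], ed$y2[i]),
                               hw, px, dims)
    if (length(idx)) S[idx] <- pmax(S[idx], base * fac[i])
  }
  if (vertex_disks) {
    vt <- mesh_vertices(mesh)
    vt <- vt[!vt$border & vt$order >= 3L, , drop = FALSE]
    for (i in seq_len(nrow(vt))) {
      idx <- pixels_in_disk(vt$x[i], vt$y[i], tcj_radius_um, px, dims)
      if (length(idx)) S[idx] <- base * config$tcj_enrichment
    }
  }
  S
}

#' Render intensity channels for a synthetic mesh
#'
#' Draws junctional signal over a uniform cytoplasmic background: edge
#' strips of 1.5 px half-width (slightly wider than the ~2 px label
#' skeleton, so every band pixel carries signal) at `edge_intensity_base`
#' (scaled by `polarity_factor` for edges within 15 degrees of the ML
#' axis), vertex disks of radius 0.5 um at
#' `tcj_enrichment * edge_intensity_base`, plus seeded additive Gaussian
#' noise. Negative values are clipped at 0 (and reported).
#'
#' @param mesh a [make_mesh()] result.
#' @param config a [generator_config()]; must share `pixel_size_um`.
#' @param channels character vector of channel names, e.g. `c("AJ", "TJ")`.
#' @param noise draw Gaussian noise (sd `config$noise_sd`)? Disable for
#'   exact round-trip checks.
#' @return named list of intensity matrices (a.u.).
#' @export
render_channels <- function(mesh, config, channels = "AJ", noise = TRUE) {
  if (abs(mesh$pixel_size_um - config$pixel_size_um) > 1e-9)
    stop("mesh and config disagree on pixel_size_um")
  dims <- dim(mesh$label_image)
  out <- vector("list", length(channels))
  names(out) <- channels
  for (k in seq_along(channels)) {
    S <- render_signal(mesh, config, dims)
    img <- config$background_level + S
    if (noise && config$noise_sd > 0) {
      set.seed(config$seed + 10007L * k)
      img <- img + matrix(stats::rnorm(length(img), 0, config$noise_sd),
                          dims[1], dims[2])
    }
    nneg <- sum(img < 0)
    if (nneg > 0) {
      message(sprintf("render_channels: clipped %d negative pixels to 0 in '%s'",
                      nneg, channels[k]))
      img[img < 0] <- 0
    }
    out[[k]] <- img
  }
  out
}

#' Inject junctional gaps at mesh vertices
#'
#' Each interior vertex of order k is independently voided with probability
#' `gap_prob_by_order[k]` (orders above 5 use the 5+ entry): pixels within a
#' sampled radius revert to background (plus noise). Gap radii come from a
#' truncated normal (`gap_radius_um`, lower bound `gap_radius_min_um`);
#' non-positive or sub-minimum samples are re-drawn. When a `"TJ"` channel
#' is present, tight-junction gaps occur only at AJ gap sites (probability
#' `tj_gap_prob`) with half the AJ radius.
#'
#' @param mesh a `cell_mesh`.
#' @param channels named list of intensity images from [render_channels()].
#' @param config a [generator_config()].
#' @param seed RNG seed for gap placement (defaults to `config$seed + 1`).
#' @return `list(channels = modified channels, truth = data.frame)` where
#'   truth has one row per injected gap: `x, y, radius_um, junction_order,
#'   channel`.
#' @export
inject_gaps <- function(mesh, channels, config, seed = config$seed + 1L) {
  stopifnot(all(names(config$gap_prob_by_order) %in% c("3", "4", "5")))
  px <- mesh$pixel_size_um
  dims <- dim(mesh$label_image)
  vt <- mesh_vertices(mesh)
  vt <- vt[!vt$border & vt$order >= 3L, , drop = FALSE]
  set.seed(seed)
  pk <- config$gap_prob_by_order[as.character(pmin(vt$order, 5L))]
  hit <- stats::runif(nrow(vt)) < pk
  n <- sum(hit)
  truth <- data.frame(x = numeric(0), y = numeric(0), radius_um = numeric(0),
                      junction_order = integer(0), channel = character(0))
  if (n > 0L) {
    r <- rtruncnorm_min(n, config$gap_radius_um[1], config$gap_radius_um[2],
                        config$gap_radius_min_um)
    vh <- vt[hit, , drop = FALSE]
    truth <- data.frame(x = vh$x, y = vh$y, radius_um = r,
                        junction_order = vh$order, channel = "AJ")
    if ("AJ" %in% names(channels)) {
      for (i in seq_len(n)) {
        idx <- pixels_in_disk(vh$x[i], vh$y[i], r[i], px, dims)
        channels$AJ[idx] <- config$background_level +
          if (config$noise_sd > 0) stats::rnorm(length(idx), 0, config$noise_sd) else 0
      }
    }
    if ("TJ" %in% names(channels) && config$tj_gap_prob > 0) {
      tj <- stats::runif(n) < config$tj_gap_prob
      if (any(tj)) {
        vtj <- vh[tj, , drop = FALSE]
        rtj <- r[tj] * 0.5
        for (i in seq_len(nrow(vtj))) {
          idx <- pixels_in_disk(vtj$x[i], vtj$y[i], rtj[i], px, dims)
          channels$TJ[idx] <- config$background_level +
            if (config$noise_sd > 0) stats::rnorm(length(idx), 0, config$noise_sd) else 0
        }
        truth <- rbind(truth, data.frame(x = vtj$x, y = vtj$y, radius_um = rtj,
                                         junction_order = vtj$order,
                                         channel = "TJ"))
      }
    }
  }
  truth$gap_id <- seq_len(nrow(truth))
  list(channels = channels, truth = truth)
}

#' Simulate a post-ablation recoil trace
#'
#' Vertex-pair distance versus time after laser ablation of the connecting
#' interface, following an exponential (Kelvin-Voigt) relaxation
#' `d(t) = L0 + A (1 - exp(-t / tau))`, sampled at `dt_s` intervals from the
#' pre-ablation frame (t = 0) to `T_s`, with additive Gaussian measurement
#' noise.
#'
#' @param recoil list with `L0_um, A_um, tau_s, dt_s, T_s, noise_sd_um`
#'   (e.g. `preset("control_late")$recoil`).
#' @param seed RNG seed.
#' @param orientation,stage optional labels carried on the trace.
#' @return object of class `recoil_trace`: list with `times_s`,
#'   `distances_um`, labels, and the generating parameters.
#' @export
simulate_recoil_trace <- function(recoil, seed = 1L,
                                  orientation = "ML", stage = "late") {
  stopifnot(recoil$dt_s > 0, recoil$T_s >= recoil$dt_s)
  t <- seq(0, recoil$T_s, by = recoil$dt_s)
  d <- recoil$L0_um + recoil$A_um * (1 - exp(-t / recoil$tau_s))
  if (recoil$noise_sd_um > 0) {
    set.seed(seed)
    d <- d + stats::rnorm(length(d), 0, recoil$noise_sd_um)
  }
  structure(list(times_s = t, distances_um = d,
                 edge_orientation_class = orientation, stage = stage,
                 params = recoil, seed = seed),
            class = "recoil_trace")
}

#' @export
print.recoil_trace <- function(x, ...) {
  cat(sprintf("<recoil_trace (%s, %s): %d samples, d0 = %.2f um>\n",
              x$edge_orientation_class, x$stage, length(x$times_s),
              x$distances_um[1]))
  invisible(x)
}

#' Write / read a ground-truth event table
#'
#' Truth tables (gap injections, division and rosette schedules) are plain
#' CSV, one row per event, and round-trip losslessly.
#'
#' @param truth a data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
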