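# Raster and table I/O plus pipeline orchestration and reporting.
#
# Conventions stamped into every output: 0-based pixel-centered
# coordinates, x = mediolateral axis, half-open regions, and a provenance
# line (config hash, seed, package version).

#' Read a TIFF image or stack
#'
#' Single- or multi-page TIFF; label images must be integer-typed (a
#' float-typed file read as labels is an explicit error). Intensity stacks
#' written by [write_image_stack()] are stored as 32-bit float in units of
#' a.u./65535 and are rescaled back on read.
#'
#' @param path TIFF file.
#' @param kind `"label"` or `"intensity"`.
#' @param pixel_size_um pixel size override; required (TIFF pixel-size
#'   metadata is not relied upon).
#' @return a matrix (single page) or list of matrices (stack), with
#'   attributes `pixel_size_um` and `kind`; page order is preserved.
#' @export
read_image_stack <- function(path, kind = c("intensity", "label"),
                             pixel_size_um = NULL) {
  kind <- match.arg(kind)
  if (is.null(pixel_size_um))
    stop("pixel_size_um must be supplied (no trusted pixel size in TIFF metadata)")
  if (kind == "label") {
    info <- attributes(tiff::readTIFF(path, info = TRUE))
    if (!is.null(info$bits.per.sample) && info$bits.per.sample > 16L)
      stop("float-typed label image: labels must be integer (8/16-bit)")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = (kind == "label"))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]
    if (kind == "label") {
      if (any(abs(m - round(m)) > 1e-6))
        stop("float-typed label image: labels must be integer")
      matrix(as.integer(round(m)), nrow(m), ncol(m))
    } else m * 65535
  })
  out <- if (length(pages) == 1L) pages[[1]] else pages
  attr(out, "pixel_size_um") <- pixel_size_um
  attr(out, "kind") <- kind
  out
}

#' Write a TIFF image or stack
#'
#' Labels are written as 16-bit unsigned integer; intensity images as
#' 32-bit float in units of a.u./65535 (lossless to float precision for the
#' a.u. ranges used here).
#'
#' @param images matrix or list of matrices (pages, in order).
#' @param path output file.
#' @param kind `"label"` or `"intensity"`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(images, path, kind = c("intensity", "label")) {
  kind <- match.arg(kind)
  if (!is.list(images)) images <- list(images)
  scaled <- lapply(images, function(m) {
    if (kind == "label") {
      if (max(m) > 65535L) stop("label exceeds 16-bit range")
      m / 65535
    } else m / 65535
  })
  bits <- if (kind == "label") 16L else 32L
  tiff::writeTIFF(scaled, path, bits.per.sample = bits)
  invisible(path)
}

provenance_line <- function(config, seed) {
  cfg_json <- jsonlite::toJSON(config[!vapply(config, is.function, logical(1))],
                               auto_unbox = TRUE, digits = NA, null = "null")
  sprintf("# epijunction %s | config %s | seed %s | 0-based pixel-centered coords, x = ML axis, half-open regions",
          as.character(utils::packageVersion("epijunction")),
          content_hash(as.character(cfg_json)), seed)
}

# write a CSV with a provenance comment header
write_stamped_csv <- function(df, path, config, seed) {
  con <- file(path, "w")
  writeLines(provenance_line(config, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Write a junction graph to JSON and its edge table to CSV
#'
#' @param graph a `junction_graph`.
#' @param json_path,csv_path output files (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_graph <- function(graph, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      vertices = graph$vertices, edges = graph$edges, cells = graph$cells,
      pixel_size_um = graph$pixel_size_um, ml_axis_deg = graph$ml_axis_deg,
      field_um = graph$field_um,
      convention = "0-based pixel-centered coordinates; x = ML axis"),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  if (!is.null(csv_path)) {
    ed <- graph$edges
    utils::write.csv(
      data.frame(id = ed$id, v1 = ed$v1, v2 = ed$v2, cell1 = ed$c1,
                 cell2 = ed$c2, length_um = ed$length_um,
                 angle_deg = ed$angle_deg),
      csv_path, row.names = FALSE)
  }
  invisible(c(json_path, csv_path))
}

#' Run configuration for the analysis pipeline
#'
#' @param preset_name generator preset driving the synthetic run.
#' @param seed base seed.
#' @param out_dir output directory (created if missing).
#' @param n_fields synthetic fields to generate and analyze.
#' @param stats which statistics to compute.
#' @param threshold_fraction gap detection threshold.
#' @return object of class `run_config`.
#' @export
run_config <- function(preset_name = "mutant_late", seed = 1L,
                       out_dir = tempfile("epijunction_run_"),
                       n_fields = 3L,
                       stats = c("polarity", "tcj", "gaps"),
                       threshold_fraction = 0.3) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1, n_fields >= 1L)
  structure(list(preset_name = preset_name, seed = as.integer(seed),
                 out_dir = out_dir, n_fields = as.integer(n_fields),
                 stats = stats, threshold_fraction = threshold_fraction),
            class = "run_config")
}

#' Run the generate-and-analyze pipeline
#'
#' Generates `n_fields` synthetic fields under the configured preset,
#' writes label/intensity TIFFs and truth CSVs, runs the requested static
#' statistics (planar polarity, TCJ ratios, gap detection/merging/
#' stratification/counts) and writes per-field tables plus a run summary
#' JSON. Every output carries the config hash, seed and package version;
#' a rerun with the same config is byte-identical.
#'
#' @param rc a [run_config()].
#' @return (invisibly) list with `summary` (per-field statistics) and
#'   `out_dir`.
#' @export
run_pipeline <- function(rc) {
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- preset(rc$preset_name, seed = rc$seed)
  fields <- vector("list", rc$n_fields)
  for (k in seq_len(rc$n_fields)) {
    seed_k <- rc$seed + k - 1L
    cfg_k <- cfg; cfg_k$seed <- seed_k
    mesh <- make_mesh(cfg$n_cells, cfg$field_um, seed = seed_k,
                      n_order4 = cfg$n_order4, n_order5 = cfg$n_order5,
                      min_edge_um = 1.1, pixel_size_um = cfg$pixel_size_um)
    ch <- render_channels(mesh, cfg_k)
    inj <- inject_gaps(mesh, ch, cfg_k)
    pfx <- file.path(rc$out_dir, sprintf("field%02d", k))
    write_image_stack(mesh$label_image, paste0(pfx, "_labels.tif"), "label")
    write_image_stack(inj$channels$AJ, paste0(pfx, "_AJ.tif"), "intensity")
    write_truth(inj$truth, paste0(pfx, "_truth.csv"))

    graph <- extract_graph(mesh$label_image, cfg$pixel_size_um)
    bg <- estimate_background(inj$channels$AJ, graph, seed = seed_k)
    res <- list(field = k, seed = seed_k, background = bg$value)
    if ("polarity" %in% rc$stats) {
      pol <- tryCatch(planar_polarity(inj$channels$AJ, graph, bg),
                      error = function(e) NULL)
      if (is.null(pol)) stop("stat 'polarity' failed: empty ML or AP bin")
      res$polarity_ratio <- pol$ratio
      write_stamped_csv(data.frame(ml_mean = pol$ml_mean, ap_mean = pol$ap_mean,
                                   ratio = pol$ratio, n_ml = pol$n_ml,
                                   n_ap = pol$n_ap),
                        paste0(pfx, "_polarity.csv"), cfg_k, seed_k)
    }
    if ("tcj" %in% rc$stats) {
      v3 <- graph$vertices$id[graph$vertices$order == 3L]
      ratios <- vapply(v3, function(v)
        tryCatch(tcj_ratio(inj$channels$AJ, graph, v, bg)$ratio,
                 error = function(e) NA_real_), numeric(1))
      tab <- data.frame(vertex_id = v3, ratio = ratios)
      write_stamped_csv(tab, paste0(pfx, "_tcj.csv"), cfg_k, seed_k)
      res$tcj_mean_ratio <- mean(ratios, na.rm = TRUE)
    }
    if ("gaps" %in% rc$stats) {
      gaps <- detect_gaps(inj$channels$AJ, graph, bg,
                          threshold_fraction = rc$threshold_fraction)
      merged <- merge_overlapping_gaps(gaps)
      strat <- stratify_gap_frequency(gaps, graph)
      gtab <- merged
      gtab$merged_from <- vapply(gtab$merged_from %||% as.list(gtab$id),
                                 function(v) paste(v, collapse = ";"),
                                 character(1))
      write_stamped_csv(as.data.frame(gtab), paste0(pfx, "_gaps.csv"),
                        cfg_k, seed_k)
      res$gap_count <- region_gap_count(merged)
      res$gap_fraction_3 <- strat[["3"]]
      res$gap_fraction_4 <- strat[["4"]]
      res$gap_fraction_5p <- strat[["5+"]]
    }
    fields[[k]] <- res
  }
  summary <- do.call(rbind, lapply(fields, function(x)
    as.data.frame(x[!vapply(x, is.null, logical(1))])))
  jsonlite::write_json(
    list(preset = rc$preset_name, seed = rc$seed,
         config_hash = content_hash(as.character(
           jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null"))),
         version = as.character(utils::packageVersion("epijunction")),
         threshold_fraction = rc$threshold_fraction,
         fields = summary),
    file.path(rc$out_dir, "run_summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(summary = summary, out_dir = rc$out_dir))
}

#' Summary report with figure-style box statistics
#'
#' Aggregates per-field statistics into a single JSON report and draws
#' box-and-whisker plots in the legend convention (boxes 25th-75th
#' percentile, whiskers 5th-95th, line at the median, plus at the mean).
#'
#' @param summary per-field data frame from [run_pipeline()].
#' @param out_dir output directory for `report.json` and `report.pdf`.
#' @return (invisibly) the report list (per-metric box statistics).
#' @export
make_report <- function(summary, out_dir = tempdir()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- setdiff(names(summary), c("field", "seed"))
  box_stats <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NULL)
    q <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    list(n = length(v), mean = mean(v), p5 = q[1], p25 = q[2],
         median = q[3], p75 = q[4], p95 = q[5])
  }
  report <- lapply(summary[metrics], box_stats)
  report <- report[!vapply(report, is.null, logical(1))]
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  grDevices::pdf(file.path(out_dir, "report.pdf"), width = 7, height = 5)
  on.exit(grDevices::dev.off())
  for (m in names(report)) {
    v <- summary[[m]][!is.na(summary[[m]])]
    r <- report[[m]]
    graphics::plot(NA, xlim = c(0.5, 1.5), ylim = range(v, 0), xaxt = "n",
                   xlab = "", ylab = m, main = m)
    graphics::rect(0.8, r$p25, 1.2, r$p75, col = "grey85")
    graphics::segments(1, r$p5, 1, r$p25)
    graphics::segments(1, r$p75, 1, r$p95)
    graphics::segments(0.8, r$median, 1.2, r$median, lwd = 2)
    graphics::points(1, r$mean, pch = 3)
    graphics::points(jitter(rep(1, length(v)), amount = 0.08), v, pch = 16,
                     cex = 0.6, col = "steelblue")
  }
  invisible(report)
}
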