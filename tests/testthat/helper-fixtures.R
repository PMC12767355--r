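# Shared fixtures, computed lazily and cached for the whole test run.
# Everything is generated in code; no stored data.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small mid-density mesh with engineered 4- and 5-cell vertices
small_mesh <- function() {
  fixture("small_mesh", function()
    make_mesh(50, 35, seed = 11, n_order4 = 8, n_order5 = 3, min_edge_um = 1.1))
}

# noise-free render of the small mesh with polarity 3 and enrichment 1.8
quiet_render <- function() {
  fixture("quiet_render", function() {
    mesh <- small_mesh()
    cfg <- generator_config(n_cells = 50, field_um = c(35, 35), seed = 11,
                            n_order4 = 8, n_order5 = 3,
                            polarity_factor = 3, tcj_enrichment = 1.8,
                            noise_sd = 0)
    list(mesh = mesh, cfg = cfg,
         channels = render_channels(mesh, cfg, noise = FALSE),
         truth_graph = as_junction_graph(mesh),
         graph = extract_graph(mesh$label_image, mesh$pixel_size_um))
  })
}

# run the full generate -> inject -> extract -> detect pipeline on one field
run_gap_field <- function(preset_name, seed) {
  cfg <- preset(preset_name, seed = seed)
  mesh <- make_mesh(cfg$n_cells, cfg$field_um, seed = seed,
                    n_order4 = cfg$n_order4, n_order5 = cfg$n_order5,
                    min_edge_um = 1.1, pixel_size_um = cfg$pixel_size_um)
  ch <- render_channels(mesh, cfg)
  inj <- inject_gaps(mesh, ch, cfg)
  graph <- extract_graph(mesh$label_image, mesh$pixel_size_um)
  bg <- estimate_background(inj$channels$AJ, graph, seed = seed)
  gaps <- detect_gaps(inj$channels$AJ, graph, bg)
  list(mesh = mesh, cfg = cfg, channels = inj$channels, truth = inj$truth,
       graph = graph, background = bg, gaps = gaps,
       merged = merge_overlapping_gaps(gaps))
}

# accumulate stratified gap fractions and region counts over seeded fields
accumulate_fields <- function(preset_name, seeds) {
  num <- c(0, 0, 0); den <- c(0, 0, 0); counts <- integer(0)
  for (seed in seeds) {
    r <- run_gap_field(preset_name, seed)
    strat <- stratify_gap_frequency(r$gaps, r$graph)
    cen <- junction_census(r$graph)
    ok <- !is.na(strat)
    num[ok] <- num[ok] + strat[ok] * cen[ok]
    den <- den + cen
    counts <- c(counts, region_gap_count(r$merged))
  }
  list(fractions = num / den, n = den, counts = counts)
}

# a compact movie used by unit tests (divisions, rosettes, area)
small_movie <- function() {
  fixture("small_movie", function() {
    cfg <- preset("mutant_movie", seed = 301)
    cfg$n_cells <- 120L
    cfg$field_um <- c(75, 75)
    cfg$division_rate_per_hour <- 0.15
    cfg$rosette_count <- 8L
    tl <- make_timelapse(cfg)
    list(tl = tl, graphs = movie_graphs(tl))
  })
}

# movie fixtures (shared across division / rosette / area criteria)
mutant_movies <- function(n = 5L) {
  fixture("mutant_movies", function() {
    lapply(seq_len(n), function(s) {
      tl <- make_timelapse(preset("mutant_movie", seed = 100 + s))
      list(tl = tl, graphs = movie_graphs(tl))
    })
  })
}

control_movies <- function(n = 5L) {
  fixture("control_movies", function() {
    lapply(seq_len(n), function(s) {
      tl <- make_timelapse(preset("control_movie", seed = 200 + s))
      list(tl = tl, graphs = movie_graphs(tl))
    })
  })
}

# division scoring pooled over movies
score_divisions <- function(movies) {
  rows <- lapply(movies, function(m) track_divisions(m$tl))
  do.call(rbind, rows)
}

score_rosettes <- function(movies) {
  rows <- lapply(movies, function(m)
    rosette_gap_fates(track_rosettes(m$graphs), m$tl))
  do.call(rbind, lapply(rows, function(r) r[, c("id", "first_frame", "gap_fate",
                                               "formation_mode")]))
}

expect_within_3se <- function(observed, expected, n, info = NULL) {
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), 3 * se + 1e-12,
            label = paste0(info, ": |", round(observed, 4), " - ", expected,
                           "| vs 3SE = ", round(3 * se, 4)))
}
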