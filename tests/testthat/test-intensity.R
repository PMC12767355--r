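# Intensity statistics: background, edge means, planar polarity, TCJ
# enrichment, line profiles, mitotic index, cohort aggregation.

test_that("background estimation recovers a constant and the render level", {
  qr <- quiet_render()
  const <- matrix(7.5, nrow(qr$channels$AJ), ncol(qr$channels$AJ))
  bg1 <- estimate_background(const, qr$graph, seed = 1)
  expect_equal(bg1$value, 7.5)
  expect_gte(bg1$n_rois, 20)
  expect_lte(bg1$n_rois, 40)
  bg2 <- estimate_background(qr$channels$AJ, qr$graph, seed = 2)
  expect_equal(bg2$value, qr$cfg$background_level, tolerance = 1e-9)
  bg3 <- estimate_background(qr$channels$AJ, qr$graph, seed = 2)
  expect_identical(bg2$value, bg3$value)  # deterministic for a fixed seed
})

test_that("edge mean intensity matches a brute-force pixel enumeration oracle", {
  qr <- quiet_render()
  img <- qr$channels$AJ
  px <- qr$graph$pixel_size_um
  ids <- head(order(-qr$truth_graph$edges$length_um), 5)
  for (i in ids) {
    pl <- qr$truth_graph$polylines[[i]]
    got <- edge_mean_intensity(img, pl, px, line_width_um = 0.5)
    # oracle: scan every pixel in the image for distance to the chord
    nr <- nrow(img); nc <- ncol(img)
    pxx <- (rep(seq_len(nc), each = nr) - 0.5) * px
    pyy <- (rep(seq_len(nr), times = nc) - 0.5) * px
    d <- epijunction:::dist_to_segment(pxx, pyy, pl[1, ], pl[2, ])
    expect_equal(got, mean(img[d <= 0.25]), tolerance = 1e-12)
    # invariant to polyline point order
    expect_equal(edge_mean_intensity(img, pl[2:1, ], px, 0.5), got)
  }
  # uniform image -> that value
  u <- matrix(3, nrow(img), ncol(img))
  expect_equal(edge_mean_intensity(u, qr$truth_graph$polylines[[ids[1]]], px), 3)
})

test_that("planar polarity is exact on noise-free renders and scale-invariant", {
  qr <- quiet_render()
  bg <- qr$cfg$background_level
  pol <- planar_polarity(qr$channels$AJ, qr$truth_graph, bg)
  expect_equal(pol$ratio, 3, tolerance = 1e-9)
  # via the extracted graph as well
  polx <- planar_polarity(qr$channels$AJ, qr$graph, bg)
  expect_equal(polx$ratio, 3, tolerance = 0.05)
  # scale invariance: c * (I - bg) + bg leaves the ratio unchanged
  img2 <- (qr$channels$AJ - bg) * 2.7 + bg
  pol2 <- planar_polarity(img2, qr$truth_graph, bg)
  expect_equal(pol2$ratio, pol$ratio, tolerance = 1e-9)
  # uniform junctional intensity -> ratio 1
  cfg1 <- qr$cfg; cfg1$polarity_factor <- 1
  ch1 <- render_channels(qr$mesh, cfg1, noise = FALSE)
  expect_equal(planar_polarity(ch1$AJ, qr$truth_graph, bg)$ratio, 1,
               tolerance = 1e-9)
})

test_that("polarity recovery holds under noise across factors 1, 1.5, 3", {
  for (pf in c(1, 1.5, 3)) {
    ratios <- vapply(1:6, function(seed) {
      mesh <- make_mesh(50, 35, seed = seed, n_order4 = 8, n_order5 = 3,
                        min_edge_um = 1.1)
      cfg <- generator_config(n_cells = 50, field_um = c(35, 35), seed = seed,
                              polarity_factor = pf, noise_sd = 4)
      ch <- render_channels(mesh, cfg)
      g <- as_junction_graph(mesh)
      bg <- estimate_background(ch$AJ, extract_graph(mesh$label_image, 0.25),
                                seed = seed)
      planar_polarity(ch$AJ, g, bg)$ratio
    }, numeric(1))
    se <- stats::sd(ratios) / sqrt(length(ratios))
    expect_lt(abs(mean(ratios) - pf), 3 * se + 0.02)
  }
})

test_that("zero_polarity preset reads as unpolarized", {
  cfg <- preset("zero_polarity", seed = 21)
  mesh <- make_mesh(cfg$n_cells, cfg$field_um, seed = 21,
                    n_order4 = cfg$n_order4, n_order5 = cfg$n_order5,
                    min_edge_um = 1.1)
  ch <- render_channels(mesh, cfg)
  g <- as_junction_graph(mesh)
  pol <- planar_polarity(ch$AJ, g, cfg$background_level)
  expect_equal(pol$ratio, 1, tolerance = 0.05)
})

test_that("TCJ ratio: identity at equal intensities, exact enrichment recovery", {
  qr <- quiet_render()
  bg <- qr$cfg$background_level
  # enrichment 1 -> ratio 1 regardless of background level
  cfg1 <- qr$cfg; cfg1$tcj_enrichment <- 1; cfg1$polarity_factor <- 1
  ch1 <- render_channels(qr$mesh, cfg1, noise = FALSE)
  v3 <- qr$truth_graph$vertices$id[qr$truth_graph$vertices$order == 3]
  r1 <- vapply(v3, function(v)
    tryCatch(tcj_ratio(ch1$AJ, qr$truth_graph, v, bg)$ratio,
             error = function(e) NA_real_), numeric(1))
  expect_true(all(abs(stats::na.omit(r1) - 1) < 1e-9))
  # enrichment 1.8 with unit polarity -> exactly 1.8
  cfg2 <- qr$cfg; cfg2$tcj_enrichment <- 1.8; cfg2$polarity_factor <- 1
  ch2 <- render_channels(qr$mesh, cfg2, noise = FALSE)
  r2 <- vapply(v3, function(v)
    tryCatch(tcj_ratio(ch2$AJ, qr$truth_graph, v, bg)$ratio,
             error = function(e) NA_real_), numeric(1))
  expect_gt(sum(!is.na(r2)), 5)
  expect_true(all(abs(stats::na.omit(r2) - 1.8) < 1e-9))
  # higher-order vertices are rejected for this statistic
  v5 <- qr$truth_graph$vertices$id[qr$truth_graph$vertices$order >= 5][1]
  expect_error(tcj_ratio(ch2$AJ, qr$truth_graph, v5, bg), "order")
})

test_that("line profiles are max-normalized, symmetric, and bilinear-exact", {
  px <- 0.25
  img <- matrix(10, 80, 80)
  # vertical ridge at x = 10 um with a Gaussian cross-section
  xs <- (seq_len(80) - 0.5) * px
  for (cc in seq_len(80)) img[, cc] <- 10 + 100 * exp(-(xs[cc] - 10)^2 / 0.5)
  pr <- line_profile(img, c(10, 10), 0, length_um = 3, n_samples = 31,
                     background = 10, pixel_size_um = px)
  expect_true(attr(pr, "normalized"))
  expect_equal(max(pr$intensity), 1)
  expect_equal(pr$intensity[16], 1, tolerance = 1e-6)  # peak at the center
  expect_equal(pr$intensity, rev(pr$intensity), tolerance = 1e-6)
  # bilinear oracle at arbitrary sample points
  got <- epijunction:::bilinear_sample(img, c(10.13, 9.7), c(10.4, 10.1), px)
  for (k in 1:2) {
    x <- c(10.13, 9.7)[k]; y <- c(10.4, 10.1)[k]
    cc <- x / px + 0.5; rr <- y / px + 0.5
    c0 <- floor(cc); r0 <- floor(rr); fc <- cc - c0; fr <- rr - r0
    oracle <- img[r0, c0] * (1 - fr) * (1 - fc) + img[r0 + 1, c0] * fr * (1 - fc) +
      img[r0, c0 + 1] * (1 - fr) * fc + img[r0 + 1, c0 + 1] * fr * fc
    expect_equal(got[k], oracle, tolerance = 1e-12)
  }
  # all-background line is flagged and returned unnormalized
  flat <- matrix(5, 40, 40)
  pr2 <- line_profile(flat, c(5, 5), 45, background = 5, pixel_size_um = px)
  expect_false(attr(pr2, "normalized"))
})

test_that("mitotic index counts marked nuclei over cells in the region", {
  g <- quiet_render()$graph
  reg <- region_spec(c(0, 0), 35)
  expect_equal(mitotic_index(NULL, g, reg), 0)
  cells <- g$cells[epijunction:::in_region(g$cells$x, g$cells$y, reg), ]
  all_marked <- cbind(cells$x, cells$y)
  expect_equal(mitotic_index(all_marked, g, reg), 1)
  ten <- all_marked[1:10, ]
  expect_equal(mitotic_index(ten, g, reg), 10 / nrow(cells))
  expect_error(mitotic_index(ten, g, region_spec(c(500, 500), 10)), "no cells")
})

test_that("cohort summary aggregates region -> embryo -> cohort", {
  # one value per embryo: cohort mean is the plain mean
  s1 <- cohort_summary(c(1, 2, 3), c("a", "b", "c"))
  expect_equal(s1$cohort_mean, 2)
  expect_equal(s1$dispersion_value, stats::sd(1:3) / sqrt(3))
  # equal group sizes: equals the pooled mean
  v <- c(1, 3, 2, 4, 3, 5)
  s2 <- cohort_summary(v, rep(c("a", "b", "c"), each = 2))
  expect_equal(s2$cohort_mean, mean(v))
  # SEM vs SD against the textbook formulas
  per <- tapply(v, rep(c("a", "b", "c"), each = 2), mean)
  expect_equal(cohort_summary(v, rep(c("a", "b", "c"), each = 2), "sd")$dispersion_value,
               stats::sd(per))
  # unbalanced groups weight embryos, not regions
  s3 <- cohort_summary(c(0, 0, 0, 6), c("a", "a", "a", "b"))
  expect_equal(s3$cohort_mean, 3)
})
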