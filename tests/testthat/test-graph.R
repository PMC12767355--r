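# Junction graph extraction and geometric morphometrics.

test_that("a 2x2 four-label block yields one order-4 vertex", {
  lab <- matrix(0L, 20, 20)
  lab[1:10, 1:10] <- 1L; lab[11:20, 1:10] <- 2L
  lab[1:10, 11:20] <- 3L; lab[11:20, 11:20] <- 4L
  g <- extract_graph(lab, 0.25)
  expect_equal(nrow(g$vertices), 1L)
  expect_equal(g$vertices$order, 4L)
  expect_equal(c(g$vertices$x, g$vertices$y), c(2.5, 2.5), tolerance = 0.3)
})

test_that("extraction recovers the generator's census and vertex orders", {
  mesh <- small_mesh()
  g <- extract_graph(mesh$label_image, mesh$pixel_size_um)
  gt <- as_junction_graph(mesh)
  expect_equal(as.numeric(junction_census(g)),
               as.numeric(junction_census(gt)), tolerance = 0.06)
  # matched vertices agree in position and (almost always) in order
  d <- sqrt(outer(gt$vertices$x, g$vertices$x, "-")^2 +
            outer(gt$vertices$y, g$vertices$y, "-")^2)
  nn <- apply(d, 1, which.min)
  dm <- d[cbind(seq_len(nrow(gt$vertices)), nn)]
  expect_lt(stats::median(dm), 0.3)
  agree <- mean(gt$vertices$order == g$vertices$order[nn], na.rm = TRUE)
  expect_gte(agree, 0.9)
})

test_that("extraction is idempotent and structurally invariant to label permutation", {
  mesh <- small_mesh()
  g1 <- extract_graph(mesh$label_image, mesh$pixel_size_um)
  g2 <- extract_graph(mesh$label_image, mesh$pixel_size_um)
  expect_identical(g1$vertices, g2$vertices)
  expect_identical(g1$edges, g2$edges)
  # permute labels
  perm <- sample(seq_along(mesh$labels))
  lab2 <- mesh$label_image
  lab2[mesh$label_image > 0L] <- perm[mesh$label_image[mesh$label_image > 0L]]
  g3 <- extract_graph(lab2, mesh$pixel_size_um)
  expect_equal(nrow(g3$vertices), nrow(g1$vertices))
  expect_equal(sort(g3$vertices$order), sort(g1$vertices$order))
  expect_equal(nrow(g3$cells), nrow(g1$cells))
  # edge structure maps through the permutation
  k1 <- sort(paste(pmin(perm[g1$edges$c1], perm[g1$edges$c2]),
                   pmax(perm[g1$edges$c1], perm[g1$edges$c2])))
  k3 <- sort(paste(g3$edges$c1, g3$edges$c2))
  expect_identical(k1, k3)
})

test_that("single-cell and non-integer images are handled", {
  expect_warning(g <- extract_graph(matrix(1L, 10, 10), 0.25), "empty graph")
  expect_equal(nrow(g$vertices), 0L)
  expect_error(extract_graph(matrix(runif(100), 10, 10), 0.25), "integer")
})

test_that("angle folding matches a brute-force atan2 oracle", {
  set.seed(42)
  for (i in 1:50) {
    p <- matrix(runif(4, 0, 10), 2, 2)
    a <- edge_angle(p)
    raw <- atan2(p[2, 2] - p[1, 2], p[2, 1] - p[1, 1]) * 180 / pi
    oracle <- abs(raw) %% 180
    if (oracle > 90) oracle <- 180 - oracle
    expect_equal(a, oracle, tolerance = 1e-9)
    expect_equal(edge_angle(p[2:1, ]), a, tolerance = 1e-9)  # reversal
  }
  expect_equal(edge_angle(rbind(c(0, 0), c(1, 0))), 0)
  expect_equal(edge_angle(rbind(c(0, 0), c(-1, 1))), 45)  # 135 folds to 45
  expect_warning(a0 <- edge_angle(rbind(c(1, 1), c(1, 1))), "zero-length")
  expect_true(is.na(a0))
})

test_that("junction census sums to the vertex count and empty regions are zero", {
  g <- quiet_render()$graph
  cen <- junction_census(g)
  expect_equal(sum(cen), nrow(g$vertices))
  empty <- junction_census(g, region_spec(c(1000, 1000), 10))
  expect_equal(as.numeric(empty), c(0, 0, 0))
})

test_that("cell areas match the shoelace oracle and respect the region", {
  mesh <- small_mesh()
  gt <- as_junction_graph(mesh)
  reg <- region_spec(c(5, 5), 25)
  st <- cell_area_stats(gt, reg)
  # oracle: shoelace areas of non-border cells with centroid in the region
  oracle <- vapply(seq_along(mesh$polys), function(k) {
    p <- mesh$coords[mesh$polys[[k]], , drop = FALSE]
    epijunction:::polygon_area(p)
  }, numeric(1))
  sel <- match(st$areas$label, gt$cells$label)
  expect_equal(st$areas$area_um2, oracle[sel], tolerance = 1e-9)
  expect_lte(sum(st$areas$area_um2), 25 * 25 + 1e-9)
  expect_equal(st$mean_um2, mean(oracle[sel]))
  # pixel-based areas agree with polygon truth within raster tolerance
  gx <- extract_graph(mesh$label_image, mesh$pixel_size_um)
  common <- intersect(gx$cells$label, gt$cells$label[!gt$cells$border])
  a_pix <- gx$cells$area_um2[match(common, gx$cells$label)]
  a_true <- gt$cells$area_um2[match(common, gt$cells$label)]
  expect_equal(a_pix, a_true, tolerance = 0.08)
})

test_that("tissue profile metrics: spans, ratio and height", {
  line1 <- cbind(seq(0, 10, length.out = 21), 0)
  line2 <- cbind(seq(0, 10, length.out = 15), 3)
  m <- tissue_profile_metrics(line1, line2, 0.5)
  expect_equal(m$apical_span, 10)
  expect_equal(m$basal_span, 10)
  expect_equal(m$span_ratio, 1)
  expect_equal(m$cell_height, 3)
  # identical polylines -> ratio 1, height 0
  m2 <- tissue_profile_metrics(line1, line1)
  expect_equal(m2$span_ratio, 1)
  expect_equal(m2$cell_height, 0)
  # arc length matches the segment-sum oracle on a random polyline
  set.seed(9)
  pl <- cbind(cumsum(runif(10)), cumsum(rnorm(10)))
  m3 <- tissue_profile_metrics(pl, line1)
  expect_equal(m3$apical_span, sum(sqrt(diff(pl[, 1])^2 + diff(pl[, 2])^2)))
  # curved apical over straight basal: ratio = arc ratio
  expect_equal(m3$span_ratio, m3$apical_span / 10)
})
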