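# Gap detection, merging, stratification and AJ-TJ association.

make_gap_table <- function(x, y, r, order_class = "3") {
  out <- data.frame(id = seq_along(x), x = x, y = y, radius_um = r,
                    order_class = rep_len(order_class, length(x)),
                    vertex_id = seq_along(x), score = rep(0, length(x)))
  out$area_um2 <- pi * out$radius_um^2
  class(out) <- c("gap_table", "data.frame")
  out
}

test_that("minimum enclosing circle: analytic cases and a sampled-boundary oracle", {
  # two unit circles with centers 1 apart -> radius 1.5 on the midline
  m <- min_enclosing_circle(rbind(c(0, 0), c(1, 0)), c(1, 1))
  expect_equal(m$radius, 1.5, tolerance = 1e-9)
  expect_equal(m$center, c(0.5, 0), tolerance = 1e-9)
  # one circle containing the other -> the big one
  m2 <- min_enclosing_circle(rbind(c(0, 0), c(0.5, 0)), c(2, 0.3))
  expect_equal(m2$radius, 2)
  # random cases vs an oracle on densely sampled boundary points
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(2:4, 1)
    ctr <- matrix(runif(2 * n, 0, 10), n, 2)
    rr <- runif(n, 0.2, 2)
    m3 <- min_enclosing_circle(ctr, rr)
    th <- seq(0, 2 * pi, length.out = 720)
    bx <- as.vector(t(outer(ctr[, 1], rep(1, 720)) + outer(rr, cos(th))))
    by <- as.vector(t(outer(ctr[, 2], rep(1, 720)) + outer(rr, sin(th))))
    # oracle radius: minimax over a grid refined around the solver center
    dmax <- function(p) max(sqrt((bx - p[1])^2 + (by - p[2])^2))
    o <- stats::optim(m3$center + 0.3, dmax, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    expect_lte(m3$radius, o$value * 1.005 + 1e-9)
    expect_gte(m3$radius, o$value * 0.995 - 1e-9)
    # containment of every constituent circle
    dd <- sqrt((ctr[, 1] - m3$center[1])^2 + (ctr[, 2] - m3$center[2])^2)
    expect_true(all(dd + rr <= m3$radius + 1e-6))
  }
})

test_that("merging is idempotent, order-invariant, and containing", {
  g <- make_gap_table(c(0, 1, 1.8, 10, 10.5, 30), c(0, 0, 0, 10, 10, 30),
                      c(1, 1, 0.5, 0.8, 0.6, 1))
  m1 <- merge_overlapping_gaps(g)
  expect_equal(nrow(m1), 3L)  # chain of 3, pair, singleton
  m2 <- merge_overlapping_gaps(m1)
  expect_equal(m2$x, m1$x)
  expect_equal(m2$radius_um, m1$radius_um)
  # permutation of the input yields the same merged set
  perm <- c(4, 2, 6, 1, 5, 3)
  gp <- g[perm, ]; gp$id <- seq_len(6); gp$vertex_id <- seq_len(6)
  class(gp) <- c("gap_table", "data.frame")
  m3 <- merge_overlapping_gaps(gp)
  expect_equal(sort(round(m3$radius_um, 9)), sort(round(m1$radius_um, 9)))
  expect_equal(sort(round(m3$x, 9)), sort(round(m1$x, 9)))
  # every constituent circle is inside its merged circle
  for (i in seq_len(nrow(m1))) {
    members <- m1$merged_from[[i]]
    dd <- sqrt((g$x[members] - m1$x[i])^2 + (g$y[members] - m1$y[i])^2)
    expect_true(all(dd + g$radius_um[members] <= m1$radius_um[i] + 1e-6))
  }
  # two disjoint circles stay unchanged
  d0 <- make_gap_table(c(0, 5), c(0, 0), c(1, 1))
  expect_equal(nrow(merge_overlapping_gaps(d0)), 2L)
})

test_that("intact renders produce almost no false gaps", {
  fp <- 0; nv <- 0
  for (seed in 31:33) {
    cfg <- preset("mutant_late", seed = seed)
    cfg$gap_prob_by_order[] <- 0
    mesh <- make_mesh(cfg$n_cells, cfg$field_um, seed = seed,
                      n_order4 = cfg$n_order4, n_order5 = cfg$n_order5,
                      min_edge_um = 1.1)
    ch <- render_channels(mesh, cfg)
    inj <- inject_gaps(mesh, ch, cfg)
    expect_equal(nrow(inj$truth), 0L)  # probability 0 -> empty truth
    g <- extract_graph(mesh$label_image, mesh$pixel_size_um)
    bg <- estimate_background(inj$channels$AJ, g, seed = seed)
    gaps <- detect_gaps(inj$channels$AJ, g, bg)
    fp <- fp + nrow(gaps); nv <- nv + nrow(g$vertices)
  }
  expect_lt(fp / nv, 0.02)
})

test_that("an injected gap is recovered with the right class and radius", {
  cfg <- preset("mutant_late", seed = 44)
  cfg$noise_sd <- 0
  mesh <- make_mesh(cfg$n_cells, cfg$field_um, seed = 44,
                    n_order4 = cfg$n_order4, n_order5 = cfg$n_order5,
                    min_edge_um = 1.1)
  ch <- render_channels(mesh, cfg, noise = FALSE)
  vt <- epijunction:::mesh_vertices(mesh)
  v4 <- vt[!vt$border & vt$order == 4, ][1, ]
  r_true <- 0.6
  idx <- epijunction:::pixels_in_disk(v4$x, v4$y, r_true, 0.25, dim(ch$AJ))
  ch$AJ[idx] <- cfg$background_level
  g <- extract_graph(mesh$label_image, mesh$pixel_size_um)
  gaps <- detect_gaps(ch$AJ, g, cfg$background_level)
  expect_equal(nrow(gaps), 1L)
  expect_equal(gaps$order_class, "4")
  expect_lt(sqrt((gaps$x - v4$x)^2 + (gaps$y - v4$y)^2), 0.5)
  expect_lt(abs(gaps$radius_um - r_true), 0.25 + 1e-9)  # within one pixel
})

test_that("an all-background image flags every vertex", {
  qr <- quiet_render()
  flat <- matrix(qr$cfg$background_level, nrow(qr$channels$AJ),
                 ncol(qr$channels$AJ))
  # reference edge level from the real render, then score the blank image
  g <- qr$truth_graph
  bg <- qr$cfg$background_level
  med <- attr(detect_gaps(qr$channels$AJ, g, bg), "median_edge")
  gaps <- detect_gaps(flat, g, bg, median_edge = med)
  expect_equal(nrow(gaps), nrow(g$vertices))
})

test_that("probability 1 at order 3 voids every tricellular vertex", {
  cfg <- preset("mutant_late", seed = 45)
  cfg$gap_prob_by_order <- c("3" = 1, "4" = 0, "5" = 0)
  mesh <- make_mesh(cfg$n_cells, cfg$field_um, seed = 45,
                    n_order4 = cfg$n_order4, n_order5 = cfg$n_order5,
                    min_edge_um = 1.1)
  ch <- render_channels(mesh, cfg)
  inj <- inject_gaps(mesh, ch, cfg)
  vt <- epijunction:::mesh_vertices(mesh)
  expect_equal(nrow(inj$truth), sum(!vt$border & vt$order == 3))
  expect_true(all(inj$truth$junction_order == 3))
})

test_that("AJ-TJ association reproduces complement bookkeeping", {
  # geometric construction: TJ gaps inside the first k AJ circles
  build <- function(n_aj, n_assoc) {
    aj <- make_gap_table(x = 3 * seq_len(n_aj), y = rep(0, n_aj),
                         r = rep(0.8, n_aj))
    tj <- make_gap_table(x = 3 * seq_len(n_assoc) + 0.2, y = rep(0.1, n_assoc),
                         r = rep(0.3, n_assoc))
    associate_aj_tj(aj, tj)
  }
  a <- build(498, 56)
  expect_equal(unname(a$summary["n_associated"]), 56)
  expect_equal(unname(a$summary["n_unassociated"]), 442)
  b <- build(150, 9)
  expect_equal(unname(b$summary["n_unassociated"]), 141)
  expect_equal(sum(b$associations$tj_area_um2 == 0), 141)
  # no TJ gaps -> every AJ site scored zero
  c0 <- associate_aj_tj(make_gap_table(1:5, rep(0, 5), rep(0.5, 5)),
                        make_gap_table(numeric(0), numeric(0), numeric(0)))
  expect_true(all(c0$associations$tj_area_um2 == 0))
  expect_false(any(c0$associations$associated))
})

test_that("gap area distributions follow pi r^2 and include zero-scored TJ sites", {
  g <- make_gap_table(c(0, 10), c(0, 0), c(1, 2))
  d <- gap_area_distribution(g)
  expect_equal(d$areas_um2, pi * c(1, 4))
  expect_equal(d$mean_um2, mean(pi * c(1, 4)))
  # TJ distribution from associations keeps the zeros
  aj <- make_gap_table(c(0, 5, 10), c(0, 0, 0), c(1, 1, 1))
  tj <- make_gap_table(0.1, 0, 0.4)
  assoc <- associate_aj_tj(aj, tj)
  dt <- gap_area_distribution(assoc$associations)
  expect_equal(sort(dt$areas_um2), sort(c(pi * 0.16, 0, 0)), tolerance = 1e-9)
  # all-unassociated -> mean 0
  assoc0 <- associate_aj_tj(aj, make_gap_table(numeric(0), numeric(0), numeric(0)))
  expect_equal(gap_area_distribution(assoc0$associations)$mean_um2, 0)
})

test_that("region gap counts use the half-open box and the bicellular rule", {
  g <- make_gap_table(c(1, 5, 5, 9), c(1, 5, 5, 9), rep(0.4, 4),
                      order_class = c("3", "bicellular", "4", "5+"))
  expect_equal(region_gap_count(g), 3L)
  expect_equal(region_gap_count(g, exclude_bicellular = FALSE), 4L)
  reg <- region_spec(c(0, 0), 5)
  expect_equal(region_gap_count(g, reg), 1L)  # (5,5) is outside [0,5)
  reg2 <- region_spec(c(5, 5), 5)
  expect_equal(region_gap_count(g, reg2), 2L)  # (5,5) and (9,9) in [5,10)
  expect_equal(region_gap_count(make_gap_table(numeric(0), numeric(0),
                                               numeric(0))), 0L)
})
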