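# Synthetic mesh generator: geometry, determinism, conservation.

test_that("a 2x2 seed grid produces a central 4-cell vertex", {
  seeds <- rbind(c(5, 5), c(15, 5), c(5, 15), c(15, 15))
  mesh <- make_mesh(4, 20, seed = 1, relaxation_steps = 0, seeds = seeds)
  vt <- epijunction:::mesh_vertices(mesh)
  central <- vt[!vt$border, ]
  expect_equal(nrow(central), 1L)
  expect_equal(central$order, 4L)
  expect_equal(c(central$x, central$y), c(10, 10), tolerance = 1e-6)
})

test_that("mean apical area equals field area over n_cells", {
  mesh <- make_mesh(50, 100, seed = 3)
  areas <- vapply(mesh$polys, function(v)
    epijunction:::polygon_area(mesh$coords[v, , drop = FALSE]), numeric(1))
  expect_equal(mean(areas), 100 * 100 / 50, tolerance = 1e-6)
  expect_equal(sum(areas), 100 * 100, tolerance = 1e-6)
})

test_that("meshes are deterministic for a fixed seed", {
  m1 <- make_mesh(40, 40, seed = 7, n_order4 = 5, n_order5 = 2)
  m2 <- make_mesh(40, 40, seed = 7, n_order4 = 5, n_order5 = 2)
  expect_identical(m1$label_image, m2$label_image)
  expect_equal(m1$coords, m2$coords)
})

test_that("degenerate inputs are rejected", {
  expect_error(make_mesh(2, 50), "n_cells")
  expect_error(make_mesh(100, 0.5), "degenerate")
  expect_error(make_mesh(4, 3), "3x mean cell diameter")
})

test_that("Euler relation V - E + F = 2 holds across seeds and orders", {
  for (seed in 1:5) {
    mesh <- make_mesh(60, 40, seed = seed, n_order4 = 10, n_order5 = 4)
    expect_identical(mesh_euler_characteristic(mesh), 2L)
  }
})

test_that("requested higher-order vertex counts are realised", {
  # the clearance rule can veto individual contractions, so per-mesh counts
  # scatter around the request; the request is met on average and exactly
  # for the (sparser) 5-cell class
  n4 <- integer(0)
  for (s in 4:7) {
    mesh <- make_mesh(100, 50, seed = s, n_order4 = 25, n_order5 = 8,
                      min_edge_um = 1.1)
    vt <- epijunction:::mesh_vertices(mesh)
    int <- vt[!vt$border, ]
    n4 <- c(n4, sum(int$order == 4))
    expect_equal(sum(int$order >= 5), 8L)
    expect_lte(abs(sum(int$order == 4) - 25L), 6L)
  }
  expect_lte(abs(mean(n4) - 25), 3)
})

test_that("every cell label forms one connected raster component", {
  mesh <- small_mesh()
  lab <- mesh$label_image
  for (l in sample(mesh$labels, 10)) {
    idx <- which(lab == l)
    expect_gt(length(idx), 0)
    # simple BFS connectivity check on the label's pixels
    nr <- nrow(lab)
    seen <- idx[1]
    frontier <- idx[1]
    idxset <- idx
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, c(-1, 1, -nr, nr), "+")))
      nb <- setdiff(intersect(nb, idxset), seen)
      seen <- c(seen, nb)
      frontier <- nb
    }
    expect_equal(length(seen), length(idx))
  }
})
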