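test_that("alpha shape reproduces exact volumes of simple polytopes", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  a <- compute_alpha_shape(tet, alpha = 1000)
  expect_equal(a$volume, 1 / 6)
  expect_identical(a$n_tetrahedra, 1L)
  expect_identical(a$boundary_faces, 4L)
  # surface of the unit corner tetrahedron: 3 * 1/2 + sqrt(3)/2
  expect_equal(a$surface_area, 3 / 2 + sqrt(3) / 2)

  expect_identical(compute_alpha_shape(tet, alpha = 0)$volume, 0)

  expect_warning(out <- compute_alpha_shape(tet[1:3, ], alpha = 10),
                 "degenerate|fewer")
  expect_identical(out$volume, 0)
  coplanar <- cbind(matrix(runif(20), 10, 2), 0.5)
  expect_warning(out2 <- compute_alpha_shape(coplanar, alpha = 10),
                 "degenerate")
  expect_identical(out2$volume, 0)

  # the full Delaunay volume of a cube with interior points is the cube
  cube <- as.matrix(expand.grid(c(0, 10), c(0, 10), c(0, 10)))
  set.seed(51)
  inner <- matrix(runif(45, 0.5, 9.5), ncol = 3)
  expect_equal(compute_alpha_shape(rbind(cube, inner), alpha = 1e9)$volume,
               1000, tolerance = 1e-9)
})

test_that("alpha shape of a spherical shell point cloud approximates the ball", {
  set.seed(52)
  u <- matrix(rnorm(1500), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- round(u * 60)  # 500 points on a digital sphere of radius 60
  a <- compute_alpha_shape(pts, alpha = 240)
  expect_lt(abs(a$volume - 4 / 3 * pi * 60^3) / (4 / 3 * pi * 60^3), 0.10)

  # volume is monotone in alpha and saturates at the convex hull
  alphas <- c(10, 60, 100, 240, 1e6)
  vols <- vapply(alphas, function(al) compute_alpha_shape(pts, al)$volume,
                 numeric(1))
  expect_true(all(diff(vols) >= 0))
  expect_identical(compute_alpha_shape(pts, 1e9)$volume,
                   compute_alpha_shape(pts, 1e12)$volume)
})

test_that("cell graph matches the all-pairs oracle", {
  two <- rbind(c(0, 0, 0), c(0, 0, 59))
  g <- build_cell_graph(two)
  expect_identical(nrow(g$edges), 1L)
  expect_identical(length(g$outliers), 0L)

  apart <- rbind(c(0, 0, 0), c(0, 0, 61))
  g2 <- build_cell_graph(apart)
  expect_identical(sort(g2$outliers), c(1L, 2L))
  expect_identical(nrow(g2$edges), 0L)

  set.seed(53)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    pts <- matrix(runif(3 * n, 0, 150), ncol = 3)
    g <- build_cell_graph(pts, 60, 55)
    # all-pairs oracle: edges at distance <= 60; outliers are edge-less
    # nodes whose nearest neighbour is farther than 55
    dd <- as.matrix(dist(pts)); diag(dd) <- Inf
    e_ref <- matrix(integer(0), 0, 2)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a < b && dd[a, b] <= 60) e_ref <- rbind(e_ref, c(a, b))
    }
    connected <- unique(as.vector(e_ref))
    out_ref <- which(apply(dd, 1, min) > 55)
    out_ref <- setdiff(out_ref, connected)
    expect_identical(sort(g$outliers), sort(out_ref))
    expect_identical(g$edges[order(g$edges[, 1], g$edges[, 2]), ,
                             drop = FALSE],
                     e_ref, ignore_attr = TRUE)
  }
})

test_that("cell graph edges are symmetric, loop-free and stable under outlier removal", {
  set.seed(54)
  pts <- matrix(runif(90, 0, 120), ncol = 3)
  g <- build_cell_graph(pts, 60, 55)
  expect_true(all(g$edges[, 1] < g$edges[, 2]))  # no self loops, one per pair
  # outlier removal never removes edges between retained nodes
  g_all <- build_cell_graph(pts, 60, Inf)
  kept_edges <- g_all$edges[g_all$edges[, 1] %in% g$nodes &
                              g_all$edges[, 2] %in% g$nodes, , drop = FALSE]
  expect_identical(g$edges, kept_edges, ignore_attr = TRUE)
  # degree counts incident edges
  expect_identical(sum(g$degree), 2L * nrow(g$edges))
})

test_that("volume distributions summarise correctly", {
  rec <- data.frame(volume_um3 = c(1, 2, 3))
  d <- nuclei_volume_distribution(rec, binwidth = 1)
  expect_identical(d$median, 2)
  expect_identical(d$n, 3L)

  same <- data.frame(volume_um3 = rep(250, 9))
  d2 <- nuclei_volume_distribution(same, binwidth = 50)
  expect_identical(sum(d2$histogram$count > 0), 1L)
  expect_identical(sum(d2$histogram$count), 9L)

  expect_warning(d3 <- nuclei_volume_distribution(
    data.frame(volume_um3 = numeric(0))), "median undefined|no records")
  expect_true(is.na(d3$median))
})

test_that("phantom organoid median nucleus volume is recovered within 10%", {
  sp <- organoid_phantom_spec(n_nuclei = 12, noise_sd = 0, seed = 17,
                              psf_sigma_lateral = 1e-9, psf_sigma_axial = 1e-9,
                              shape = c(128, 128, 128), pitch_z = 0.654)
  ph <- generate_organoid_stack(sp)
  res <- segment_nuclei(ph$stack, pipeline_config())
  truth_med <- median(as.integer(table(ph$truth[ph$truth > 0]))) *
    sp$pitch_xy^3
  d <- nuclei_volume_distribution(res$records)
  expect_lt(abs(d$median - truth_med) / truth_med, 0.10)
})
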