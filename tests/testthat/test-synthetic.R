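test_that("bead phantom renders point sources at the requested positions", {
  # no beads: constant background
  sp0 <- bead_phantom_spec(n_beads = 0, noise_sd = 0, shape = c(10, 12, 12))
  b0 <- generate_bead_stack(sp0)
  expect_true(all(b0$stack$voxels == sp0$background))

  # one noiseless bead: voxel argmax within half a voxel of the true centre
  sp1 <- bead_phantom_spec(n_beads = 1, noise_sd = 0, seed = 5)
  b1 <- generate_bead_stack(sp1)
  am <- which(b1$stack$voxels == max(b1$stack$voxels), arr.ind = TRUE)[1, ]
  expect_true(all(abs(am - b1$centres[1, ]) <= 0.5 + 1e-9))

  # determinism: same seed, identical stacks
  spd <- bead_phantom_spec(seed = 9)
  expect_identical(generate_bead_stack(spd)$stack$voxels,
                   generate_bead_stack(spd)$stack$voxels)

  # explicit centres violating the separation rule are rejected
  sp2 <- bead_phantom_spec(n_beads = 2)
  expect_error(
    generate_bead_stack(sp2, centres = rbind(c(24, 40, 40), c(24, 40, 42))),
    "overlap")
})

test_that("bead phantom spec enforces its invariants", {
  expect_error(bead_phantom_spec(psf_sigma_lateral = 0), "sigma")
  expect_error(bead_phantom_spec(psf_sigma_lateral = 2, psf_sigma_axial = 1),
               "sigma")
  expect_error(bead_phantom_spec(n_beads = -1), "n_beads")
})

test_that("organoid ground-truth volumes match a brute-force inside test", {
  sp <- organoid_phantom_spec(n_nuclei = 1, noise_sd = 0, seed = 2,
                              shape = c(24, 64, 64))
  ph <- generate_organoid_stack(sp)
  expect_identical(sort(unique(as.integer(ph$truth[ph$truth > 0]))), 1L)
  # independent voxel-membership oracle over the whole grid
  d <- dim(ph$truth)
  pitches <- c(sp$pitch_z, sp$pitch_xy, sp$pitch_xy)
  c_um <- ph$centres[1, ] * pitches
  cnt <- 0L
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    q <- ((z * pitches[1] - c_um[1]) / sp$nucleus_semi_axes[1])^2 +
      ((y * pitches[2] - c_um[2]) / sp$nucleus_semi_axes[2])^2 +
      ((x * pitches[3] - c_um[3]) / sp$nucleus_semi_axes[3])^2
    if (q <= 1) cnt <- cnt + 1L
  }
  expect_identical(sum(ph$truth == 1L), cnt)
})

test_that("organoid phantom places the requested monolayer", {
  sp <- organoid_phantom_spec(seed = 4)
  ph <- generate_organoid_stack(sp)
  ids <- sort(unique(as.integer(ph$truth[ph$truth > 0])))
  expect_identical(ids, 1:50)

  # no two labels 26-adjacent: every voxel's 26-neighbourhood is single-label
  d <- dim(ph$truth)
  fg <- which(ph$truth > 0)
  zz <- ((fg - 1L) %% d[1]) + 1L
  yy <- (((fg - 1L) %/% d[1]) %% d[2]) + 1L
  xx <- ((fg - 1L) %/% (d[1] * d[2])) + 1L
  touching <- FALSE
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    jz <- zz + dz; jy <- yy + dy; jx <- xx + dx
    ok <- jz >= 1 & jz <= d[1] & jy >= 1 & jy <= d[2] & jx >= 1 & jx <= d[3]
    nb <- ph$truth[cbind(jz[ok], jy[ok], jx[ok])]
    if (any(nb > 0 & nb != ph$truth[fg][ok])) touching <- TRUE
  }
  expect_false(touching)

  # determinism
  expect_identical(generate_organoid_stack(sp)$truth, ph$truth)

  # nucleus volumes (isotropic voxel units) sit strictly inside the gate
  vol_iso <- as.integer(table(ph$truth[ph$truth > 0])) *
    (sp$pitch_z / sp$pitch_xy)
  expect_true(all(vol_iso > 500 & vol_iso < 18000))
  analytic <- 4 / 3 * pi * prod(sp$nucleus_semi_axes) / sp$pitch_xy^3
  expect_true(analytic > 500 && analytic < 18000)

  # detectability contract: nuclei exceed the lumen mean by >= 5 noise SDs
  lum_mask <- ph$truth == 0L
  expect_gt(mean(ph$stack$voxels[ph$truth > 0]) -
              mean(ph$stack$voxels[lum_mask]), 5 * sp$noise_sd)
})

test_that("infeasible organoid placement reports the achieved count", {
  sp <- organoid_phantom_spec(n_nuclei = 500, shell_radius = 12,
                              shape = c(24, 64, 64))
  expect_error(generate_organoid_stack(sp), "placed")
})

test_that("centroid matching is one-to-one and greedy-nearest", {
  ref <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  est <- rbind(c(10, 0, 1), c(1, 0, 0), c(50, 50, 50))
  m <- match_centroids(ref, est, max_dist = 3)
  expect_identical(nrow(m$matches), 2L)
  expect_identical(sort(m$matches$est), c(1L, 2L))
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$precision, 2 / 3)
  # each index used at most once
  expect_false(any(duplicated(m$matches$ref)))
  expect_false(any(duplicated(m$matches$est)))
})
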