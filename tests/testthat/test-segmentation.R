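test_that("median filter matches the per-voxel sort oracle", {
  v <- array(5, c(4, 4, 4))
  expect_equal(median_filter3d(v, 3), v)  # constant unchanged

  imp <- array(0, c(5, 5, 5)); imp[3, 3, 3] <- 100
  expect_true(all(median_filter3d(imp, 3) == 0))  # impulse removed

  set.seed(31)
  for (i in 1:20) {
    d <- sample(4:7, 3, replace = TRUE)
    v <- array(sample(0:20, prod(d), replace = TRUE), d)
    expect_identical(median_filter3d(v, 3), oracle_median3d(v, 3))
  }
  expect_error(median_filter3d(v, 0), ">= 1")
})

test_that("local threshold matches the brute-force window-mean oracle", {
  expect_false(any(local_threshold(array(3, c(6, 6, 6)), 2)))  # strict >

  # bright cube: mask contains the interior, is contained in cube + 1
  v <- array(0, c(20, 20, 20))
  v[7:14, 7:14, 7:14] <- 100
  m <- local_threshold(v, 10)
  inside <- array(FALSE, dim(v)); inside[8:13, 8:13, 8:13] <- TRUE
  dil <- array(FALSE, dim(v)); dil[6:15, 6:15, 6:15] <- TRUE
  expect_true(all(m[inside]))
  expect_true(all(which(m) %in% which(dil)))

  set.seed(32)
  for (i in 1:20) {
    d <- sample(5:8, 3, replace = TRUE)
    v <- array(runif(prod(d), 0, 50), d)
    r <- sample(1:3, 1)
    expect_identical(local_threshold(v, r), oracle_local_threshold(v, r))
  }
})

test_that("multiscale LoG detection finds one seed per blob", {
  expect_identical(nrow(detect_seeds_log(array(0, c(10, 10, 10)))$points), 0L)

  g1 <- function(n, c0, s) exp(-((seq_len(n) - c0)^2) / (2 * s^2))
  sig <- 10 / (2 * sqrt(2 * log(2)))  # FWHM-equivalent diameter 10 voxels
  blob <- 100 * outer(outer(g1(40, 20.3, sig), g1(40, 19.6, sig)),
                      g1(40, 21.2, sig))
  ss <- detect_seeds_log(blob, 8, 12)
  expect_identical(nrow(ss$points), 1L)
  expect_true(all(abs(ss$points[1, ] - c(20.3, 19.6, 21.2)) <= 1))
  expect_true(ss$scales >= 8 && ss$scales <= 12)

  two <- array(0, c(40, 40, 70))
  two[, , 1:40] <- blob
  two[, , 31:70] <- two[, , 31:70] + blob  # second blob 30 voxels away in x
  ss2 <- detect_seeds_log(two, 8, 12)
  expect_identical(nrow(ss2$points), 2L)

  expect_error(detect_seeds_log(blob, 12, 8), "range_min")
})

test_that("seed dilation paints digital balls with unique labels", {
  m <- dilate_seeds(matrix(c(10, 10, 10), 1), 3, c(20, 20, 20))
  expect_identical(sum(m > 0), 123L)  # lattice ball of radius 3
  expect_true(all(m %in% c(0L, 1L)))

  corner <- dilate_seeds(matrix(c(1, 1, 1), 1), 3, c(20, 20, 20))
  expect_lt(sum(corner > 0), 123L)

  none <- dilate_seeds(matrix(numeric(0), 0, 3), 3, c(5, 5, 5))
  expect_true(all(none == 0L))

  expect_error(dilate_seeds(rbind(c(5, 5, 5), c(5, 5, 9)), 3, c(20, 20, 20)),
               "closer than")
  expect_error(dilate_seeds(rbind(c(5, 5, 5), c(5, 5, 11)), 3, c(20, 20, 20)),
               "overlap")
})

test_that("watershed agrees exactly with the priority-flood oracle", {
  # two markers in disjoint mask components
  x <- array(1, c(4, 4, 8))
  mask <- array(TRUE, dim(x)); mask[, , 4:5] <- FALSE
  mk <- array(0L, dim(x)); mk[2, 2, 2] <- 1L; mk[2, 2, 7] <- 2L
  lab <- watershed_segment(x, mk, mask)
  expect_true(all(lab[, , 1:3] == 1L))
  expect_true(all(lab[, , 6:8] == 2L))
  expect_true(all(lab[, , 4:5] == 0L))

  # one marker labels exactly its connected mask component
  set.seed(41)
  mask <- array(runif(6^3) < 0.6, c(6, 6, 6))
  mask[3, 3, 3] <- TRUE
  mk <- array(0L, dim(mask)); mk[3, 3, 3] <- 1L
  lab <- watershed_segment(array(1, dim(mask)), mk, mask)
  ref <- oracle_watershed(array(1, dim(mask)), mk, mask)
  expect_identical(lab, ref)

  # random landscapes, markers and masks
  set.seed(42)
  for (i in 1:20) {
    cs <- random_watershed_case(sample(5:8, 3, replace = TRUE))
    if (sum(cs$markers > 0) == 0) next
    expect_identical(watershed_segment(cs$x, cs$markers, cs$mask),
                     oracle_watershed(cs$x, cs$markers, cs$mask))
  }

  mk_bad <- array(0L, c(3, 3, 3)); mk_bad[1, 1, 1] <- 1L
  expect_error(watershed_segment(array(1, c(3, 3, 3)), mk_bad,
                                 array(FALSE, c(3, 3, 3))),
               "marker outside mask")
})

test_that("volume gate applies strict bounds and relabels survivors", {
  lab <- label_map_with_volumes(c(400, 500, 501, 17999, 18000, 20000))
  out <- filter_by_volume(lab, 500, 18000)
  vols <- sort(as.integer(table(out$labels[out$labels > 0])))
  expect_identical(vols, c(501L, 17999L))
  expect_identical(sort(unique(as.integer(out$labels[out$labels > 0]))),
                   c(1L, 2L))
  expect_identical(sort(out$records$volume_voxels), c(501L, 17999L))

  empty <- filter_by_volume(array(0L, c(4, 4, 4)))
  expect_identical(nrow(empty$records), 0L)

  # all regions inside the gate: identity up to relabelling
  lab2 <- label_map_with_volumes(c(600, 1000))
  out2 <- filter_by_volume(lab2, 500, 18000)
  expect_identical(sum(out2$labels > 0), sum(lab2 > 0))

  # widening the gate never decreases the survivor count
  n_narrow <- nrow(filter_by_volume(lab, 500, 18000)$records)
  n_wide <- nrow(filter_by_volume(lab, 399, 20001)$records)
  expect_gte(n_wide, n_narrow)
})

test_that("segmentation recovers sharp-edged isotropic phantoms to voxel accuracy", {
  # isotropic, unblurred phantom isolates the geometric pipeline: volumes
  # must match the discretised ellipsoids within 10% (boundary voxels)
  sp <- organoid_phantom_spec(n_nuclei = 8, noise_sd = 0, seed = 13,
                              psf_sigma_lateral = 1e-9, psf_sigma_axial = 1e-9,
                              shape = c(128, 128, 128), pitch_z = 0.654)
  ph <- generate_organoid_stack(sp)
  res <- segment_nuclei(ph$stack, pipeline_config())
  expect_identical(nrow(res$records), 8L)
  truth_vol <- as.integer(table(ph$truth[ph$truth > 0]))
  m <- match_centroids(ph$centres,
                       as.matrix(res$records[, c("centroid_z", "centroid_y",
                                                 "centroid_x")]),
                       max_dist = 3)
  expect_identical(nrow(m$matches), 8L)
  seg_vol <- res$records$volume_voxels[m$matches$est]
  expect_true(all(abs(seg_vol - truth_vol[m$matches$ref]) /
                    truth_vol[m$matches$ref] <= 0.10))
})

test_that("segmenting a blank stack yields no labels", {
  blank <- image_stack(array(0, c(24, 24, 24)), 0.654, 0.654)
  res <- segment_nuclei(blank)
  expect_identical(nrow(res$records), 0L)
  expect_true(all(res$labels == 0L))
})
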