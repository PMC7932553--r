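geom128 <- acquisition_geometry(pixel_size_um = 1, n_slices = 1L,
                                field_um = 128)
par_def <- segmentation_params()

noisy_bg <- function(n = 128, level = 0.2, sd = 0.02, seed = 7) {
  set.seed(seed)
  matrix(pmax(0, level + rnorm(n * n, 0, sd)), n, n)
}

test_that("top-hat preprocessing flattens background and keeps small objects", {
  flat <- matrix(0.37, 64, 64)
  expect_true(all(preprocess_slice(flat, tiny_geom(64, 1L), par_def) == 0))

  sq <- matrix(0.1, 64, 64)
  sq[30:32, 40:42] <- 0.9
  out <- preprocess_slice(sq, tiny_geom(64, 1L), par_def)
  expect_equal(out[30:32, 40:42], matrix(0.8, 3, 3))
  expect_true(all(out[sq == 0.1] < 1e-12))

  # slowly varying illumination leaves residual far below the detection
  # threshold scale of a noisy slice
  grad <- outer(seq(0.1, 0.4, length.out = 128),
                seq(1, 1.5, length.out = 128))
  res <- preprocess_slice(grad, geom128, par_def)
  expect_lt(max(res), par_def$bright_z_min * mad(noisy_bg()))
})

test_that("crystal candidates: planted discs are recovered exactly, size gates hold", {
  expect_equal(nrow(detect_crystal_candidates(
    matrix(0, 64, 64), tiny_geom(64, 1L), par_def)$regions), 0L)

  sl <- noisy_bg()
  centers <- cbind(c(20, 20, 64, 100, 108), c(20, 100, 64, 30, 104))
  for (i in 1:5) sl <- add_disc(sl, centers[i, 1], centers[i, 2], 3, 0.5)
  rs <- detect_crystal_candidates(sl, geom128, par_def)
  expect_equal(nrow(rs$regions), 5L)
  planted_area <- sum((outer(-3:3, -3:3, function(a, b) a^2 + b^2)) <= 9)
  expect_true(all(abs(rs$regions$area_um2 - planted_area) <= 12))
  # detected centroids sit on the planted centres
  got <- rs$regions[order(rs$regions$centroid_y_px), ]
  want <- centers[order(centers[, 1]), ]
  expect_true(all(abs(got$centroid_y_px - want[, 1]) < 1))
  expect_true(all(abs(got$centroid_x_px - want[, 2]) < 1))

  big <- add_disc(noisy_bg(seed = 8), 64, 64, 8, 0.6)  # ~201 um2 > max
  expect_equal(nrow(detect_crystal_candidates(big, geom128,
                                              par_def)$regions), 0L)
})

test_that("detection is invariant to gain and equivariant to translation", {
  sl <- add_disc(add_disc(noisy_bg(seed = 9), 40, 40, 2, 0.5),
                 90, 70, 3, 0.55)
  base <- detect_crystal_candidates(sl, geom128, par_def)
  gain <- detect_crystal_candidates(3.7 * sl, geom128, par_def)
  expect_identical(gain$labels, base$labels)

  shifted <- matrix(median(sl), 128, 128)
  shifted[11:128, 6:128] <- sl[1:118, 1:123]
  sh <- detect_crystal_candidates(shifted, geom128, par_def)
  expect_equal(nrow(sh$regions), nrow(base$regions))
  expect_equal(sort(sh$regions$centroid_y_px),
               sort(base$regions$centroid_y_px) + 10)
  expect_equal(sort(sh$regions$centroid_x_px),
               sort(base$regions$centroid_x_px) + 5)
})

test_that("skin structure: papilla annuli are found and filled, speckle is not", {
  expect_equal(nrow(detect_skin_structure(
    matrix(0, 64, 64), tiny_geom(64, 1L), par_def)$regions), 0L)

  sl <- noisy_bg(seed = 10, level = 0.1)
  ring <- (outer((1:128) - 64, rep(1, 128)) ^ 2 +
           t(outer((1:128) - 64, rep(1, 128))) ^ 2)
  ring_mask <- ring <= 25^2 & ring >= 17^2
  sl[ring_mask] <- 0.45
  rs <- detect_skin_structure(sl, geom128, par_def)
  expect_equal(nrow(rs$regions), 1L)
  expect_gte(rs$regions$area_um2, par_def$structure_area_min_um2)
  cover <- sum(rs$labels > 0 & ring_mask) / sum(ring_mask)
  expect_gte(cover, 0.9)

  # sparse speckle (epidermal-confound density): smoothed blobs stay
  # below the structure area gate
  spk <- noisy_bg(seed = 11, level = 0.1)
  for (p in list(c(20, 20), c(20, 100), c(64, 60), c(100, 25),
                 c(110, 105))) {
    spk[p[1] + (-1:1), p[2] + (-1:1)] <- 0.6
  }
  expect_equal(nrow(detect_skin_structure(spk, geom128, par_def)$regions), 0L)
})

test_that("structure-free noise slices yield no structure despite Otsu", {
  rs <- detect_skin_structure(noisy_bg(seed = 13), geom128, par_def)
  expect_equal(nrow(rs$regions), 0L)
})

test_that("overlap exclusion removes exactly the structure-overlapping candidates", {
  sl <- noisy_bg(seed = 14, level = 0.1)
  sl <- add_disc(sl, 40, 40, 20, 0.4)    # structure disc
  sl <- add_disc(sl, 40, 40, 2, 0.8)     # confounder inside it
  sl <- add_disc(sl, 100, 100, 2, 0.8)   # isolated crystal
  sl <- add_disc(sl, 100, 20, 3, 0.8)    # isolated crystal
  cand <- detect_crystal_candidates(sl, geom128, par_def)
  struct <- detect_skin_structure(sl, geom128, par_def)
  expect_equal(nrow(struct$regions), 1L)
  iso <- exclude_structure(cand, struct, par_def)
  expect_identical(iso$kind, "isolated_crystal")
  # exactly the two isolated crystals survive; the in-structure
  # confounder (and any structure-rim artifact) is excluded
  expect_equal(nrow(iso$regions), 2L)
  expect_true(all(iso$regions$centroid_y_px > 90))
  # areas of survivors unchanged
  expect_setequal(iso$regions$area_um2,
                  cand$regions$area_um2[cand$regions$centroid_y_px > 90])
  # empty structure: identity up to kind
  none <- detect_skin_structure(matrix(0, 128, 128), geom128, par_def)
  none$slice_index <- cand$slice_index
  same <- exclude_structure(cand, none, par_def)
  expect_identical(same$labels, cand$labels)
  expect_equal(same$regions$area_um2, cand$regions$area_um2)
})

test_that("exclusion contract: matching slice and shape are required", {
  sl <- noisy_bg(seed = 15)
  cand <- detect_crystal_candidates(sl, geom128, par_def, slice_index = 3L)
  struct <- detect_skin_structure(sl, geom128, par_def, slice_index = 4L)
  expect_error(exclude_structure(cand, struct, par_def), "different slices")
  struct2 <- detect_skin_structure(matrix(0, 64, 64), tiny_geom(64, 1L),
                                   par_def, slice_index = 3L)
  expect_error(exclude_structure(cand, struct2, par_def), "shapes")
})

test_that("exclusion never increases count or total area (simulated slices)", {
  g <- small_geom(128)
  sim <- cached("seg_prop", simulate_stack(
    sim_config(geometry = g, n_crystals = 25, seed = 21)))
  for (k in c(18, 25, 32, 40, 48)) {
    sl <- sim$stack$voxels[, , k]
    cand <- detect_crystal_candidates(sl, g, par_def, k)
    struct <- detect_skin_structure(sl, g, par_def, k)
    iso <- exclude_structure(cand, struct, par_def)
    expect_lte(nrow(iso$regions), nrow(cand$regions))
    expect_lte(sum(iso$regions$area_um2), sum(cand$regions$area_um2))
  }
})

test_that("per-slice recall and precision reach 0.9 on simulator output", {
  g <- small_geom(160)
  sim <- cached("seg_recall", simulate_stack(
    sim_config(geometry = g, n_crystals = 30, seed = 31)))
  per <- sim$truth$per_crystal
  iso_truth <- per[!per$inside_structure, ]
  hits <- 0L
  n_det <- n_det_on_truth <- 0L
  for (k in sort(unique(iso_truth$slice))) {
    sl <- sim$stack$voxels[, , k]
    cand <- detect_crystal_candidates(sl, g, par_def, k)
    struct <- detect_skin_structure(sl, g, par_def, k)
    iso <- exclude_structure(cand, struct, par_def)
    # recall: a planted crystal is found if a detection centroid lies
    # within 2 px of its centre on its centre slice
    truth_k <- iso_truth[iso_truth$slice == k, ]
    for (j in seq_len(nrow(truth_k))) {
      d <- sqrt((iso$regions$centroid_y_px - truth_k$centroid_y_px[j])^2 +
                (iso$regions$centroid_x_px - truth_k$centroid_x_px[j])^2)
      if (any(d <= 2)) hits <- hits + 1L
    }
    # precision: a detection is true if it overlaps the planted mask
    # (crystals may also span neighbouring slices)
    cm <- sim$truth$crystal_mask[, , k]
    for (lab in iso$regions$label) {
      n_det <- n_det + 1L
      if (any(cm[iso$labels == lab])) n_det_on_truth <- n_det_on_truth + 1L
    }
  }
  expect_gte(hits / nrow(iso_truth), 0.9)    # recall
  expect_gte(n_det_on_truth / n_det, 0.9)    # precision
})

test_that("parameter validation rejects inconsistent gates", {
  expect_error(segmentation_params(crystal_area_min_um2 = 10,
                                   crystal_area_max_um2 = 5))
  expect_error(segmentation_params(bright_z_min = 0))
  expect_error(segmentation_params(crystal_area_max_um2 = 600))
})
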