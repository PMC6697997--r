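# Quantization, sub-volume extraction, plane averaging, lesion aggregation.

test_that("quantization spans the lesion range and clamps outside values", {
  v <- array(0, c(4, 4, 4))
  mask <- array(FALSE, c(4, 4, 4))
  mask[2:3, 2:3, 2:3] <- TRUE
  v[mask] <- seq(0, 10, length.out = sum(mask))
  b <- quantize_lesion(v, mask, 128)
  expect_identical(b[2, 2, 2], 1L)     # lesion minimum -> bin 1
  expect_identical(b[3, 3, 3], 128L)   # lesion maximum -> bin 128
  # out-of-mask voxels are binned with lesion edges and clamped
  v2 <- v
  v2[1, 1, 1] <- -5
  v2[4, 4, 4] <- 25
  b2 <- quantize_lesion(v2, mask, 128)
  expect_identical(b2[1, 1, 1], 1L)
  expect_identical(b2[4, 4, 4], 128L)
})

test_that("degenerate quantization inputs behave as specified", {
  v <- array(1, c(3, 3, 3))
  mask <- array(TRUE, c(3, 3, 3))
  expect_warning(b <- quantize_lesion(v, mask, 16), "constant")
  expect_true(all(b == 1L))
  expect_error(quantize_lesion(v, array(FALSE, c(3, 3, 3))), "empty")
})

test_that("sub-volume extraction clips at image faces without inventing data", {
  b <- array(seq_len(9 * 9 * 9), c(9, 9, 9))
  storage.mode(b) <- "integer"
  mid <- extract_subvolume(b, c(5, 5, 5), 5)
  expect_true(all(mid$valid))
  expect_identical(mid$values[3, 3, 3], b[5, 5, 5])
  face <- extract_subvolume(b, c(1, 5, 5), 5)
  expect_identical(sum(face$valid), 3L * 5L * 5L)  # 5x5x3 slab survives
  expect_true(all(is.na(face$values[!face$valid])))
  corner <- extract_subvolume(b, c(1, 1, 1), 5)
  expect_identical(sum(corner$valid), 27L)          # 3x3x3 octant
  expect_error(extract_subvolume(b, c(0, 5, 5), 5), "inside")
})

test_that("a constant sub-volume yields the textureless limits per voxel", {
  sub <- extract_subvolume(array(3L, c(9, 9, 9)), c(5, 5, 5), 5)
  f <- voxel_features(sub, texture_config(epsilon = 1e-8))
  expect_equal(unname(f), c(1e8, 0, 0))
})

test_that("voxel features average the three central directional planes", {
  # axial (first-axis) central plane is a checkerboard; the other two
  # central planes are constant stripes crossing it
  cube <- array(1L, c(5, 5, 5))
  checker <- matrix(1L + (outer(1:5, 1:5, "+") %% 2L), 5, 5)
  cube[3, , ] <- checker
  sub <- extract_subvolume(cube, c(3, 3, 3), 5)
  cfg <- texture_config(policy = "all-valid")
  f <- voxel_features(sub, cfg)
  fa <- ngtdm_features(checker, policy = "all-valid")
  # sagittal/coronal central planes hold one checker line each; compute them
  fc <- ngtdm_features(cube[, 3, ], policy = "all-valid")
  fs <- ngtdm_features(cube[, , 3], policy = "all-valid")
  expect_equal(f[["busyness"]],
               mean(c(fa[["busyness"]], fc[["busyness"]], fs[["busyness"]])),
               tolerance = 1e-12)
})

test_that("per-voxel triplets equal the mean of plane-wise recomputation", {
  set.seed(5)
  binned <- array(sample.int(12, 10 * 10 * 10, replace = TRUE), c(10, 10, 10))
  storage.mode(binned) <- "integer"
  cfg <- texture_config(policy = "all-valid")
  for (k in 1:10) {
    ctr <- sample(1:10, 3, replace = TRUE)
    sub <- extract_subvolume(binned, ctr, 5)
    got <- voxel_features(sub, cfg)
    planes <- list(sub$values[3, , ], sub$values[, 3, ], sub$values[, , 3])
    valids <- list(sub$valid[3, , ], sub$valid[, 3, ], sub$valid[, , 3])
    ref <- rowMeans(mapply(function(p, v) {
      p[!v] <- 1L
      ngtdm_features(p, v, policy = "all-valid")
    }, planes, valids))
    expect_equal(unname(got), unname(ref), tolerance = 1e-12)
  }
})

test_that("the compiled lesion path agrees with the R voxel path", {
  set.seed(31)
  les <- generate_lesion(phantom_config("benign"), seed = 31, id = "x")
  cfg <- texture_config()
  binned <- quantize_lesion(les$early, les$mask, cfg$n_bins)
  centers <- which(les$mask, arr.ind = TRUE)
  lf <- lesion_features(les$early, les$mask, cfg)
  idx <- sample(nrow(centers), 25)
  for (i in idx) {
    sub <- extract_subvolume(binned, centers[i, ], cfg$subvolume)
    expect_equal(unname(voxel_features(sub, cfg)),
                 unname(lf$voxel_features[i, ]), tolerance = 1e-12)
  }
})

test_that("lesion averaging is exact for uniform and two-voxel lesions", {
  # single-voxel lesion in a constant background
  v <- array(2, c(9, 9, 9))
  v[5, 5, 5] <- 10
  mask <- array(FALSE, c(9, 9, 9))
  mask[5, 5, 5] <- TRUE
  expect_warning(
    lf <- lesion_features(v, mask, texture_config(epsilon = 1e-8)),
    "constant")  # a one-voxel lesion has a degenerate intensity range
  expect_equal(lf$suvmax, 10)
  expect_identical(lf$n_voxels, 1L)
  # two-voxel lesion: lesion busyness is the mean of the per-voxel values
  mask2 <- mask
  mask2[5, 5, 6] <- TRUE
  set.seed(8)
  v2 <- array(rnorm(9^3, 5, 1), c(9, 9, 9))
  lf2 <- lesion_features(v2, mask2, texture_config())
  expect_equal(lf2$busyness, mean(lf2$voxel_features[, "busyness"]),
               tolerance = 1e-12)
  expect_equal(lf2$coarseness, mean(lf2$voxel_features[, "coarseness"]),
               tolerance = 1e-12)
})

test_that("lesion features are invariant to global affine SUV rescaling", {
  for (seed in 1:5) {
    kind <- if (seed %% 2 == 0) "benign" else "malignant"
    les <- generate_lesion(phantom_config(kind), seed = seed, id = "x")
    a <- runif(1, 0.5, 3)
    b <- runif(1, -2, 2)
    f0 <- lesion_features(les$early, les$mask)
    f1 <- lesion_features(les$early$data * a + b, les$mask)
    expect_equal(f0$busyness, f1$busyness, tolerance = 1e-12)
    expect_equal(f0$coarseness, f1$coarseness, tolerance = 1e-12)
    expect_equal(f0$contrast, f1$contrast, tolerance = 1e-12)
  }
})

test_that("benign-style phantoms are busier and less coarse than malignant", {
  fb <- with(generate_lesion(phantom_config("benign"), seed = 42, id = "b"),
             lesion_features(early, mask))
  fm <- with(generate_lesion(phantom_config("malignant"), seed = 42, id = "m"),
             lesion_features(early, mask))
  expect_gt(fb$busyness, fm$busyness)
  expect_lt(fb$coarseness, fm$coarseness)
})

test_that("voxels with fully clipped neighborhoods are counted, not imputed", {
  # a lesion hugging an image corner has voxels whose every central plane
  # loses its strict interior
  v <- array(rnorm(6^3, 5, 1), c(6, 6, 6))
  mask <- array(FALSE, c(6, 6, 6))
  mask[1:3, 1:3, 1:3] <- TRUE
  lf <- lesion_features(v, mask, texture_config(policy = "strict-interior"))
  expect_gte(lf$n_undefined, 0L)
  expect_identical(lf$n_voxels, 27L)
  defined <- !is.na(lf$voxel_features[, 1])
  expect_equal(lf$busyness, mean(lf$voxel_features[defined, "busyness"]),
               tolerance = 1e-12)
})
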