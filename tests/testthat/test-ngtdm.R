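# NGTDM construction and the three texture features on 2-D patches.

test_that("single-interior-pixel patch gives the hand-enumerated table", {
  patch <- matrix(c(1, 1, 1, 1, 2, 1, 1, 1, 1), 3, 3)
  tab <- build_ngtdm(patch)
  # only the center is eligible under strict interior; A = mean of 8 ones
  expect_identical(tab$n_considered, 1L)
  expect_equal(unname(tab$s[2]), 1)
  expect_equal(unname(tab$s[1]), 0)
  expect_equal(unname(tab$p[2]), 1)
  expect_identical(tab$levels_present, 2L)
  expect_equal(ngtdm_coarseness(tab, 1e-8), 1 / (1e-8 + 1))
  # a single gray level among considered pixels: contrast 0 by convention
  expect_identical(ngtdm_contrast(tab), 0)
  expect_identical(ngtdm_busyness(tab), 0)
})

test_that("constant patches are the textureless limit", {
  tab <- build_ngtdm(matrix(7L, 5, 5))
  expect_equal(sum(tab$s), 0)
  expect_equal(unname(tab$p[7]), 1)
  expect_identical(tab$n_gray_levels, 1L)
  expect_equal(ngtdm_coarseness(tab, 1e-8), 1e8)
  expect_identical(ngtdm_contrast(tab), 0)
  expect_identical(ngtdm_busyness(tab), 0)
  # the compiled feature path agrees
  f <- ngtdm_features(matrix(7L, 5, 5))
  expect_equal(unname(f), c(1e8, 0, 0))
})

test_that("coarseness strictly decreases when local differences grow", {
  set.seed(1)
  p <- random_patch(5, 5, bins = 8)
  tab <- build_ngtdm(p$vals, p$valid)
  doubled <- tab
  doubled$s <- tab$s * 2
  expect_lt(ngtdm_coarseness(doubled), ngtdm_coarseness(tab))
})

test_that("checkerboard is busier than a half-split patch", {
  checker <- matrix(1L + (outer(1:4, 1:4, "+") %% 2L), 4, 4)
  halves <- matrix(rep(c(1L, 1L, 2L, 2L), each = 4), 4, 4, byrow = TRUE)
  b_checker <- ngtdm_features(checker, policy = "all-valid")[["busyness"]]
  b_halves <- ngtdm_features(halves, policy = "all-valid")[["busyness"]]
  expect_gt(b_checker, b_halves)
  # agreement with the brute-force oracle on both patches
  all_ok <- matrix(TRUE, 4, 4)
  expect_equal(b_checker,
               oracle_features(oracle_ngtdm(checker, all_ok,
                                            policy = "all-valid"))[["busyness"]],
               tolerance = 1e-12)
  expect_equal(b_halves,
               oracle_features(oracle_ngtdm(halves, all_ok,
                                            policy = "all-valid"))[["busyness"]],
               tolerance = 1e-12)
})

test_that("random patches match the brute-force oracle under both policies", {
  set.seed(42)
  for (k in 1:100) {
    nr <- sample(3:7, 1)
    nc <- sample(3:7, 1)
    p <- random_patch(nr, nc, bins = sample(1:16, 1), p_valid = runif(1, 0.5, 1))
    for (policy in c("strict-interior", "all-valid")) {
      ref <- oracle_ngtdm(p$vals, p$valid, policy = policy)
      got <- ngtdm_features(p$vals, p$valid, policy = policy)
      expect_equal(unname(got), unname(oracle_features(ref)),
                   tolerance = 1e-10)
      if (ref$n > 0) {
        tab <- build_ngtdm(p$vals, p$valid, policy = policy)
        expect_equal(unname(tab$s), ref$s[seq_along(tab$s)], tolerance = 1e-12)
        expect_identical(tab$n_considered, ref$n)
        # R-level formula functions agree with the compiled triplet
        expect_equal(unname(got),
                     c(ngtdm_coarseness(tab), ngtdm_contrast(tab),
                       ngtdm_busyness(tab)),
                     tolerance = 1e-12)
      } else {
        expect_error(build_ngtdm(p$vals, p$valid, policy = policy),
                     class = "petngtdm_empty_ngtdm")
      }
    }
  }
})

test_that("coarseness and contrast are invariant under bin translation", {
  # translating all bins leaves s(i) and every (i - j) difference unchanged,
  # so coarseness and contrast are fixed; busyness is not (its denominator
  # weights probabilities by the absolute gray level i)
  set.seed(7)
  for (k in 1:20) {
    p <- random_patch(5, 5, bins = 8)
    for (policy in c("strict-interior", "all-valid")) {
      f0 <- ngtdm_features(p$vals, p$valid, policy = policy)
      f1 <- ngtdm_features(p$vals + 5L, p$valid, policy = policy)
      expect_equal(f1[["coarseness"]], f0[["coarseness"]], tolerance = 1e-12)
      expect_equal(f1[["contrast"]], f0[["contrast"]], tolerance = 1e-12)
    }
  }
})

test_that("features are finite and nonnegative on arbitrary valid input", {
  set.seed(99)
  for (k in 1:50) {
    p <- random_patch(sample(3:6, 1), sample(3:6, 1),
                      bins = sample(1:16, 1), p_valid = runif(1, 0.3, 1))
    f <- ngtdm_features(p$vals, p$valid, policy = "all-valid")
    if (anyNA(f)) next  # no eligible pixel: undefined is the contract
    expect_true(all(is.finite(f)))
    expect_true(all(f >= 0))
  }
})

test_that("coarseness and busyness move oppositely along a texture sweep", {
  # interpolate from a flat patch toward a checkerboard
  checker <- (outer(1:8, 1:8, "+") %% 2)
  amps <- c(0, 0.25, 0.5, 0.75, 1)
  feats <- sapply(amps, function(a) {
    patch <- matrix(1L + as.integer(round(a * 7 * checker)), 8, 8)
    ngtdm_features(patch)
  })
  expect_true(all(diff(feats["coarseness", ]) <= 1e-12))
  expect_true(all(diff(feats["busyness", ]) >= -1e-12))
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(build_ngtdm(matrix(1L, 3, 3), matrix(FALSE, 3, 3)),
               class = "petngtdm_empty_ngtdm")
  expect_error(build_ngtdm(matrix(0L, 3, 3)), "bin indices")
  expect_error(ngtdm_coarseness(build_ngtdm(matrix(1L, 3, 3)), epsilon = 0),
               "positive")
})
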