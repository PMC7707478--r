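test_that("white top-hat removes flat background and keeps small features", {
  expect_true(all(top_hat(matrix(57, 32, 32), 5) == 0))
  m <- matrix(0, 32, 32); m[15:17, 15:17] <- 200
  expect_identical(top_hat(m, 5), m)
  expect_error(top_hat(matrix(0, 20, 20), 10), "half the image")
})

test_that("top-hat equals image minus brute-force opening, and is bounded", {
  for (s in 1:5) {
    set.seed(s)
    img <- matrix(runif(16 * 16, 0, 255), 16, 16)
    th <- top_hat(img, 3)
    expect_equal(th, img - oracle_opening(img, 3), tolerance = 1e-12)
    expect_true(all(th >= -1e-12))
    expect_true(all(th <= img + 1e-12))
  }
})

test_that("vesselness vanishes on flat fields and peaks on ridge centerlines", {
  expect_true(all(hessian_vesselness(matrix(42, 40, 40)) == 0))
  n <- 33
  ridge <- outer(rep(1, n), 200 * exp(-((1:n) - 17)^2 / (2 * 1.5^2)))
  v <- hessian_vesselness(ridge, scales = 3)
  peaks <- apply(v[5:(n - 4), ], 1, which.max)
  expect_true(all(abs(peaks - 17) <= 1))
  # isotropy: transposing the image transposes the response
  set.seed(3)
  img <- matrix(runif(24 * 24, 0, 255), 24, 24)
  expect_equal(hessian_vesselness(t(img)), t(hessian_vesselness(img)),
               tolerance = 1e-8)
})

test_that("Huang threshold separates a two-level histogram", {
  img <- matrix(c(rep(30, 60), rep(200, 40)), 10, 10)
  t_star <- huang_threshold(img)
  expect_gte(t_star, 30)
  expect_lt(t_star, 200)
  expect_identical(sum(img > t_star), 40L)
  expect_error(huang_threshold(matrix(7, 8, 8)), "constant")
})

test_that("Huang threshold matches the exhaustive-candidate oracle and shifts with the data", {
  for (s in 1:10) {
    set.seed(s)
    img <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    expect_identical(huang_threshold(img), oracle_huang(img))
  }
  set.seed(99)
  img <- matrix(sample(20:200, 256, replace = TRUE), 16, 16)
  expect_identical(huang_threshold(img + 10), huang_threshold(img) + 10L)
})

test_that("median local threshold matches the brute-force window oracle", {
  expect_false(any(median_local_threshold(matrix(100, 20, 20), 3, 0)))
  z <- matrix(0, 11, 11); z[6, 6] <- 255
  expect_identical(which(median_local_threshold(z, 2, 0)), which(z == 255))
  for (s in 1:5) {
    set.seed(s)
    img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    expect_identical(median_local_threshold(img, 3, 0),
                     img > oracle_window_median(img, 3))
  }
})

test_that("mask combination follows set algebra", {
  set.seed(1)
  a <- matrix(runif(100) > 0.5, 10, 10)
  b <- matrix(runif(100) > 0.5, 10, 10)
  expect_identical(combine_masks(a, a, "AND"), a)
  expect_false(any(combine_masks(a, matrix(FALSE, 10, 10), "AND")))
  expect_identical(sum(combine_masks(a, b, "AND")), sum(a & b))
  expect_identical(sum(combine_masks(a, b, "OR")),
                   sum(a) + sum(b) - sum(a & b))
  expect_error(combine_masks(a, b[1:5, ]), "dimensions differ")
})

test_that("the dual-path chain records its steps and the AND mask is a subset of both paths", {
  gt <- generate_plexus_phantom(phantom_spec("SCP", image_size = 128, seed = 3))
  img <- simulate_acquisition(gt, noiseless())
  vm <- binarize_plexus(img)
  expect_s3_class(vm, "vessel_map")
  expect_identical(vapply(vm$method_chain, `[[`, "", "step"),
                   c("top_hat", "hessian_vesselness", "huang_threshold",
                     "median_local_threshold", "combine_masks"))
  expect_true(all(vm$mask <= vm$path_masks$vesselness))
  expect_true(all(vm$mask <= vm$path_masks$median_local))
  expect_gt(dice_overlap(vm$mask, gt$vessel_mask), 0.6)
  vm2 <- binarize_plexus(img)
  expect_identical(vm$mask, vm2$mask)
})

test_that("degenerate all-zero images fail in the Huang step", {
  img <- en_face_image(matrix(0, 64, 64), "SCP", "V1")
  expect_error(binarize_plexus(img), "constant")
  imgcc <- en_face_image(matrix(0, 64, 64), "CC", "V1")
  expect_error(binarize_plexus(imgcc), "SCP/DCP")
})
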