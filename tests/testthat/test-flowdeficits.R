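test_that("Phansalkar threshold has the closed form on constant fields", {
  img <- matrix(127.5, 40, 40)   # normalized value 0.5, sigma = 0
  flow <- phansalkar_threshold(img)
  t_expected <- 0.5 * (1 + 2 * exp(-5) - 0.25)
  expect_equal(attr(flow, "threshold")[20, 20], t_expected, tolerance = 1e-12)
  expect_true(all(flow))
  # an all-zero frame thresholds at 0 and nothing exceeds it: all void
  dark <- phansalkar_threshold(matrix(0, 40, 40))
  expect_false(any(dark))
  expect_true(all(attr(dark, "threshold") == 0))
})

test_that("Phansalkar matches the brute-force window-statistics oracle", {
  for (s in 1:5) {
    set.seed(s)
    img <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
    got <- phansalkar_threshold(img, phansalkar_params(radius = 3))
    ora <- oracle_phansalkar(img, 3)
    expect_identical(unclass(got)[, ], ora$mask)
    expect_equal(attr(got, "threshold"), ora$threshold, tolerance = 1e-12)
  }
})

test_that("raising k moves the flow mask according to local SD vs r", {
  set.seed(8)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  m1 <- phansalkar_threshold(img, phansalkar_params(radius = 3, k = 0.25))
  m2 <- phansalkar_threshold(img, phansalkar_params(radius = 3, k = 0.35))
  st <- octametrics:::cpp_local_stats_circle(pmin(pmax(img, 0), 255) / 255, 3)
  gained <- !m1 & m2
  lost <- m1 & !m2
  # threshold change is mu * dk * (sigma/r - 1): negative iff sigma < r
  expect_true(all(st$sd[gained] < 0.5))
  expect_true(all(st$sd[lost] > 0.5))
  # and the masks agree with thresholds recomputed per pixel
  expect_identical(unclass(m2)[, ], oracle_phansalkar(img, 3, k = 0.35)$mask)
})

test_that("particle analysis counts and measures void components", {
  full <- matrix(TRUE, 10, 10)
  r0 <- extract_flow_deficits(full)
  expect_identical(r0$n_deficits, 0L)
  expect_identical(r0$total_fd_percent, 0)
  one <- matrix(TRUE, 10, 10); one[3:7, 4:8] <- FALSE
  r1 <- extract_flow_deficits(one)
  expect_identical(r1$n_deficits, 1L)
  expect_identical(r1$total_fd_percent, 25)
  expect_equal(sum(r1$deficit_areas_percent), r1$total_fd_percent)
})

test_that("component labeling agrees with a flood-fill oracle", {
  for (s in 1:10) {
    set.seed(s)
    flow <- matrix(runif(24 * 24) > 0.45, 24, 24)
    r <- extract_flow_deficits(flow)
    areas <- oracle_component_areas(!flow)
    expect_identical(sort(r$deficit_areas_px), as.numeric(areas))
    expect_identical(r$n_deficits, length(areas))
    # partition: flow and voids tile the frame exactly
    expect_identical(r$flow_percent + r$total_fd_percent, 100)
  }
})

test_that("a size floor drops small deficits only", {
  flow <- matrix(TRUE, 20, 20)
  flow[2:3, 2:3] <- FALSE            # 4 px void
  flow[10:15, 10:15] <- FALSE        # 36 px void
  r <- extract_flow_deficits(flow, min_deficit_px = 10)
  expect_identical(r$n_deficits, 1L)
  expect_identical(r$deficit_areas_px, 36)
})

test_that("CC metrics recover the phantom void fraction and are deterministic", {
  gt <- generate_cc_phantom(phantom_spec("CC", image_size = 128, seed = 14))
  img <- simulate_acquisition(gt, noiseless())
  fd <- compute_cc_metrics(img)
  expect_lt(abs(fd$total_fd_percent - gt$true_fd), 10)
  fd2 <- compute_cc_metrics(img)
  expect_identical(fd$total_fd_percent, fd2$total_fd_percent)
  scp <- en_face_image(matrix(100, 64, 64), "SCP", "V1")
  expect_error(compute_cc_metrics(scp), "CC images")
})
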