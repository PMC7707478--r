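test_that("plexus phantoms hit the density target and are seed-deterministic", {
  sp <- phantom_spec("SCP", image_size = 128, capillary_density_target = 0.5,
                     seed = 11)
  gt <- generate_plexus_phantom(sp)
  expect_gte(gt$true_pd, 40)
  expect_lte(gt$true_pd, 60)
  gt2 <- generate_plexus_phantom(sp)
  expect_identical(gt$vessel_mask, gt2$vessel_mask)
  expect_identical(gt$clean_intensity, gt2$clean_intensity)
  # different seed gives a different network
  gt3 <- generate_plexus_phantom(phantom_spec("SCP", image_size = 128,
                                              capillary_density_target = 0.5,
                                              seed = 12))
  expect_gt(sum(gt$vessel_mask != gt3$vessel_mask), 0)
})

test_that("ground-truth scalars are self-consistent with the stored masks", {
  for (px in c("SCP", "DCP")) {
    gt <- generate_plexus_phantom(phantom_spec(px, image_size = 128, seed = 21))
    n <- length(gt$vessel_mask)
    expect_identical(gt$true_pd, 100 * sum(gt$vessel_mask) / n)
    expect_identical(gt$true_vld, 100 * sum(gt$centerline_mask) / n)
    expect_identical(gt$true_vdi, sum(gt$vessel_mask) / sum(gt$centerline_mask))
    expect_true(all(gt$centerline_mask <= gt$vessel_mask))
    expect_true(min(gt$clean_intensity) >= 0 && max(gt$clean_intensity) <= 255)
  }
  gt <- generate_cc_phantom(phantom_spec("CC", image_size = 128, seed = 21))
  expect_identical(gt$true_fd, 100 * sum(gt$void_mask) / length(gt$void_mask))
})

test_that("a straight tube of caliber 7 has ground-truth VDI near 7", {
  cv <- render_tubes(120, list(list(x = 1:120, y = rep(60, 120), radius = 3.5)))
  mask <- cv >= 0.5
  skel <- skeletonize(mask)
  vdi <- sum(mask) / sum(skel)
  expect_gt(vdi, 7 * 0.85)
  expect_lt(vdi, 7 * 1.15)
})

test_that("an unreachable density target fails loudly, naming both fractions", {
  sp <- phantom_spec("SCP", image_size = 64, capillary_density_target = 0.5,
                     vessel_caliber_range = c(0.05, 0.05),
                     n_large_vessels = 0, seed = 5)
  expect_error(generate_plexus_phantom(sp), "achieved.*requested")
})

test_that("CC phantoms hit the void target, including the empty case", {
  gt <- generate_cc_phantom(phantom_spec("CC", image_size = 128,
                                         void_fraction_target = 0.30, seed = 9))
  expect_gte(gt$true_fd, 24)
  expect_lte(gt$true_fd, 36)
  gt0 <- generate_cc_phantom(phantom_spec("CC", image_size = 128,
                                          void_fraction_target = 0, seed = 9))
  expect_identical(sum(gt0$void_mask), 0L)
  expect_identical(gt0$true_fd, 0)
  # a rectangular void has area fraction by plain arithmetic
  vm <- matrix(FALSE, 304, 304); vm[101:130, 51:80] <- TRUE
  gtr <- octametrics:::new_ground_truth(
    "CC", phantom_spec("CC"), clean_intensity = matrix(150, 304, 304),
    void_mask = vm)
  expect_equal(gtr$true_fd, 100 * 900 / 92416)
})

test_that("phantom spec validation rejects bad geometry", {
  expect_error(phantom_spec("SCP", image_size = 32), ">= 64")
  expect_error(phantom_spec("SCP", vessel_caliber_range = c(3, 1)), "min <= max")
  expect_error(phantom_spec("SCP", capillary_density_target = 1.2), "\\(0, 1\\)")
  expect_error(phantom_spec("CC", void_fraction_target = 1), "\\[0, 1\\)")
  expect_error(generate_plexus_phantom(phantom_spec("CC")), "SCP or DCP")
  expect_error(generate_cc_phantom(phantom_spec("DCP")), "must be CC")
})
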