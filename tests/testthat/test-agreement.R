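test_that("paired comparison gates on normality and handles degenerate arms", {
  s0 <- paired_sample(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  r0 <- paired_compare(s0)
  expect_identical(r0$p_value, 1)
  expect_true(r0$degenerate)
  # constant nonzero shift: infinitely consistent evidence
  rc <- paired_compare(paired_sample(c(10, 11, 12), c(9, 10, 11)))
  expect_identical(rc$p_value, 0)
  # shift + jitter: hand-computed paired t
  v1 <- c(1, 2, 3, 4, 5)
  v4 <- v1 + 10 + c(0.1, -0.1, 0.2, -0.2, 0)
  r <- paired_compare(paired_sample(v1, v4))
  d <- v1 - v4
  t_stat <- mean(d) / (sd(d) / sqrt(5))
  expect_identical(r$test, "paired t")
  expect_equal(r$p_value, 2 * pt(-abs(t_stat), 4))
  expect_lt(r$p_value, 0.001)
})

test_that("CCC equals the moment formula and factors as rho times C_b", {
  # identity line
  ri <- concordance_correlation(paired_sample(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(ri$rho_c, 1)
  expect_equal(ri$c_b, 1)
  expect_identical(ri$category, "perfect")
  # location shift by one (biased) SD: closed form 2/3
  v1 <- c(1, 2, 3)
  rs <- concordance_correlation(paired_sample(v1, v1 + sqrt(2 / 3)))
  expect_equal(rs$rho_c, 2 / 3, tolerance = 1e-12)
  expect_equal(rs$rho, 1)
  # random pairs vs term-by-term oracle
  set.seed(12)
  for (rep in 1:5) {
    x <- rnorm(28, 50, 5); y <- 0.8 * x + rnorm(28, 12, 3)
    r <- concordance_correlation(paired_sample(x, y))
    expect_equal(r$rho_c, oracle_ccc(x, y), tolerance = 1e-12)
    expect_equal(r$rho_c, r$rho * r$c_b, tolerance = 1e-12)
    expect_lte(abs(r$rho_c), abs(r$rho))
    expect_gte(r$ci_high, r$ci_low)
  }
  expect_error(concordance_correlation(paired_sample(c(1, 1, 1), c(1, 2, 3))),
               "constant arm")
})

test_that("CCC equals rho exactly iff means and variances agree", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- rev(x)                     # same mean and variance
  r_eq <- concordance_correlation(paired_sample(x, y))
  expect_equal(r_eq$rho_c, r_eq$rho, tolerance = 1e-12)
  r_ne <- concordance_correlation(paired_sample(x, y + 2))
  expect_lt(abs(r_ne$rho_c), abs(r_ne$rho))
})

test_that("CCC decreases monotonically with a growing location shift", {
  set.seed(5)
  x <- rnorm(28, 60, 4)
  shifts <- c(0, 1, 2, 4, 8)
  cccs <- sapply(shifts, function(s)
    concordance_correlation(paired_sample(x, x + s))$rho_c)
  expect_true(all(diff(cccs) < 0))
  expect_equal(cccs[1], 1)
})

test_that("agreement categories follow the published cut-points", {
  expect_identical(classify_agreement(0.308), "poor")
  expect_identical(classify_agreement(0.93), "moderate")
  expect_identical(classify_agreement(0.995), "perfect")
  expect_identical(classify_agreement(c(0.90, 0.95, 0.99)),
                   c("moderate", "substantial", "substantial"))
  expect_error(classify_agreement(1.2), "exceed 1")
})

test_that("Bland-Altman reports bias, limits and significance", {
  s0 <- paired_sample(c(4, 5, 6), c(4, 5, 6))
  b0 <- bland_altman(s0)
  expect_identical(b0$bias, 0)
  expect_identical(c(b0$loa_low, b0$loa_high), c(0, 0))
  expect_false(b0$bias_significant)
  bc <- bland_altman(paired_sample(c(10, 11, 12), c(9, 10, 11)))
  expect_identical(bc$bias, 1)
  expect_identical(bc$sd_diff, 0)
  expect_identical(c(bc$loa_low, bc$loa_high), c(1, 1))
  expect_true(bc$bias_significant)
  set.seed(3)
  v1 <- rnorm(28, 30, 3); v4 <- v1 + rnorm(28, 1, 0.8)
  ba <- bland_altman(paired_sample(v1, v4))
  d <- v1 - v4
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_low, mean(d) - qnorm(0.975) * sd(d))
  expect_equal(ba$loa_high, mean(d) + qnorm(0.975) * sd(d))
  expect_equal(ba$bias_ci_low, mean(d) - qt(0.975, 27) * sd(d) / sqrt(28))
  expect_lte(ba$loa_low, ba$bias)
  expect_lte(ba$bias, ba$loa_high)
})

make_cohort_metrics <- function(n_eyes = 6, seed = 42, v4_equal = FALSE) {
  set.seed(seed)
  rows <- list()
  for (e in seq_len(n_eyes)) {
    id <- sprintf("eye%02d", e)
    base <- list(SCP = c(pd = rnorm(1, 68, 2), vld = rnorm(1, 7.7, 0.4),
                         vdi = rnorm(1, 9, 0.5)),
                 DCP = c(pd = rnorm(1, 57, 2), vld = rnorm(1, 9.1, 0.3),
                         vdi = rnorm(1, 6.3, 0.3)))
    fd <- rnorm(1, 33, 2)
    for (px in c("SCP", "DCP")) {
      for (mode in c("V1", "V4")) {
        shift <- if (mode == "V4" && !v4_equal) rnorm(3, c(1, -0.4, 0.4), 0.2)
                 else c(0, 0, 0)
        b <- base[[px]] + shift
        rows[[length(rows) + 1]] <- data.frame(
          eye_id = id, plexus = px, mode = mode, pd_percent = b[["pd"]],
          vld_percent = b[["vld"]], vdi_pixels = b[["vdi"]],
          fd_percent = NA_real_, stringsAsFactors = FALSE)
      }
    }
    for (mode in c("V1", "V4")) {
      rows[[length(rows) + 1]] <- data.frame(
        eye_id = id, plexus = "CC", mode = mode, pd_percent = NA_real_,
        vld_percent = NA_real_, vdi_pixels = NA_real_,
        fd_percent = fd - (mode == "V4" && !v4_equal) * rnorm(1, 8, 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("the agreement report pairs by eye_id, not by row order", {
  met <- make_cohort_metrics()
  rep1 <- build_agreement_report(met)
  expect_identical(nrow(rep1$table), 7L)
  expect_setequal(rep1$table$metric,
                  c("SCP PD", "SCP VLD", "SCP VDI", "DCP PD", "DCP VLD",
                    "DCP VDI", "CC FD"))
  shuffled <- met[sample(nrow(met)), ]
  rep2 <- build_agreement_report(shuffled)
  expect_equal(rep1$table, rep2$table)
})

test_that("identical arms give perfect concordance and degenerate p-values", {
  rep0 <- build_agreement_report(make_cohort_metrics(v4_equal = TRUE))
  expect_true(all(rep0$table$ccc == 1))
  expect_true(all(rep0$table$ccc_category == "perfect"))
  expect_true(all(rep0$table$p_value == 1))
  expect_true(all(rep0$table$delta_mean == 0))
})

test_that("eyes missing one arm are excluded with a message; too few pairs fail", {
  met <- make_cohort_metrics()
  drop <- met$eye_id == "eye01" & met$plexus == "SCP" & met$mode == "V4"
  expect_message(rep1 <- build_agreement_report(met[!drop, ]),
                 "missing one arm")
  expect_identical(rep1$table$n[rep1$table$metric == "SCP PD"], 5L)
  expect_identical(rep1$table$n[rep1$table$metric == "CC FD"], 6L)
  met3 <- make_cohort_metrics(n_eyes = 2)
  expect_error(build_agreement_report(met3), "fewer than 3")
})
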