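#' Paired sample of one metric under two acquisition modes
#'
#' @param v1,v4 numeric vectors of per-eye values, same order/length
#'   (n >= 3, finite).
#' @param metric_name label of the metric.
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(v1, v4, metric_name = "metric") {
  if (length(v1) != length(v4)) stop_octa("arms have different lengths")
  if (length(v1) < 3) stop_octa("need at least 3 paired observations")
  if (!all(is.finite(v1), is.finite(v4))) stop_octa("non-finite values in arms")
  structure(list(metric_name = metric_name, v1 = as.numeric(v1),
                 v4 = as.numeric(v4), n = length(v1)),
            class = "paired_sample")
}

#' Normality-gated paired comparison
#'
#' Applies the Shapiro-Wilk test to the per-eye differences `v1 - v4`; if
#' its p-value is at least `alpha` the paired t-test is used, otherwise the
#' Wilcoxon signed-rank test. Degenerate cases: all differences zero gives
#' p = 1 with a flag; constant non-zero differences give p = 0 (a
#' perfectly consistent shift).
#'
#' @param s a [paired_sample()].
#' @param alpha normality gate level for the Shapiro-Wilk p-value.
#' @return List with `p_value`, `test` (test name), `shapiro_p`, and
#'   `degenerate` flag.
#' @export
paired_compare <- function(s, alpha = 0.05) {
  stopifnot(inherits(s, "paired_sample"))
  d <- s$v1 - s$v4
  if (all(d == 0))
    return(list(p_value = 1, test = "degenerate (no differences)",
                shapiro_p = NA_real_, degenerate = TRUE))
  if (sd(d) == 0)
    return(list(p_value = 0, test = "paired t (degenerate constant shift)",
                shapiro_p = NA_real_, degenerate = TRUE))
  sw <- shapiro.test(d)$p.value
  if (sw >= alpha) {
    pv <- t.test(s$v1, s$v4, paired = TRUE)$p.value
    test <- "paired t"
  } else {
    pv <- suppressWarnings(wilcox.test(s$v1, s$v4, paired = TRUE))$p.value
    test <- "Wilcoxon signed-rank"
  }
  list(p_value = pv, test = test, shapiro_p = sw, degenerate = FALSE)
}

#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)` with biased
#' (1/n) moment estimators. The coefficient factors as
#' `rho_c = rho * C_b`: Pearson precision `rho` times the accuracy
#' (bias-correction) factor `C_b`, which measures how far the best-fit line
#' deviates from the 45-degree identity line. The 95% CI uses the Fisher
#' z-transform of `rho_c` with Lin's asymptotic standard error.
#'
#' @param s a [paired_sample()]; both arms must be non-constant.
#' @param conf confidence level.
#' @return An object of class `ccc_result` with `rho_c`, `rho`, `c_b`,
#'   `ci_low`, `ci_high`, `category` (see [classify_agreement()]) and `n`.
#' @examples
#' s <- paired_sample(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 4.3))
#' concordance_correlation(s)
#' @export
concordance_correlation <- function(s, conf = 0.95) {
  stopifnot(inherits(s, "paired_sample"))
  x <- s$v1; y <- s$v4; n <- s$n
  if (sd(x) == 0 || sd(y) == 0)
    stop_octa("constant arm: Pearson correlation (and CCC) undefined")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  rho_c <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  rho <- cor(x, y)
  c_b <- if (rho != 0) rho_c / rho else NA_real_
  # Fisher z CI with Lin (1989) SE
  if (abs(rho_c) < 1 && rho != 0 && n > 2) {
    u <- (mx - my) / sqrt(sqrt(sx2) * sqrt(sy2))
    z <- atanh(rho_c)
    var_z <- ((1 - rho^2) * rho_c^2 / ((1 - rho_c^2) * rho^2) +
                4 * rho_c^3 * (1 - rho_c) * u^2 / (rho * (1 - rho_c^2)^2) -
                2 * rho_c^4 * u^4 / (rho^2 * (1 - rho_c^2)^2)) / (n - 2)
    # the three terms cancel exactly under a pure location shift (rho = 1);
    # round-off can leave a tiny negative remainder
    se_z <- sqrt(max(var_z, 0))
    zq <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- tanh(z + c(-1, 1) * zq * se_z)
  } else {
    ci <- c(rho_c, rho_c)
  }
  structure(list(rho_c = rho_c, rho = rho, c_b = c_b,
                 ci_low = ci[1], ci_high = ci[2],
                 category = classify_agreement(rho_c), n = n,
                 metric_name = s$metric_name),
            class = "ccc_result")
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf("Lin's CCC (%s, n = %d): rho_c = %.3f [%.3f to %.3f] (%s)\n",
              x$metric_name, x$n, x$rho_c, x$ci_low, x$ci_high, x$category))
  cat(sprintf("  precision rho = %.3f, accuracy C_b = %.3f\n", x$rho, x$c_b))
  invisible(x)
}

#' Agreement category of a CCC value
#'
#' Strength-of-agreement bands: poor below 0.90, moderate from 0.90 to
#' 0.95, substantial from 0.95 to 0.99, perfect above 0.99. Boundaries are
#' left-closed (0.90 is moderate, 0.95 is substantial) and 0.99 exactly is
#' substantial.
#'
#' @param rho_c CCC value(s), each at most 1.
#' @return Character vector of categories.
#' @examples
#' classify_agreement(c(0.308, 0.93, 0.995))
#' @export
classify_agreement <- function(rho_c) {
  if (any(rho_c > 1 + 1e-12)) stop_octa("rho_c cannot exceed 1")
  ifelse(rho_c < 0.90, "poor",
         ifelse(rho_c < 0.95, "moderate",
                ifelse(rho_c <= 0.99, "substantial", "perfect")))
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `v1 - v4`. Reports the bias (mean difference),
#' the 95% limits of agreement `bias -/+ 1.96 * sd` (sample SD, n - 1
#' denominator) within which about 95% of differences fall, the Student-t
#' 95% CI of the bias, and whether the bias is significant (zero outside
#' its CI).
#'
#' @param s a [paired_sample()].
#' @param conf confidence level for bias CI and limit multiplier.
#' @return An object of class `ba_result`.
#' @export
bland_altman <- function(s, conf = 0.95) {
  stopifnot(inherits(s, "paired_sample"))
  d <- s$v1 - s$v4
  n <- s$n
  bias <- mean(d)
  sd_d <- sd(d)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  loa <- bias + c(-1, 1) * zq * sd_d
  ci <- bias + c(-1, 1) * qt(1 - (1 - conf) / 2, n - 1) * sd_d / sqrt(n)
  structure(list(bias = bias, sd_diff = sd_d,
                 loa_low = loa[1], loa_high = loa[2],
                 bias_ci_low = ci[1], bias_ci_high = ci[2],
                 bias_significant = !(ci[1] <= 0 && 0 <= ci[2]),
                 means = (s$v1 + s$v4) / 2, differences = d,
                 n = n, metric_name = s$metric_name),
            class = "ba_result")
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s, n = %d): bias %.3f [%.3f to %.3f], LoA [%.3f, %.3f]%s\n",
              x$metric_name, x$n, x$bias, x$bias_ci_low, x$bias_ci_high,
              x$loa_low, x$loa_high,
              if (x$bias_significant) " (bias significant)" else ""))
  invisible(x)
}

#' @export
plot.ba_result <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "Mean of V1 and V4", ylab = "Difference (V1 - V4)",
                 main = x$metric_name, pch = 19, ...)
  graphics::abline(h = x$bias, col = "blue")
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "red", lty = 2)
  graphics::abline(h = 0, col = "grey50", lty = 3)
  invisible(x)
}

# Delta convention used throughout the report: V1 minus V4 (column order of
# a paired-modes table).
metric_delta <- function(v1, v4) mean(v1) - mean(v4)

#' Cohort-level V1-vs-V4 agreement report
#'
#' Builds one row per metric (SCP/DCP x PD/VLD/VDI plus CC FD) from a
#' long-format cohort metrics table: per-arm mean and SD, the difference
#' `Delta = V1 - V4` (mean and SD), the normality-gated paired p-value,
#' Lin's CCC with CI and category, and the Bland-Altman bias and limits.
#' Eyes are paired by `eye_id` (row order is irrelevant); eyes missing one
#' arm are excluded from that metric with a logged count.
#'
#' @param metrics data frame with columns `eye_id`, `plexus`, `mode`
#'   (`"V1"`/`"V4"`) and metric columns `pd_percent`, `vld_percent`,
#'   `vdi_pixels` (SCP/DCP rows) and `fd_percent` (CC rows), as produced by
#'   [quantify_cohort()].
#' @return An object of class `octa_agreement`: a data frame `table` plus
#'   per-metric `samples` and Bland-Altman plot data.
#' @export
build_agreement_report <- function(metrics) {
  need <- c("eye_id", "plexus", "mode")
  if (!all(need %in% names(metrics)))
    stop_octa("metrics table must have columns ", paste(need, collapse = ", "))
  defs <- list(
    list(label = "SCP PD",  plexus = "SCP", col = "pd_percent"),
    list(label = "SCP VLD", plexus = "SCP", col = "vld_percent"),
    list(label = "SCP VDI", plexus = "SCP", col = "vdi_pixels"),
    list(label = "DCP PD",  plexus = "DCP", col = "pd_percent"),
    list(label = "DCP VLD", plexus = "DCP", col = "vld_percent"),
    list(label = "DCP VDI", plexus = "DCP", col = "vdi_pixels"),
    list(label = "CC FD",   plexus = "CC",  col = "fd_percent"))
  rows <- list(); samples <- list(); ba_data <- list()
  excluded <- integer(0)
  for (df in defs) {
    if (!df$col %in% names(metrics)) next
    sub <- metrics[metrics$plexus == df$plexus & !is.na(metrics[[df$col]]), ]
    if (nrow(sub) == 0) next
    w1 <- sub[sub$mode == "V1", c("eye_id", df$col)]
    w4 <- sub[sub$mode == "V4", c("eye_id", df$col)]
    ids <- intersect(w1$eye_id, w4$eye_id)
    n_excl <- length(union(w1$eye_id, w4$eye_id)) - length(ids)
    excluded[df$label] <- n_excl
    if (n_excl > 0)
      message(sprintf("%s: %d eye(s) missing one arm, excluded", df$label, n_excl))
    if (length(ids) < 3)
      stop_octa(df$label, ": fewer than 3 complete eye-pairs")
    v1 <- w1[[df$col]][match(ids, w1$eye_id)]
    v4 <- w4[[df$col]][match(ids, w4$eye_id)]
    s <- paired_sample(v1, v4, metric_name = df$label)
    pc <- paired_compare(s)
    cc <- concordance_correlation(s)
    ba <- bland_altman(s)
    d <- v1 - v4
    rows[[df$label]] <- data.frame(
      metric = df$label, n = s$n,
      v1_mean = mean(v1), v1_sd = sd(v1),
      v4_mean = mean(v4), v4_sd = sd(v4),
      delta_mean = metric_delta(v1, v4), delta_sd = sd(d),
      p_value = pc$p_value, test = pc$test,
      ccc = cc$rho_c, ccc_low = cc$ci_low, ccc_high = cc$ci_high,
      ccc_category = cc$category,
      ba_bias = ba$bias, ba_loa_low = ba$loa_low, ba_loa_high = ba$loa_high,
      ba_bias_significant = ba$bias_significant,
      stringsAsFactors = FALSE)
    samples[[df$label]] <- list(sample = s, paired = pc, ccc = cc, ba = ba)
    ba_data[[df$label]] <- data.frame(
      metric = df$label, eye_id = ids, mean = (v1 + v4) / 2, difference = d,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop_octa("no analyzable metrics in input")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, samples = samples,
                 ba_plot_data = do.call(rbind, c(ba_data, make.row.names = FALSE)),
                 excluded = excluded),
            class = "octa_agreement")
}

#' @export
print.octa_agreement <- function(x, digits = 3, ...) {
  cat("V1 vs V4 agreement report (", x$table$n[1], " eyes)\n\n", sep = "")
  tab <- x$table
  out <- data.frame(
    metric = tab$metric,
    `V1 mean (SD)` = sprintf("%.2f (%.2f)", tab$v1_mean, tab$v1_sd),
    `V4 mean (SD)` = sprintf("%.2f (%.2f)", tab$v4_mean, tab$v4_sd),
    `Delta (V1-V4)` = sprintf("%.2f (%.2f)", tab$delta_mean, tab$delta_sd),
    p = signif(tab$p_value, digits),
    CCC = sprintf("%.3f [%.3f, %.3f]", tab$ccc, tab$ccc_low, tab$ccc_high),
    category = tab$ccc_category,
    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.octa_agreement <- function(object, ...) {
  object$table
}

#' @export
plot.octa_agreement <- function(x, metrics = NULL, ...) {
  keep <- names(x$samples)
  if (!is.null(metrics)) keep <- intersect(keep, metrics)
  nk <- length(keep)
  old <- graphics::par(mfrow = grDevices::n2mfrow(nk), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in keep) plot(x$samples[[nm]]$ba, ...)
  invisible(x)
}
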