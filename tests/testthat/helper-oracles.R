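# Brute-force reference implementations, kept deliberately naive and
# independent of the package's computational paths.

clampi <- function(v, lo, hi) pmin(pmax(v, lo), hi)

dice_overlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Exhaustive grayscale opening (erosion then dilation) with a disk
# structuring element; out-of-bounds offsets are ignored.
oracle_opening <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  offs <- expand.grid(di = (-radius):radius, dj = (-radius):radius)
  offs <- as.matrix(offs[offs$di^2 + offs$dj^2 <= radius^2, c("di", "dj")])
  sweep1 <- function(m, f) {
    out <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      ii <- offs[, 1] + i; jj <- offs[, 2] + j
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      out[i, j] <- f(m[cbind(ii[ok], jj[ok])])
    }
    out
  }
  sweep1(sweep1(img, min), max)
}

# Direct per-pixel evaluation of the Huang-Wang fuzzy entropy over all
# candidate thresholds.
oracle_huang <- function(img) {
  g <- as.integer(round(img))
  lo <- min(g); hi <- max(g)
  stopifnot(lo < hi)
  C <- hi - lo
  shannon <- function(u) {
    ifelse(u <= 0 | u >= 1, 0, -u * log(u) - (1 - u) * log(1 - u))
  }
  best_t <- NA_integer_; best_e <- Inf
  for (t in lo:(hi - 1)) {
    below <- g <= t
    if (!any(below) || all(below)) next
    m0 <- mean(g[below]); m1 <- mean(g[!below])
    mu <- ifelse(below, 1 / (1 + abs(g - m0) / C), 1 / (1 + abs(g - m1) / C))
    e <- sum(shannon(mu))
    if (e < best_e - 1e-12) { best_e <- e; best_t <- t }
  }
  best_t
}

# Per-pixel window median with replicated (clamped-index) edges.
oracle_window_median <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- clampi(i + (-radius):radius, 1, nr)
    jj <- clampi(j + (-radius):radius, 1, nc)
    vals <- img[ii, jj]   # clamped index grid keeps duplicated edge entries
    out[i, j] <- sort(vals)[(length(vals) + 1) / 2]
  }
  out
}

# Per-pixel circular-window mean/SD (population) and Phansalkar threshold.
oracle_phansalkar <- function(img, radius, k = 0.25, r = 0.5, p = 2, q = 10) {
  z <- clampi(img, 0, 255) / 255
  nr <- nrow(z); nc <- ncol(z)
  off <- expand.grid(dy = (-radius):radius, dx = (-radius):radius)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  mask <- matrix(NA, nr, nc); thr <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- z[cbind(clampi(i + off$dy, 1, nr), clampi(j + off$dx, 1, nc))]
    mu <- mean(vals); sg <- sqrt(mean(vals^2) - mu^2)
    t <- mu * (1 + p * exp(-q * mu) + k * (sg / r - 1))
    thr[i, j] <- t
    mask[i, j] <- z[i, j] > t
  }
  list(mask = mask, threshold = thr)
}

# BFS flood-fill component labeling (8-connectivity); returns sorted areas.
oracle_component_areas <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  areas <- integer(0)
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    queue <- list(c(i0, j0)); seen[i0, j0] <- TRUE; a <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]; a <- a + 1L
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && nj >= 1 && ni <= nr && nj <= nc &&
            mask[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
    areas <- c(areas, a)
  }
  sort(areas)
}

# Term-by-term evaluation of Lin's concordance from raw sums.
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

noiseless <- function() noise_model("gaussian", sigma = 0, n_volumes = 1)
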