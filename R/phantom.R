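#' Specification of a synthetic en face angiogram phantom
#'
#' Collects the geometry and density parameters from which a seeded phantom
#' is generated. Defaults emulate a 3x3 mm macular scan sampled at 304x304
#' pixels (about 9.9 um per pixel).
#'
#' @param plexus `"SCP"` (superficial capillary plexus: several large vessels
#'   plus a capillary mesh), `"DCP"` (deep plexus: thin capillaries
#'   converging radially toward a foveal epicenter) or `"CC"`
#'   (choriocapillaris: granular texture with dark signal-void patches).
#' @param image_size side length in pixels (square image).
#' @param scale mm per pixel.
#' @param n_large_vessels number of thick arteriole/venule-caliber tubes
#'   (SCP only).
#' @param capillary_density_target fraction of the frame that the vessel
#'   mask should cover, in (0, 1). Defaults: 0.55 for SCP, 0.45 for DCP.
#' @param vessel_caliber_range capillary caliber range in pixels
#'   (`c(min, max)`).
#' @param large_caliber_range caliber range of the SCP large vessels in
#'   pixels.
#' @param void_fraction_target fraction of the frame occupied by
#'   choriocapillaris flow voids (CC only), in \[0, 1).
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @examples
#' phantom_spec("DCP", image_size = 128, seed = 7)
#' @export
phantom_spec <- function(plexus = c("SCP", "DCP", "CC"), image_size = 304,
                         scale = 3 / 304, n_large_vessels = 4,
                         capillary_density_target = NULL,
                         vessel_caliber_range = c(1, 3),
                         large_caliber_range = c(6, 12),
                         void_fraction_target = 0.30, seed = 1) {
  plexus <- match.arg(plexus)
  if (is.null(capillary_density_target))
    capillary_density_target <- switch(plexus, SCP = 0.55, DCP = 0.45, CC = NA_real_)
  if (length(image_size) != 1 || image_size < 64)
    stop_octa("`image_size` must be a single value >= 64")
  if (vessel_caliber_range[1] > vessel_caliber_range[2] ||
      large_caliber_range[1] > large_caliber_range[2])
    stop_octa("caliber range must satisfy min <= max")
  if (any(c(vessel_caliber_range, large_caliber_range) <= 0))
    stop_octa("calibers must be positive")
  if (plexus != "CC" &&
      (capillary_density_target <= 0 || capillary_density_target >= 1))
    stop_octa("`capillary_density_target` must lie in (0, 1)")
  if (plexus == "CC" &&
      (void_fraction_target < 0 || void_fraction_target >= 1))
    stop_octa("`void_fraction_target` must lie in [0, 1)")
  structure(
    list(plexus = plexus, image_size = as.integer(image_size), scale = scale,
         n_large_vessels = as.integer(n_large_vessels),
         capillary_density_target = capillary_density_target,
         vessel_caliber_range = vessel_caliber_range,
         large_caliber_range = large_caliber_range,
         void_fraction_target = void_fraction_target,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  tgt <- if (x$plexus == "CC") sprintf("void %.2f", x$void_fraction_target)
         else sprintf("density %.2f", x$capillary_density_target)
  cat(sprintf("<phantom_spec> %s %dx%d px (%.4f mm/px), %s, seed %d\n",
              x$plexus, x$image_size, x$image_size, x$scale, tgt, x$seed))
  invisible(x)
}

#' Render anti-aliased tubes onto a coverage canvas
#'
#' Each tube is a sampled path with a per-point radius; every sample stamps a
#' disk whose per-pixel coverage is `clamp(radius + 0.5 - distance, 0, 1)`
#' and the canvas keeps the pointwise maximum. Thresholding the canvas at
#' 0.5 yields an unambiguous boolean vessel mask.
#'
#' @param size side length of the square canvas in pixels.
#' @param paths list of tubes, each a list with numeric vectors `x`, `y`
#'   (1-based pixel coordinates, fractional allowed) and `radius` (scalar or
#'   per-point).
#' @param canvas optional existing canvas to stamp onto.
#' @return Numeric matrix in \[0, 1\].
#' @examples
#' cv <- render_tubes(64, list(list(x = 1:64, y = rep(32, 64), radius = 3.5)))
#' mean(cv >= 0.5)
#' @export
render_tubes <- function(size, paths, canvas = NULL) {
  if (is.null(canvas)) canvas <- matrix(0, size, size)
  for (p in paths) {
    r <- rep_len(p$radius, length(p$x))
    canvas <- cpp_stamp_tubes(canvas, as.numeric(p$x), as.numeric(p$y),
                              as.numeric(r))
  }
  canvas
}

# Smooth random-walk tube path with bounded heading drift. Optional vortex
# geometry: the heading is steered toward the local spiral direction
# (radial direction plus `spiral_angle`) around `center`, and the path
# stops at the inner radius `r_min` (perifoveal ring). Returns NULL if
# fewer than two in-frame samples result.
walk_path <- function(x0, y0, theta0, n_steps, turn_sd, size, step = 1,
                      center = NULL, spiral_angle = 0, steer = 0,
                      r_min = 0) {
  xs <- numeric(n_steps); ys <- numeric(n_steps)
  x <- x0; y <- y0; th <- theta0
  turns <- rnorm(n_steps, 0, turn_sd)
  for (k in seq_len(n_steps)) {
    if (!is.null(center)) {
      if (sqrt((center[1] - x)^2 + (center[2] - y)^2) < r_min) {
        n_steps <- k - 1; break
      }
      target <- atan2(center[2] - y, center[1] - x) + spiral_angle
      d <- ((target - th + pi) %% (2 * pi)) - pi
      th <- th + steer * d
    }
    th <- th + turns[k]
    x <- x + step * cos(th); y <- y + step * sin(th)
    if (x < -4 || y < -4 || x > size + 5 || y > size + 5) { n_steps <- k - 1; break }
    xs[k] <- x; ys[k] <- y
  }
  if (n_steps < 2) return(NULL)
  list(x = xs[seq_len(n_steps)], y = ys[seq_len(n_steps)])
}

# Smooth unit-mean multiplicative field (about +/- `amp`) emulating
# perfusion heterogeneity of the decorrelation signal.
perfusion_modulation <- function(n, amp = 0.10, sigma = 8) {
  g <- gaussian_kernel(sigma)
  z <- cpp_sep_convolve(matrix(rnorm(n * n), n, n), g, g)
  1 + amp * (z - mean(z)) / sd(z)
}

# Map a soft coverage canvas to an 8-bit clean intensity grid: dark
# background (~25) and bright vessels (>= ~185 wherever coverage >= 0.5),
# with a one-pixel smooth shoulder from the anti-aliased tube profile.
canvas_to_intensity <- function(canvas, background = 25, peak = 230) {
  s <- pmin(canvas, 1)^0.35
  round(background + (peak - background) * s)
}

new_ground_truth <- function(plexus, spec, clean_intensity,
                             vessel_mask = NULL, centerline_mask = NULL,
                             void_mask = NULL) {
  n <- length(clean_intensity)
  gt <- list(
    plexus = plexus, spec = spec,
    clean_intensity = clean_intensity,
    vessel_mask = vessel_mask, centerline_mask = centerline_mask,
    void_mask = void_mask,
    true_pd = if (!is.null(vessel_mask)) 100 * sum(vessel_mask) / n else NA_real_,
    true_vld = if (!is.null(centerline_mask)) 100 * sum(centerline_mask) / n else NA_real_,
    true_vdi = if (!is.null(centerline_mask) && sum(centerline_mask) > 0)
      sum(vessel_mask) / sum(centerline_mask) else NA_real_,
    true_fd = if (!is.null(void_mask)) 100 * sum(void_mask) / n else NA_real_)
  class(gt) <- "octa_phantom"
  gt
}

#' @export
print.octa_phantom <- function(x, ...) {
  cat(sprintf("<octa_phantom> %s %dx%d px", x$plexus,
              nrow(x$clean_intensity), ncol(x$clean_intensity)))
  if (!is.na(x$true_pd))
    cat(sprintf(" | true PD %.1f%%, VLD %.2f%%, VDI %.2f px",
                x$true_pd, x$true_vld, x$true_vdi))
  if (!is.na(x$true_fd)) cat(sprintf(" | true FD %.1f%%", x$true_fd))
  cat("\n")
  invisible(x)
}

#' Generate a retinal plexus phantom with known ground truth
#'
#' Draws a vascular network as smooth curved tubes on a dark background. SCP
#' phantoms contain `n_large_vessels` thick tubes plus a capillary mesh;
#' DCP phantoms contain only thin capillaries whose paths bias radially
#' toward a central epicenter. Capillaries are added until the vessel-mask
#' area fraction reaches `capillary_density_target` (achieved fraction is
#' guaranteed within 20% relative of the target, otherwise an error is
#' raised). The ground-truth centerline is the Zhang-Suen skeleton of the
#' vessel mask.
#'
#' @param spec a [phantom_spec()] with `plexus` `"SCP"` or `"DCP"`.
#' @return An `octa_phantom` with elements `clean_intensity` (8-bit grid),
#'   `vessel_mask`, `centerline_mask`, and ground-truth scalars `true_pd`,
#'   `true_vld`, `true_vdi` (percent, percent, pixels).
#' @examples
#' gt <- generate_plexus_phantom(phantom_spec("DCP", image_size = 96,
#'                                            capillary_density_target = 0.3,
#'                                            seed = 3))
#' gt$true_pd
#' @export
generate_plexus_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!spec$plexus %in% c("SCP", "DCP"))
    stop_octa("`spec$plexus` must be SCP or DCP (use generate_cc_phantom for CC)")
  with_seed(spec$seed, {
    n <- spec$image_size
    canvas <- matrix(0, n, n)
    target <- spec$capillary_density_target

    if (spec$plexus == "SCP" && spec$n_large_vessels > 0) {
      for (v in seq_len(spec$n_large_vessels)) {
        edge <- sample(4, 1)
        pos <- runif(1, 0.1, 0.9) * n
        start <- switch(edge, c(1, pos), c(n, pos), c(pos, 1), c(pos, n))
        inward <- switch(edge, 0, pi, pi / 2, -pi / 2)
        th0 <- inward + rnorm(1, 0, 0.3)
        p <- walk_path(start[1], start[2], th0, n_steps = 3 * n,
                       turn_sd = 0.03, size = n)
        if (is.null(p)) next
        caliber <- runif(1, spec$large_caliber_range[1], spec$large_caliber_range[2])
        canvas <- cpp_stamp_tubes(canvas, p$x, p$y,
                                  rep(caliber / 2, length(p$x)))
      }
    }

    epicenter <- c((n + 1) / 2, (n + 1) / 2)
    max_tubes <- 4000L
    achieved <- mean(canvas >= 0.5)
    tube <- 0L
    while (achieved < target && tube < max_tubes) {
      tube <- tube + 1L
      caliber <- runif(1, spec$vessel_caliber_range[1], spec$vessel_caliber_range[2])
      short <- (target - achieved) < 0.01
      if (spec$plexus == "SCP") {
        p <- walk_path(runif(1, 1, n), runif(1, 1, n), runif(1, 0, 2 * pi),
                       n_steps = sample(if (short) 30:60 else 80:250, 1),
                       turn_sd = 0.15, size = n)
      } else {
        # vortex mesh: thin capillaries spiral toward the epicenter and
        # stop at a perifoveal inner ring, so coverage stays homogeneous
        phi <- runif(1, 0, 2 * pi)
        rr <- sqrt(runif(1, (0.12)^2, (0.5)^2)) * n   # area-uniform radius
        x0 <- epicenter[1] + rr * cos(phi)
        y0 <- epicenter[2] + rr * sin(phi)
        sa <- sample(c(-1, 1), 1) * runif(1, 0.9, 1.3)  # ~52-75 deg spiral
        th0 <- atan2(epicenter[2] - y0, epicenter[1] - x0) + sa
        p <- walk_path(x0, y0, th0,
                       n_steps = sample(if (short) 30:60 else 60:160, 1),
                       turn_sd = 0.12, size = n, center = epicenter,
                       spiral_angle = sa, steer = 0.25, r_min = 0.06 * n)
      }
      if (is.null(p)) next
      canvas <- cpp_stamp_tubes(canvas, p$x, p$y, rep(caliber / 2, length(p$x)))
      achieved <- mean(canvas >= 0.5)
    }
    if (abs(achieved - target) > 0.2 * target)
      stop_octa(sprintf(
        "vessel density target unreachable: achieved %.3f vs requested %.3f after %d tubes",
        achieved, target, tube))

    vessel_mask <- canvas >= 0.5
    centerline <- skeletonize(vessel_mask)
    clean <- canvas_to_intensity(canvas) * perfusion_modulation(n)
    new_ground_truth(spec$plexus, spec,
                     clean_intensity = round(pmin(pmax(clean, 0), 255)),
                     vessel_mask = vessel_mask, centerline_mask = centerline)
  })
}

#' Generate a choriocapillaris phantom with known flow-deficit ground truth
#'
#' Produces a granular bright background (band-limited random texture) with
#' irregular dark patches whose union is the ground-truth signal-void mask.
#' Blobs are added until the void area fraction reaches
#' `void_fraction_target` (within 20% relative, otherwise an error); a
#' target of zero yields an empty void mask.
#'
#' @param spec a [phantom_spec()] with `plexus = "CC"`.
#' @return An `octa_phantom` with `clean_intensity`, `void_mask` and
#'   `true_fd` (percent of frame area).
#' @examples
#' gt <- generate_cc_phantom(phantom_spec("CC", image_size = 96,
#'                                        void_fraction_target = 0.2, seed = 5))
#' gt$true_fd
#' @export
generate_cc_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$plexus != "CC") stop_octa("`spec$plexus` must be CC")
  with_seed(spec$seed, {
    n <- spec$image_size
    # band-limited granular texture: smoothed white noise, sd ~28 about 150
    g <- gaussian_kernel(1.2)
    z <- cpp_sep_convolve(matrix(rnorm(n * n), n, n), g, g)
    z <- (z - mean(z)) / sd(z)
    texture <- pmin(pmax(150 + 28 * z, 40), 255)

    target <- spec$void_fraction_target
    voidc <- matrix(0, n, n)
    achieved <- 0
    blob <- 0L
    max_blobs <- 4000L
    while (achieved < target && blob < max_blobs) {
      blob <- blob + 1L
      cx <- runif(1, 1, n); cy <- runif(1, 1, n)
      small <- (target - achieved) < 0.01
      k <- sample(3:6, 1)
      sc <- if (small) 0.5 else 1
      xs <- cx + rnorm(k, 0, 5 * sc)
      ys <- cy + rnorm(k, 0, 5 * sc)
      rs <- runif(k, 3, 10) * sc
      voidc <- cpp_stamp_tubes(voidc, xs, ys, rs)
      achieved <- mean(voidc >= 0.5)
    }
    if (target > 0 && abs(achieved - target) > 0.2 * target)
      stop_octa(sprintf(
        "void fraction target unreachable: achieved %.3f vs requested %.3f after %d blobs",
        achieved, target, blob))

    void_mask <- voidc >= 0.5
    clean <- round(texture * (1 - 0.85 * pmin(voidc, 1)))
    new_ground_truth("CC", spec, clean_intensity = clean, void_mask = void_mask)
  })
}

# Normalized 1-D Gaussian kernel sampled on +/- ceil(3*sigma).
gaussian_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}
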