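#' Acquisition noise model
#'
#' Describes how a clean phantom is turned into one simulated acquisition:
#' `n_volumes` independent noisy frames are generated and averaged pixelwise
#' (the multi-volume merge), then clipped to \[0, 255\]. The default noise is
#' speckle-like multiplicative Gaussian, `pixel * (1 + e) + f` with
#' `e ~ N(0, sigma^2)` and a small additive floor `f ~ N(0, floor_sd^2)`;
#' coherent-imaging speckle is dominantly multiplicative, and frame
#' averaging reduces its SD by about `sqrt(n_volumes)`. A pure additive
#' Gaussian model (`sigma` in intensity units, no floor) is kept for
#' analytic tests.
#'
#' @param noise_kind `"speckle_multiplicative"` or `"gaussian"`.
#' @param sigma noise SD: relative for speckle, intensity units (0-255) for
#'   gaussian. Must be >= 0. The default 0.8 corresponds to near-fully
#'   developed speckle (contrast ratio approaching 1), the regime in which
#'   a single-volume scan shows visible vessel discontinuity.
#' @param n_volumes number of independent frames averaged (>= 1); 1 gives a
#'   V1 acquisition, 4 a V4.
#' @param seed integer seed; same model + phantom gives bit-identical images.
#' @param floor_sd additive noise floor SD (speckle model only).
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(sigma = 0.3, n_volumes = 4, seed = 2)
#' @export
noise_model <- function(noise_kind = c("speckle_multiplicative", "gaussian"),
                        sigma = 0.80, n_volumes = 1, seed = 1, floor_sd = 4) {
  noise_kind <- match.arg(noise_kind)
  if (sigma < 0) stop_octa("`sigma` must be >= 0")
  if (n_volumes < 1) stop_octa("`n_volumes` must be >= 1")
  structure(list(noise_kind = noise_kind, sigma = sigma,
                 n_volumes = as.integer(n_volumes), seed = as.integer(seed),
                 floor_sd = floor_sd),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> %s sigma=%.3g, %d volume(s), seed %d\n",
              x$noise_kind, x$sigma, x$n_volumes, x$seed))
  invisible(x)
}

#' Simulate one acquisition of a phantom
#'
#' Generates `noise$n_volumes` independent noisy realizations of the
#' phantom's clean intensity grid, averages them pixelwise, clips to
#' \[0, 255\] and quantizes to 8 bits. With `sigma = 0` and one volume the
#' output equals the clean intensity exactly.
#'
#' @param gt an `octa_phantom` (from [generate_plexus_phantom()] or
#'   [generate_cc_phantom()]).
#' @param noise a [noise_model()].
#' @param eye_id identifier recorded on the image.
#' @return An [en_face_image()]; `acquisition_mode` is `"V1"` for one
#'   volume, `"V4"` for four, `"V<n>"` otherwise.
#' @examples
#' gt <- generate_cc_phantom(phantom_spec("CC", image_size = 96, seed = 5))
#' img <- simulate_acquisition(gt, noise_model(sigma = 0.3, n_volumes = 4))
#' img
#' @export
simulate_acquisition <- function(gt, noise, eye_id = "eye01") {
  stopifnot(inherits(gt, "octa_phantom"), inherits(noise, "noise_model"))
  clean <- gt$clean_intensity
  acc <- with_seed(noise$seed, {
    s <- matrix(0, nrow(clean), ncol(clean))
    for (v in seq_len(noise$n_volumes)) {
      frame <- if (noise$noise_kind == "gaussian") {
        clean + rnorm(length(clean), 0, noise$sigma)
      } else {
        clean * (1 + rnorm(length(clean), 0, noise$sigma)) +
          rnorm(length(clean), 0, noise$floor_sd)
      }
      s <- s + frame
    }
    s / noise$n_volumes
  })
  pix <- round(pmin(pmax(acc, 0), 255))
  mode <- if (noise$n_volumes == 1) "V1" else if (noise$n_volumes == 4) "V4"
          else paste0("V", noise$n_volumes)
  en_face_image(pix, plexus = gt$plexus, acquisition_mode = mode,
                scale = gt$spec$scale, eye_id = eye_id)
}

#' Generate a paired synthetic cohort (V1 and V4 per eye)
#'
#' Draws `n_eyes` independent eyes, each with SCP, DCP and CC phantoms, and
#' images every phantom under both acquisition modes. Per-eye density and
#' caliber targets are jittered by up to `jitter` (relative, uniform) so the
#' paired statistics have between-eye variance, as in a real cohort.
#'
#' @param n_eyes number of eyes (>= 2).
#' @param specs named list of [phantom_spec()]s for `SCP`, `DCP`, `CC`
#'   (defaults generated from `image_size`).
#' @param noise_v1,noise_v4 [noise_model()]s for the single-volume and
#'   four-volume acquisitions (seeds are re-drawn per eye/plexus/mode from
#'   `seed`).
#' @param seed master seed for the whole cohort.
#' @param jitter relative per-eye jitter of density/caliber targets.
#' @param image_size side length used for the default specs.
#' @return An `octa_cohort`: list with `eyes` (each having `eye_id`,
#'   `truth`, and an `images` list keyed `<plexus>_<mode>`).
#' @examples
#' coh <- generate_cohort(2, seed = 11, image_size = 96)
#' length(coh$eyes[[1]]$images)
#' @export
generate_cohort <- function(n_eyes, specs = NULL,
                            noise_v1 = noise_model(n_volumes = 1),
                            noise_v4 = noise_model(n_volumes = 4),
                            seed = 1, jitter = 0.10, image_size = 304) {
  if (n_eyes < 2) stop_octa("`n_eyes` must be >= 2")
  if (is.null(specs))
    specs <- list(SCP = phantom_spec("SCP", image_size = image_size),
                  DCP = phantom_spec("DCP", image_size = image_size),
                  CC  = phantom_spec("CC",  image_size = image_size))
  plexi <- c("SCP", "DCP", "CC")
  n_seeds <- n_eyes * (length(plexi) + 2 * length(plexi) + 3)
  sds <- derive_seeds(seed, n_seeds)
  jit <- with_seed(seed + 1L, matrix(runif(n_eyes * 3, 1 - jitter, 1 + jitter),
                                     n_eyes, 3))
  eyes <- vector("list", n_eyes)
  si <- 0L
  nxt <- function() { si <<- si + 1L; sds[si] }
  for (e in seq_len(n_eyes)) {
    eye_id <- sprintf("eye%02d", e)
    truth <- list()
    images <- list()
    for (pi in seq_along(plexi)) {
      px <- plexi[pi]
      sp <- specs[[px]]
      sp$seed <- nxt()
      if (px == "CC") {
        sp$void_fraction_target <- sp$void_fraction_target * jit[e, 1]
      } else {
        sp$capillary_density_target <-
          min(0.95, sp$capillary_density_target * jit[e, 2])
        sp$vessel_caliber_range <- sp$vessel_caliber_range * jit[e, 3]
        sp$large_caliber_range <- sp$large_caliber_range * jit[e, 3]
      }
      gt <- if (px == "CC") generate_cc_phantom(sp) else generate_plexus_phantom(sp)
      truth[[px]] <- gt
      for (nm in list(noise_v1, noise_v4)) {
        nm$seed <- nxt()
        img <- simulate_acquisition(gt, nm, eye_id = eye_id)
        images[[paste(px, img$acquisition_mode, sep = "_")]] <- img
      }
    }
    eyes[[e]] <- list(eye_id = eye_id, truth = truth, images = images)
  }
  structure(list(eyes = eyes, seed = seed, jitter = jitter,
                 noise_v1 = noise_v1, noise_v4 = noise_v4),
            class = "octa_cohort")
}

#' @export
print.octa_cohort <- function(x, ...) {
  cat(sprintf("<octa_cohort> %d eyes x 3 plexus x 2 modes (%d images), seed %d\n",
              length(x$eyes), sum(lengths(lapply(x$eyes, `[[`, "images"))),
              x$seed))
  invisible(x)
}
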