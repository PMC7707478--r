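#' Parameters of the Phansalkar local threshold
#'
#' Defaults follow the ImageJ Auto Local Threshold dialect: circular window
#' of radius 15 pixels and constants `k = 0.25`, `r = 0.5`, `p = 2`,
#' `q = 10`.
#'
#' @param radius window radius in pixels (>= 1).
#' @param k,r,p,q dimensionless constants of the threshold formula
#'   (`r > 0`).
#' @param min_deficit_px optional size floor: void components smaller than
#'   this many pixels are dropped from the particle analysis (0 = keep all,
#'   the default — every void component is counted).
#' @return An object of class `phansalkar_params`.
#' @export
phansalkar_params <- function(radius = 15, k = 0.25, r = 0.5, p = 2.0,
                              q = 10.0, min_deficit_px = 0) {
  if (radius < 1) stop_octa("`radius` must be >= 1")
  if (r <= 0) stop_octa("`r` must be > 0")
  structure(list(radius = as.integer(radius), k = k, r = r, p = p, q = q,
                 min_deficit_px = as.integer(min_deficit_px)),
            class = "phansalkar_params")
}

#' Phansalkar local thresholding of a choriocapillaris image
#'
#' Intensities are normalized to \[0, 1\]; for each pixel the local mean
#' `mu` and population SD `sigma` are computed over a circular window of
#' the given radius (replicated edges) and the threshold is
#' `t = mu * (1 + p * exp(-q * mu) + k * (sigma / r - 1))`. A pixel carries
#' flow iff its normalized value is strictly greater than `t`; everything
#' else is signal void.
#'
#' @param img numeric intensity matrix in \[0, 255\] or an
#'   [en_face_image()].
#' @param params a [phansalkar_params()].
#' @return Logical matrix, `TRUE` = flow; the per-pixel threshold grid is
#'   attached as attribute `"threshold"`.
#' @export
phansalkar_threshold <- function(img, params = phansalkar_params()) {
  if (inherits(img, "octa_image")) img <- img$pixels
  z <- pmin(pmax(img, 0), 255) / 255
  st <- cpp_local_stats_circle(z, params$radius)
  thr <- st$mean * (1 + params$p * exp(-params$q * st$mean) +
                      params$k * (st$sd / params$r - 1))
  structure(z > thr, threshold = thr)
}

#' Particle analysis of signal voids
#'
#' The void mask is the complement of the flow mask; its 8-connected
#' components are labeled and measured. The per-deficit percent areas sum
#' to the total flow-deficit percentage.
#'
#' @param flow_mask logical matrix from [phansalkar_threshold()]
#'   (`TRUE` = flow).
#' @param min_deficit_px drop components smaller than this area (pixels).
#' @param eye_id,acquisition_mode metadata carried into the result.
#' @return An object of class `flow_deficits`: `n_deficits`,
#'   `deficit_areas_px`, `deficit_areas_percent`, `total_fd_percent`.
#' @export
extract_flow_deficits <- function(flow_mask, min_deficit_px = 0,
                                  eye_id = NA_character_,
                                  acquisition_mode = NA_character_) {
  void <- !flow_mask
  lab <- cpp_label8(void)
  n_px <- length(flow_mask)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  if (min_deficit_px > 0) areas <- areas[areas >= min_deficit_px]
  structure(list(
    n_deficits = length(areas),
    deficit_areas_px = as.numeric(areas),
    deficit_areas_percent = 100 * areas / n_px,
    total_fd_percent = 100 * sum(areas) / n_px,
    flow_percent = 100 * sum(flow_mask) / n_px,
    eye_id = eye_id, acquisition_mode = acquisition_mode),
    class = "flow_deficits")
}

#' @export
print.flow_deficits <- function(x, ...) {
  cat(sprintf("<flow_deficits> %s %s: %d deficits, total %.2f%% of frame\n",
              x$eye_id, x$acquisition_mode, x$n_deficits, x$total_fd_percent))
  invisible(x)
}

#' Choriocapillaris flow-deficit metrics of one en face image
#'
#' @param img an [en_face_image()] with `plexus = "CC"`.
#' @param params a [phansalkar_params()].
#' @param keep_maps keep the flow mask in the result.
#' @return A `flow_deficits` object (see [extract_flow_deficits()]).
#' @export
compute_cc_metrics <- function(img, params = phansalkar_params(),
                               keep_maps = FALSE) {
  stopifnot(inherits(img, "octa_image"))
  if (img$plexus != "CC")
    stop_octa("`compute_cc_metrics` applies to CC images, got ", img$plexus)
  flow <- phansalkar_threshold(img, params)
  out <- extract_flow_deficits(flow, params$min_deficit_px,
                               eye_id = img$eye_id,
                               acquisition_mode = img$acquisition_mode)
  if (keep_maps) out$flow_mask <- flow
  out
}
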