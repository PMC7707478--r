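#' Parameters of the dual-path vessel binarization chain
#'
#' @param tophat_radius disk radius (pixels) of the white top-hat used to
#'   flatten background before thresholding. The default (12 px, about
#'   118 um) sits just above the largest expected SCP vessel caliber so
#'   vessels survive background removal.
#' @param vesselness_scales Gaussian scales (pixels) of the Hessian
#'   vesselness filter; the default spans capillary (1 px) to arteriole
#'   (5 px, caliber ~10 px) widths so large-vessel interiors respond.
#' @param huang_levels number of histogram bins used by the Huang fuzzy
#'   threshold (256 = all 8-bit levels, no compaction).
#' @param local_radius half-width (pixels) of the median local threshold
#'   window.
#' @param local_offset intensity offset subtracted from the local median.
#' @param combine_rule how the two path masks are merged: `"AND"`
#'   (intersection, default — suppresses single-path false positives) or
#'   `"OR"`.
#' @return An object of class `binarization_params`.
#' @examples
#' binarization_params(combine_rule = "OR")
#' @export
binarization_params <- function(tophat_radius = 12, vesselness_scales = c(1, 2, 3, 5),
                                huang_levels = 256, local_radius = 15,
                                local_offset = 0, combine_rule = c("AND", "OR")) {
  combine_rule <- match.arg(combine_rule)
  if (tophat_radius < 1 || local_radius < 1)
    stop_octa("radii must be >= 1")
  if (length(vesselness_scales) < 1 || any(vesselness_scales <= 0))
    stop_octa("`vesselness_scales` must be a non-empty vector of positive scales")
  structure(list(tophat_radius = tophat_radius,
                 vesselness_scales = vesselness_scales,
                 huang_levels = as.integer(huang_levels),
                 local_radius = as.integer(local_radius),
                 local_offset = local_offset, combine_rule = combine_rule),
            class = "binarization_params")
}

#' White top-hat background flattening
#'
#' Subtracts the grayscale morphological opening with a disk structuring
#' element (`dx^2 + dy^2 <= radius^2`) from the image, removing background
#' structure larger than the disk while keeping bright features narrower
#' than it. Window positions outside the image are ignored (equivalent to
#' replicate padding for this symmetric flat element). The output is
#' pointwise non-negative and never exceeds the input.
#'
#' @param img numeric intensity matrix.
#' @param radius disk radius in pixels (`>= 1`, and less than half the
#'   smaller image dimension).
#' @return Numeric matrix of the same size.
#' @examples
#' m <- matrix(0, 32, 32); m[15:17, 15:17] <- 200
#' range(top_hat(m, 5) - m)  # small bright square passes unchanged
#' @export
top_hat <- function(img, radius) {
  if (radius < 1) stop_octa("`radius` must be >= 1")
  if (radius >= min(dim(img)) / 2)
    stop_octa("`radius` must be smaller than half the image size")
  cpp_gray_tophat(img, as.integer(radius))
}

#' Hessian (Frangi-type) vesselness filter
#'
#' Per-pixel tubularity score from the eigenvalues of the Gaussian-smoothed
#' Hessian, scale-normalized and maximized over `scales`, then rescaled to
#' \[0, 255\]. With eigenvalues ordered `|l1| <= |l2|`, bright tubes on a
#' dark background have `l2 < 0`; the response is
#' `exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` with blobness
#' `Rb = l1/l2`, second-order structure `S = sqrt(l1^2 + l2^2)`, and `c`
#' set to half the maximum of `S` at each scale. The default `beta = 1`
#' tolerates the blob-like junctions of a dense capillary mesh; smaller
#' values suppress everything but clean straight tubes.
#'
#' @param img numeric intensity matrix.
#' @param scales Gaussian standard deviations (pixels), non-empty.
#' @param beta blobness sensitivity.
#' @return Numeric matrix in \[0, 255\]; flat regions score 0.
#' @export
hessian_vesselness <- function(img, scales = c(1, 2, 3, 5), beta = 1) {
  if (length(scales) < 1) stop_octa("`scales` must be non-empty")
  best <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    r <- ceiling(3 * s)
    x <- (-r):r
    g <- exp(-x^2 / (2 * s^2)); g <- g / sum(g)
    gx <- -x / s^2 * g
    gxx <- (x^2 - s^2) / s^4 * g
    gxx <- gxx - sum(gxx) / length(gxx)   # zero DC: truncation must not leak
    # scale-normalized Hessian (gamma = 2): multiply by s^2
    hrr <- cpp_sep_convolve(img, gxx, g) * s^2   # d^2/dy^2 (rows)
    hcc <- cpp_sep_convolve(img, g, gxx) * s^2   # d^2/dx^2 (cols)
    hrc <- cpp_sep_convolve(img, gx, gx) * s^2
    tr2 <- (hrr + hcc) / 2
    disc <- sqrt(((hrr - hcc) / 2)^2 + hrc^2)
    e1 <- tr2 + disc; e2 <- tr2 - disc
    swap <- abs(e1) > abs(e2)
    lam1 <- ifelse(swap, e2, e1)   # |lam1| <= |lam2|
    lam2 <- ifelse(swap, e1, e2)
    S2 <- lam1^2 + lam2^2
    smax <- max(S2)
    if (smax < 1e-8) next   # numerically flat: derivative-kernel round-off only
    c2 <- smax / 4                 # c = half max Frobenius norm -> c^2 = S2max/4
    rb2 <- ifelse(lam2 != 0, (lam1 / lam2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
    v[lam2 >= 0] <- 0
    best <- pmax(best, v)
  }
  m <- max(best)
  if (m > 0) best <- best * (255 / m)
  best
}

#' Huang fuzzy-entropy global threshold
#'
#' Returns the threshold `t*` minimizing the Huang-Wang fuzzy entropy of the
#' 8-bit histogram. For a candidate `t`, every gray level `g` gets a fuzzy
#' membership `mu(g) = 1 / (1 + |g - m| / C)` where `m` is the mean gray
#' level of the class `g` belongs to (below-or-equal vs above `t`) and `C`
#' is the observed gray-level range; the entropy is
#' `sum_g h(g) * S(mu(g))` with the Shannon pair term
#' `S(u) = -u log u - (1-u) log(1-u)`. All gray levels with both classes
#' non-empty are candidates; ties break to the smallest `t`. Foreground is
#' `value > t*`.
#'
#' @param img numeric intensity matrix; values are rounded to integer gray
#'   levels (8-bit convention). Must contain at least two distinct levels.
#' @param levels number of histogram bins (256 keeps all 8-bit levels).
#' @return The threshold, an integer gray value.
#' @examples
#' img <- matrix(c(rep(30, 60), rep(200, 40)), 10, 10)
#' huang_threshold(img)
#' @export
huang_threshold <- function(img, levels = 256) {
  g <- as.integer(round(img))
  lo <- min(g); hi <- max(g)
  if (lo == hi)
    stop_octa("constant image: Huang threshold undefined")
  h <- tabulate(g - lo + 1L, nbins = hi - lo + 1L)
  vals <- lo:hi
  C <- hi - lo
  cs <- cumsum(h); csv <- cumsum(h * vals)
  ntot <- cs[length(cs)]; stot <- csv[length(csv)]
  cand <- which(cs > 0 & cs < ntot)       # both classes non-empty
  best_t <- NA_integer_; best_e <- Inf
  pair_entropy <- function(u) {
    e <- numeric(length(u))
    ok <- u > 0 & u < 1
    e[ok] <- -u[ok] * log(u[ok]) - (1 - u[ok]) * log(1 - u[ok])
    e
  }
  for (ti in cand) {
    m0 <- csv[ti] / cs[ti]
    m1 <- (stot - csv[ti]) / (ntot - cs[ti])
    mu <- ifelse(seq_along(vals) <= ti,
                 1 / (1 + abs(vals - m0) / C),
                 1 / (1 + abs(vals - m1) / C))
    e <- sum(h * pair_entropy(mu))
    if (e < best_e - 1e-12) { best_e <- e; best_t <- ti }
  }
  vals[best_t]
}

#' Median local threshold
#'
#' A pixel is foreground iff its (8-bit rounded) value exceeds the median of
#' its `(2 radius + 1)` square neighborhood minus `offset`. Edges are
#' handled by replication. On a constant image nothing is foreground
#' (strict inequality).
#'
#' @param img numeric intensity matrix in \[0, 255\].
#' @param radius window half-width in pixels (>= 1).
#' @param offset intensity offset subtracted from the local median.
#' @return Logical matrix.
#' @export
median_local_threshold <- function(img, radius = 15, offset = 0) {
  if (radius < 1) stop_octa("`radius` must be >= 1")
  q <- pmin(pmax(round(img), 0), 255)
  med <- cpp_window_median(q, as.integer(radius))
  q > med - offset
}

#' Combine two binary vessel masks
#'
#' @param a,b logical matrices of identical dimensions.
#' @param rule `"AND"` (intersection) or `"OR"` (union).
#' @return Logical matrix.
#' @export
combine_masks <- function(a, b, rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  if (!all(dim(a) == dim(b)))
    stop_octa("mask dimensions differ: ", paste(dim(a), collapse = "x"),
              " vs ", paste(dim(b), collapse = "x"))
  if (rule == "AND") a & b else a | b
}

#' Dual-path binarization of a retinal plexus image
#'
#' The image is top-hat filtered, then duplicated: path A applies the
#' Hessian vesselness filter followed by Huang fuzzy global thresholding of
#' the vesselness map; path B applies the median local threshold to the
#' top-hat image. The two masks are combined (intersection by default).
#' Every step and its parameters are appended to the `method_chain`.
#'
#' @param img an [en_face_image()] with plexus `"SCP"` or `"DCP"`.
#' @param params a [binarization_params()].
#' @return An object of class `vessel_map`: list with the logical `mask`,
#'   the `method_chain`, and the source image metadata.
#' @export
binarize_plexus <- function(img, params = binarization_params()) {
  stopifnot(inherits(img, "octa_image"), inherits(params, "binarization_params"))
  if (!img$plexus %in% c("SCP", "DCP"))
    stop_octa("`binarize_plexus` applies to SCP/DCP images, got ", img$plexus)
  th <- top_hat(img$pixels, params$tophat_radius)
  vess <- hessian_vesselness(th, params$vesselness_scales)
  t_star <- huang_threshold(vess, params$huang_levels)
  mask_a <- round(vess) > t_star
  mask_b <- median_local_threshold(th, params$local_radius, params$local_offset)
  mask <- combine_masks(mask_a, mask_b, params$combine_rule)
  chain <- list(
    list(step = "top_hat", radius = params$tophat_radius),
    list(step = "hessian_vesselness", scales = params$vesselness_scales),
    list(step = "huang_threshold", levels = params$huang_levels,
         threshold = t_star),
    list(step = "median_local_threshold", radius = params$local_radius,
         offset = params$local_offset),
    list(step = "combine_masks", rule = params$combine_rule))
  structure(list(mask = mask, method_chain = chain,
                 path_masks = list(vesselness = mask_a, median_local = mask_b),
                 plexus = img$plexus, acquisition_mode = img$acquisition_mode,
                 eye_id = img$eye_id, scale = img$scale),
            class = "vessel_map")
}

#' @export
print.vessel_map <- function(x, ...) {
  cat(sprintf("<vessel_map> %s %s %s: %.1f%% foreground, %d-step chain\n",
              x$eye_id, x$plexus, x$acquisition_mode,
              100 * mean(x$mask), length(x$method_chain)))
  invisible(x)
}
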