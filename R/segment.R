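#' Morphological smoothing of a binary mask
#'
#' Opening followed by closing with a disk structuring element, removing
#' speckle smaller than the disk and filling comparable holes. Radius 0 is
#' the identity.
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels (>= 0).
#' @return logical matrix, same shape.
#' @export
smooth_mask <- function(mask, radius = 2L) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop_input("mask must be a logical matrix")
  if (radius < 0L) stop_input("radius must be >= 0")
  if (radius == 0L || !any(mask)) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  m <- matrix(as.numeric(mask), nrow(mask))
  m <- EBImage::closing(EBImage::opening(m, brush), brush)
  matrix(m > 0.5, nrow(mask))
}

#' Segmentation configuration
#'
#' Collects the tunable parameters of [segment_slide()] with the package
#' defaults.
#'
#' @param background_intensity incident light intensity per channel.
#' @param basis 3 x 3 stain matrix (columns haematoxylin, eosin, residual).
#' @param entropy_radius disk radius (px) of the entropy window.
#' @param entropy_mode `"otsu"` or `"fixed"` thresholding of the entropy map.
#' @param entropy_threshold cutoff in bits for the fixed mode.
#' @param smooth_radius disk radius (px) for post-threshold mask smoothing.
#' @param median_radius optional pre-threshold median filter radius (px) on
#'   the stromal signal; 0 disables it.
#' @return list of class `segment_config`.
#' @export
segment_config <- function(background_intensity = 255,
                           basis = ruifrok_basis(),
                           entropy_radius = 5L,
                           entropy_mode = "otsu",
                           entropy_threshold = 4,
                           smooth_radius = 2L,
                           median_radius = 0L) {
  structure(list(background_intensity = background_intensity, basis = basis,
                 entropy_radius = entropy_radius, entropy_mode = entropy_mode,
                 entropy_threshold = entropy_threshold,
                 smooth_radius = smooth_radius, median_radius = median_radius),
            class = "segment_config")
}

#' Estimate the stromal fraction of an H&E image
#'
#' The full segmentation chain: an entropy filter removes the unstained
#' background, colour deconvolution (Ruifrok) separates haematoxylin and
#' eosin, the haematoxylin channel is subtracted from the eosin channel to
#' give a raw stromal signal, which is Otsu-thresholded within tissue and
#' morphologically smoothed. The stromal fraction is the smoothed stromal
#' area over the tissue area. Deterministic given the configuration.
#'
#' @param pixels H x W x 3 RGB array (or a list with a `pixels` element).
#' @param config a [segment_config()].
#' @return object of class `segmentation_result`: list with `tissue_mask`,
#'   `stroma_mask` (logical matrices, `stroma_mask` a subset of
#'   `tissue_mask`), `stromal_fraction` (in \[0, 1\], `NA` when no tissue was
#'   found), `signal` (the raw E - H field), `no_tissue` flag, and pixel
#'   counts.
#' @export
segment_slide <- function(pixels, config = segment_config()) {
  if (is.list(pixels) && !is.null(pixels$pixels)) pixels <- pixels$pixels
  check_rgb(pixels)
  tissue <- entropy_tissue_mask(pixels,
                                window_radius = config$entropy_radius,
                                threshold_mode = config$entropy_mode,
                                fixed_threshold = config$entropy_threshold)
  od <- rgb_to_od(pixels, config$background_intensity)
  dec <- colour_deconvolve(od, config$basis)
  sig <- stromal_signal(dec$concentrations[, , "haematoxylin"],
                        dec$concentrations[, , "eosin"])
  if (config$median_radius > 0L)
    sig <- EBImage::medianFilter(sig - min(sig), config$median_radius) + min(sig)
  n_tissue <- sum(tissue)
  if (n_tissue < 2L || length(unique(sig[tissue])) < 2L) {
    return(structure(list(tissue_mask = tissue,
                          stroma_mask = tissue & FALSE,
                          stromal_fraction = NA_real_, signal = sig,
                          no_tissue = TRUE, tissue_pixels = n_tissue,
                          stroma_pixels = 0L),
                     class = "segmentation_result"))
  }
  thr <- otsu_threshold(sig[tissue])
  stroma <- smooth_mask(tissue & (sig > thr), config$smooth_radius) & tissue
  structure(list(tissue_mask = tissue, stroma_mask = stroma,
                 stromal_fraction = sum(stroma) / n_tissue, signal = sig,
                 no_tissue = FALSE, tissue_pixels = n_tissue,
                 stroma_pixels = sum(stroma)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  if (x$no_tissue) {
    cat("segmentation_result: no tissue detected\n")
  } else {
    cat(sprintf("segmentation_result: stromal fraction %.3f (%d / %d tissue px)\n",
                x$stromal_fraction, x$stroma_pixels, x$tissue_pixels))
  }
  invisible(x)
}

#' Segment a batch of images
#'
#' @param images named list of H x W x 3 RGB arrays.
#' @param config a [segment_config()].
#' @return data.frame with one row per image: `image_id`, `stromal_fraction`,
#'   `tissue_pixels`, `stroma_pixels`, `flags` (`"no_tissue"` or `""`).
#' @export
segment_batch <- function(images, config = segment_config()) {
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(images))
  res <- lapply(images, segment_slide, config = config)
  data.frame(image_id = ids,
             stromal_fraction = vapply(res, `[[`, 0, "stromal_fraction"),
             tissue_pixels = vapply(res, function(r) as.integer(r$tissue_pixels), 0L),
             stroma_pixels = vapply(res, function(r) as.integer(r$stroma_pixels), 0L),
             flags = vapply(res, function(r) if (r$no_tissue) "no_tissue" else "", ""),
             row.names = NULL, stringsAsFactors = FALSE)
}
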