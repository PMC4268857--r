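gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  k <- outer(x, x, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  k / sum(k)
}

smooth_noise_field <- function(h, w, sigma) {
  f <- EBImage::filter2(matrix(rnorm(h * w), h, w), gaussian_kernel(sigma),
                        boundary = "circular")
  as.matrix(f)
}

#' Generate a synthetic H&E-style histology tile with known stromal fraction
#'
#' Forward model for the segmentation pipeline. A tissue region is carved
#' from a smoothed random field; within it a stromal sub-region is carved
#' from a second smoothed field, thresholded at the quantile that makes the
#' achieved stromal fraction match `target_fraction` (within 0.02). Tumour
#' areas are rendered haematoxylin-dominant with nuclear speckles, stroma
#' eosin-dominant with fibrous texture; RGB intensities follow the
#' Beer-Lambert law `I = I0 * 10^(-basis %*% conc)` with Gaussian pixel
#' noise, quantised to 8 bits. Background is near-white and near-uniform so
#' an entropy filter can remove it.
#'
#' @param target_fraction desired stromal share of the tissue area, in
#'   \[0, 1\].
#' @param size tile side in pixels (default 128).
#' @param seed integer seed; the tile is a deterministic function of
#'   (arguments, seed).
#' @param basis stain matrix used for rendering (default [ruifrok_basis()]).
#' @param tissue_coverage approximate share of the tile occupied by tissue.
#' @param noise_sd Gaussian intensity noise added before quantisation.
#' @return list with `pixels` (H x W x 3 integer array), `tissue_mask`,
#'   `stroma_mask` (logical matrices, the ground truth), `true_fraction`
#'   (achieved stroma / tissue), `target_fraction`, `seed`.
#' @export
generate_he_image <- function(target_fraction, size = 128L, seed,
                              basis = ruifrok_basis(),
                              tissue_coverage = 0.8, noise_sd = 2) {
  if (target_fraction < 0 || target_fraction > 1)
    stop_input("target_fraction must lie in [0, 1]")
  if (size < 32L) stop_input("size must be >= 32")
  set.seed(as.integer(seed))
  h <- w <- as.integer(size)

  tissue_field <- smooth_noise_field(h, w, sigma = size / 8)
  tissue <- tissue_field > quantile(tissue_field, 1 - tissue_coverage)
  if (sum(tissue) < 16L) stop_input("degenerate tissue region; raise coverage")

  stroma_field <- smooth_noise_field(h, w, sigma = size / 16)
  inside <- stroma_field[tissue]
  if (target_fraction <= 0) {
    stroma <- tissue & FALSE
  } else if (target_fraction >= 1) {
    stroma <- tissue
  } else {
    thr <- quantile(inside, 1 - target_fraction, names = FALSE)
    stroma <- tissue & (stroma_field > thr)
  }
  achieved <- sum(stroma) / sum(tissue)
  if (abs(achieved - target_fraction) > 0.02)
    stop_input("could not reach target fraction %.2f (achieved %.2f)",
               target_fraction, achieved)

  # stain concentration fields: tumour H-dominant, stroma E-dominant
  conc_h <- matrix(0, h, w); conc_e <- matrix(0, h, w)
  tumour <- tissue & !stroma
  texture <- function(region, base, sd_tex) {
    base + pmax(matrix(rnorm(h * w, 0, sd_tex), h, w), -base)[region]
  }
  conc_h[tumour] <- texture(tumour, 0.65, 0.18)
  conc_e[tumour] <- texture(tumour, 0.20, 0.08)
  conc_h[stroma] <- texture(stroma, 0.15, 0.06)
  conc_e[stroma] <- texture(stroma, 0.70, 0.18)
  # nuclear speckles: sparse punctate haematoxylin excess in tumour
  speck <- matrix(rbinom(h * w, 1, 0.08), h, w) == 1 & tumour
  conc_h[speck] <- conc_h[speck] + 0.5

  od <- array(0, dim = c(h, w, 3))
  flat <- cbind(as.vector(conc_h), as.vector(conc_e), 0)
  od_flat <- flat %*% t(basis)
  for (ch in 1:3) od[, , ch] <- matrix(od_flat[, ch], h, w)

  pixels <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) {
    val <- 255 * 10^(-od[, , ch]) + rnorm(h * w, 0, noise_sd)
    pixels[, , ch] <- as.integer(pmin(pmax(round(val), 0), 255))
  }
  list(pixels = pixels, tissue_mask = tissue, stroma_mask = stroma,
       true_fraction = achieved, target_fraction = target_fraction,
       seed = as.integer(seed))
}

#' Generate a ladder of tiles spanning the stromal-fraction range
#'
#' @param n number of tiles (default 20).
#' @param fractions target fractions (default evenly spaced 0.05 to 0.95).
#' @param seed integer base seed; tile i uses a seed derived from it.
#' @param ... further arguments to [generate_he_image()].
#' @return list of [generate_he_image()] results, named `tile_01` ...
#' @export
generate_he_ladder <- function(n = 20L, fractions = seq(0.05, 0.95,
                                                        length.out = n),
                               seed, ...) {
  stopifnot(length(fractions) == n)
  out <- lapply(seq_len(n), function(i)
    generate_he_image(fractions[i], seed = derive_seed(seed, i), ...))
  names(out) <- sprintf("tile_%02d", seq_len(n))
  out
}
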