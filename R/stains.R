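#' Convert RGB intensities to optical density
#'
#' Applies the Beer-Lambert transform `od = -log10(max(I, 1) / I0)` per
#' channel, so that stain concentrations combine linearly. Intensities equal
#' to the background give zero absorbance; zero intensities are clamped to 1
#' to keep densities finite.
#'
#' @param pixels H x W x 3 array of integer intensities in \[0, 255\].
#' @param background_intensity incident-light intensity per channel (scalar or
#'   length-3), the intensity of a blank (glass-only) pixel. Default 255.
#' @return H x W x 3 array of non-negative optical densities (base 10).
#' @seealso [od_to_rgb()], [colour_deconvolve()]
#' @export
rgb_to_od <- function(pixels, background_intensity = 255) {
  check_rgb(pixels)
  i0 <- background_intensity
  if (length(i0) == 1L) i0 <- rep(i0, 3L)
  if (length(i0) != 3L || any(i0 <= 0) || any(i0 > 255))
    stop_input("background_intensity must be in [1, 255] (scalar or length 3)")
  od <- pixels
  for (ch in 1:3)
    od[, , ch] <- -log10(pmax(pixels[, , ch], 1) / i0[ch])
  pmax(od, 0)
}

#' Render optical densities back to RGB intensities
#'
#' Inverse Beer-Lambert transform, quantised to 8-bit integers.
#'
#' @param od H x W x 3 array of non-negative optical densities.
#' @param background_intensity incident intensity per channel, as in
#'   [rgb_to_od()].
#' @return H x W x 3 integer array in \[0, 255\].
#' @export
od_to_rgb <- function(od, background_intensity = 255) {
  i0 <- background_intensity
  if (length(i0) == 1L) i0 <- rep(i0, 3L)
  rgb <- od
  for (ch in 1:3)
    rgb[, , ch] <- i0[ch] * 10^(-od[, , ch])
  array(as.integer(pmin(pmax(round(rgb), 0), 255)), dim = dim(od))
}

#' Ruifrok H&E stain basis
#'
#' The published haematoxylin and eosin optical-density vectors of Ruifrok &
#' Johnston, unit-normalised, with a residual third vector completed by the
#' cross product so the basis is invertible.
#'
#' @return 3 x 3 matrix whose columns are unit OD stain vectors, named
#'   `haematoxylin`, `eosin`, `residual`.
#' @export
ruifrok_basis <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  stain_basis(cbind(haematoxylin = h, eosin = e))
}

#' Build a stain basis matrix
#'
#' Accepts 2 or 3 stain OD vectors (columns), unit-normalises them and, for a
#' 2-stain basis, completes a residual third vector orthogonal to both.
#'
#' @param vectors 3 x 2 or 3 x 3 numeric matrix, one stain per column,
#'   non-negative OD components.
#' @return 3 x 3 invertible matrix of unit columns.
#' @export
stain_basis <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != 3L || !ncol(vectors) %in% 2:3)
    stop_input("stain vectors must form a 3 x 2 or 3 x 3 matrix")
  if (any(vectors < 0)) stop_input("stain OD components must be non-negative")
  nrm <- sqrt(colSums(vectors^2))
  if (any(nrm == 0)) stop_input("zero-length stain vector")
  vectors <- sweep(vectors, 2, nrm, "/")
  if (ncol(vectors) == 2L) {
    res <- c(vectors[2, 1] * vectors[3, 2] - vectors[3, 1] * vectors[2, 2],
             vectors[3, 1] * vectors[1, 2] - vectors[1, 1] * vectors[3, 2],
             vectors[1, 1] * vectors[2, 2] - vectors[2, 1] * vectors[1, 2])
    res <- abs(res)  # OD components are absorbances, keep them non-negative
    res <- res / sqrt(sum(res^2))
    vectors <- cbind(vectors, residual = res)
  }
  if (abs(det(vectors)) < 1e-8)
    stop_input("stain vectors are linearly dependent; basis not invertible")
  vectors
}

#' Colour deconvolution of an optical-density image
#'
#' Inverts the stain-mixing linear system `od = basis %*% conc` per pixel
#' (Ruifrok & Johnston), recovering one concentration channel per stain.
#'
#' @param od H x W x 3 optical-density array from [rgb_to_od()].
#' @param basis 3 x 3 stain matrix, columns unit OD vectors; see
#'   [stain_basis()]. Default [ruifrok_basis()].
#' @return list with `concentrations` (H x W x 3 array, one slice per stain,
#'   named as the basis columns) and `residual_rms`, the root-mean-square
#'   reconstruction error (0 up to floating point for an exact 3-stain model).
#' @export
colour_deconvolve <- function(od, basis = ruifrok_basis()) {
  if (length(dim(od)) != 3L || dim(od)[3] != 3L)
    stop_input("od must be an H x W x 3 array")
  basis <- as.matrix(basis)
  if (!all(dim(basis) == c(3L, 3L)) || abs(det(basis)) < 1e-8)
    stop_input("basis must be an invertible 3 x 3 matrix")
  d <- dim(od)
  flat <- matrix(od, ncol = 3L)            # pixels x channels
  conc <- flat %*% t(solve(basis))         # solves basis %*% c = od row-wise
  recon <- conc %*% t(basis)
  out <- array(conc, dim = d)
  dimnames(out) <- list(NULL, NULL, colnames(basis))
  list(concentrations = out,
       residual_rms = sqrt(mean((recon - flat)^2)))
}

#' Raw stromal signal from stain channels
#'
#' Eosin minus haematoxylin concentration per pixel: eosinophilic (fibrous,
#' stromal) regions come out positive, nuclei-dense tumour regions negative.
#'
#' @param h_channel,e_channel numeric matrices of identical shape.
#' @return matrix of the signed stromal signal.
#' @export
stromal_signal <- function(h_channel, e_channel) {
  if (!identical(dim(h_channel), dim(e_channel)))
    stop_input("haematoxylin and eosin channels must have identical shape")
  e_channel - h_channel
}
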