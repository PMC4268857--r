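disk_kernel <- function(radius) {
  sz <- 2L * radius + 1L
  cc <- radius + 1L
  k <- outer(seq_len(sz), seq_len(sz),
             function(i, j) (i - cc)^2 + (j - cc)^2 <= radius^2)
  storage.mode(k) <- "double"
  k
}

rgb_to_gray256 <- function(pixels) {
  g <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
  matrix(as.integer(pmin(pmax(round(g), 0), 255)), nrow = dim(pixels)[1])
}

#' Local Shannon entropy of a grayscale image
#'
#' For each pixel, the entropy (in bits) of the 256-level gray histogram in a
#' disk window centred on it. Computed by convolving one indicator image per
#' occurring gray level with the disk kernel, which is exact and avoids a
#' per-pixel loop. Boundaries are handled by replicating edge pixels.
#'
#' @param gray integer matrix of gray levels in \[0, 255\].
#' @param radius disk window radius in pixels (>= 1).
#' @return matrix of local entropies in bits, same shape as `gray`.
#' @export
local_entropy <- function(gray, radius = 5L) {
  if (radius < 1L) stop_input("window radius must be >= 1")
  if (min(dim(gray)) < 2L * radius + 1L)
    stop_input("image (%d x %d) smaller than the entropy window (%d px)",
               nrow(gray), ncol(gray), 2L * radius + 1L)
  kern <- disk_kernel(radius)
  total <- sum(kern)
  levels <- sort(unique(as.vector(gray)))
  acc <- matrix(0, nrow(gray), ncol(gray))
  for (g in levels) {
    ind <- matrix(as.numeric(gray == g), nrow(gray))
    cnt <- EBImage::filter2(ind, kern, boundary = "replicate")
    p <- pmin(pmax(cnt / total, 0), 1)   # FFT round-off guard
    term <- ifelse(p > 1e-12, -p * log2(p), 0)
    acc <- acc + term
  }
  acc
}

#' Entropy-based tissue mask
#'
#' Background (bare glass) is nearly uniform and has almost zero local
#' entropy; stained tissue is textured and does not. Pixels whose local
#' entropy exceeds a threshold are marked as tissue. The threshold is either
#' fixed (in bits) or chosen by Otsu's method on the entropy map.
#'
#' @param pixels H x W x 3 RGB array.
#' @param window_radius disk radius in pixels for the entropy window.
#' @param threshold_mode `"otsu"` (adaptive, default) or `"fixed"`.
#' @param fixed_threshold entropy cutoff in bits when `threshold_mode =
#'   "fixed"`.
#' @return logical H x W matrix, TRUE for tissue.
#' @export
entropy_tissue_mask <- function(pixels, window_radius = 5L,
                                threshold_mode = c("otsu", "fixed"),
                                fixed_threshold = 4) {
  check_rgb(pixels)
  threshold_mode <- match.arg(threshold_mode)
  ent <- local_entropy(rgb_to_gray256(pixels), radius = window_radius)
  if (threshold_mode == "fixed") {
    thr <- fixed_threshold
  } else {
    if (max(ent) - min(ent) < 1e-9) return(ent > max(ent))  # flat: no tissue
    thr <- otsu_threshold(as.vector(ent))
  }
  ent > thr
}

#' Otsu's threshold
#'
#' The histogram threshold maximising the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over candidate bin edges, as used throughout the
#' segmentation pipeline (tissue masking and stromal-signal splitting).
#'
#' @param values numeric vector (e.g. stromal-signal values restricted to
#'   tissue pixels). Must contain at least two distinct values.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold value (a bin edge); classify as `value > threshold`.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop_input("need at least two values")
  rng <- range(values)
  if (diff(rng) == 0)
    stop_input("all values identical; threshold undefined")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bins <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
               n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  sums <- numeric(n_bins)
  rs <- rowsum(values, bins)
  sums[as.integer(rownames(rs))] <- rs
  # class statistics per candidate edge, exact (no bin-midpoint approximation)
  n0 <- cumsum(counts)
  s0 <- cumsum(sums)
  n1 <- length(values) - n0
  m0 <- s0 / pmax(n0, 1)
  m1 <- (sum(values) - s0) / pmax(n1, 1)
  bcv <- n0 * n1 * (m0 - m1)^2
  bcv[n0 == 0 | n1 == 0] <- -Inf
  edges[which.max(bcv) + 1L]   # upper edge of the best split bin
}
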