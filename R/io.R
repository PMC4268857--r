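#' Read a gene x sample expression TSV
#'
#' Genes in rows (first column = gene id), header = sample ids, log2 values.
#' Duplicate gene ids or missing values are schema errors.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_input("%s: need a gene column plus samples", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop_input("%s: duplicate gene id '%s'", path, ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_input("%s: non-numeric expression values", path)
  if (anyNA(m)) stop_input("%s: missing expression values", path)
  rownames(m) <- ids
  m
}

#' @rdname read_expression_tsv
#' @param expr matrix to write.
#' @param path output path.
#' @export
write_expression_tsv <- function(expr, path) {
  check_expression(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids,
#' tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop_input("%s: line %d malformed (name, description, >= 1 gene)", path, i)
    genes <- unique(parts[-(1:2)])
    if (length(genes) == 0L) stop_input("%s: line %d has no genes", path, i)
    sets[[parts[1]]] <- genes
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write clinical CSV tables
#'
#' Schema: `id, entry_time, exit_time, event` plus covariate columns.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical_csv <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "entry_time", "exit_time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_input("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  bad <- which(df$exit_time < df$entry_time)
  if (length(bad) > 0L)
    stop_input("%s: exit before entry at row %d", path, bad[1])
  df
}

#' @rdname read_clinical_csv
#' @param table data.frame to write.
#' @export
write_clinical_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write RGB images as PNG
#'
#' 8-bit RGB; the integer-array convention of the segmentation functions.
#'
#' @param path file path.
#' @return H x W x 3 integer array.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  array(as.integer(round(a * 255)), dim = dim(a))
}

#' @rdname read_image_png
#' @param pixels H x W x 3 integer array in \[0, 255\].
#' @export
write_image_png <- function(pixels, path) {
  check_rgb(pixels)
  png::writePNG(pixels / 255, path)
  invisible(path)
}

#' Read an RGB image from TIFF
#'
#' 8-bit RGB TIFF tiles, returned in the same integer-array convention as
#' [read_image_png()]. Requires the tiff package.
#'
#' @param path file path.
#' @return H x W x 3 integer array.
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_input("the tiff package is required to read TIFF images")
  if (!file.exists(path)) stop_input("no such file: %s", path)
  a <- tiff::readTIFF(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  array(as.integer(round(a * 255)), dim = dim(a))
}

#' Write a binary mask as a 0/255 grayscale PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' Write an overlay PNG with stroma tinted green
#'
#' @param pixels H x W x 3 image.
#' @param stroma_mask logical matrix of stromal pixels.
#' @param path output path.
#' @export
write_overlay_png <- function(pixels, stroma_mask, path) {
  check_rgb(pixels)
  img <- pixels / 255
  g <- img[, , 2]
  g[stroma_mask] <- pmin(1, g[stroma_mask] * 0.4 + 0.6)
  img[, , 2] <- g
  img[, , 1][stroma_mask] <- img[, , 1][stroma_mask] * 0.4
  img[, , 3][stroma_mask] <- img[, , 3][stroma_mask] * 0.4
  png::writePNG(img, path)
  invisible(path)
}

#' Write per-image stromal fractions as TSV
#'
#' @param fractions data.frame from [segment_batch()].
#' @param path output path.
#' @export
write_fractions_tsv <- function(fractions, path) {
  write.table(fractions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
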