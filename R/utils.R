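#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile median sd var cor cor.test p.adjust pt rnorm
#'   runif rbinom rbeta rexp lm coef fisher.test chisq.test wilcox.test
#'   t.test hclust dist pnorm setNames
#' @importFrom utils head read.delim write.table read.csv write.csv
NULL

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# shared validation for H x W x 3 integer-intensity arrays
check_rgb <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_input("expected an H x W x 3 RGB array, got dims [%s]",
               paste(dim(pixels), collapse = ", "))
  if (dim(pixels)[1] < 32L || dim(pixels)[2] < 32L)
    stop_input("image must be at least 32 x 32 pixels")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_input("RGB intensities must lie in [0, 255] with no missing values")
  invisible(pixels)
}

check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop_input("expression must be a numeric gene x sample matrix")
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr)))
    stop_input("expression matrix needs unique gene ids as rownames")
  if (is.null(colnames(expr)))
    stop_input("expression matrix needs sample ids as colnames")
  if (anyNA(expr))
    stop_input("expression matrix contains missing values; impute at load time")
  invisible(expr)
}

# deterministic child seeds below 2^31 for staged generators
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset) * 104729L) %% 2147483629L
}
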