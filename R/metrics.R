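#' Mean squared error between two images
#'
#' @param x,reference numeric matrices of equal shape.
#' @return scalar mean of squared differences.
#' @export
mse <- function(x, reference) {
  if (!all(dim(x) == dim(reference))) stop("shape mismatch")
  mean((x - reference)^2)
}

#' Extract a horizontal line profile
#'
#' Returns the pixel values of one image row. Indexing is 1-based, matching
#' the convention "the 128th line" for a 256 x 256 image.
#'
#' @param image numeric matrix.
#' @param row_index 1-based row number.
#' @return numeric vector of length `ncol(image)`.
#' @export
line_profile <- function(image, row_index) {
  row_index <- as.integer(row_index)
  if (row_index < 1L || row_index > nrow(image)) stop("row index out of range")
  image[row_index, ]
}
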