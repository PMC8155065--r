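# Binary morphology. EBImage provides the engine; pixels outside the image
# are treated as unset for both erosion and dilation, so masks are
# zero-padded by the kernel radius before each operation and cropped after
# (EBImage's own border convention is replicate, which would keep border
# pixels alive under erosion).

#' Create a structuring element
#'
#' @param shape `"square"` (all-ones) or `"cross"` (4-connected plus shape).
#' @param size odd side length in pixels, >= 1.
#' @return An object of class `struct_element` wrapping a 0/1 kernel matrix.
#' @export
struct_element <- function(shape = c("square", "cross"), size = 3L) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) {
    abort("structuring element size must be odd and >= 1",
          class = "pdl1ic_value_error")
  }
  kern <- if (shape == "square") {
    matrix(1, size, size)
  } else {
    r <- (size - 1L) / 2L
    outer(seq_len(size), seq_len(size),
          function(i, j) as.numeric(abs(i - r - 1L) + abs(j - r - 1L) <= r))
  }
  structure(list(shape = shape, size = size, kernel = kern),
            class = "struct_element")
}

#' Disc-shaped structuring element
#'
#' @param radius disc radius in pixels; the kernel is `2*radius+1` square.
#' @return A `struct_element` with shape `"disc"`.
#' @export
disc_element <- function(radius) {
  radius <- as.integer(radius)
  stopifnot(radius >= 1)
  size <- 2L * radius + 1L
  kern <- EBImage::makeBrush(size, shape = "disc")
  structure(list(shape = "disc", size = size, kernel = kern),
            class = "struct_element")
}

#' @export
print.struct_element <- function(x, ...) {
  cat(sprintf("<struct_element %s %dx%d>\n", x$shape, x$size, x$size))
  invisible(x)
}

pad_zero <- function(bits, r) {
  out <- matrix(FALSE, nrow(bits) + 2 * r, ncol(bits) + 2 * r)
  out[(r + 1):(r + nrow(bits)), (r + 1):(r + ncol(bits))] <- bits
  out
}

crop_pad <- function(bits, r, d) {
  bits[(r + 1):(r + d[1]), (r + 1):(r + d[2])]
}

morph_bits <- function(bits, kern, op) {
  r <- (nrow(kern) - 1L) %/% 2L
  d <- dim(bits)
  if (r == 0L) return(bits)
  padded <- pad_zero(bits, r)
  img <- EBImage::Image(padded * 1.0)
  res <- if (op == "erode") EBImage::erode(img, kern) else EBImage::dilate(img, kern)
  crop_pad(EBImage::imageData(res) > 0.5, r, d)
}

erode_bits <- function(bits, elem) morph_bits(bits, elem$kernel, "erode")
dilate_bits <- function(bits, elem) morph_bits(bits, elem$kernel, "dilate")

#' Erode a binary mask
#'
#' @param mask a `binary_mask`.
#' @param elem a `struct_element`.
#' @return A `binary_mask` with the same role.
#' @export
erode_mask <- function(mask, elem = struct_element("square", 3)) {
  stopifnot(inherits(mask, "binary_mask"), inherits(elem, "struct_element"))
  binary_mask(erode_bits(mask$bits, elem), role = mask$role)
}

#' Dilate a binary mask
#'
#' @inheritParams erode_mask
#' @return A `binary_mask` with the same role.
#' @export
dilate_mask <- function(mask, elem = struct_element("square", 3)) {
  stopifnot(inherits(mask, "binary_mask"), inherits(elem, "struct_element"))
  binary_mask(dilate_bits(mask$bits, elem), role = mask$role)
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with the same element; used for the
#' aggregation-hull area of clustered immune cells.
#'
#' @inheritParams erode_mask
#' @return A `binary_mask` with the same role.
#' @export
close_mask <- function(mask, elem) {
  stopifnot(inherits(mask, "binary_mask"), inherits(elem, "struct_element"))
  # closing must be extensive: pad by the full kernel radius before the
  # dilate so the erode cannot eat back past the original support at borders
  r <- (nrow(elem$kernel) - 1L) %/% 2L
  d <- dim(mask$bits)
  padded <- pad_zero(mask$bits, r)
  out <- morph_bits(morph_bits(padded, elem$kernel, "dilate"), elem$kernel, "erode")
  binary_mask(crop_pad(out | padded, r, d), role = mask$role)
}
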