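# Image containers and I/O.
#
# Pixel arrays are row-major with the origin at the top-left: pixels[i, j, ]
# is image row i (from the top), column j (from the left), 0-based concepts
# map to 1-based R indices. Channel values are 8-bit integers in [0, 255].

MASK_ROLES <- c("stain", "epithelium", "necrotic", "ic", "other")

# Supported HSV scale conventions. "hue179" is the common 8-bit
# computer-vision convention (hue in 0-179 = degrees/2, S and V in 0-255);
# "hue255" rescales all three channels to 0-255.
HSV_CONVENTIONS <- list(
  hue179 = c(h = 179, s = 255, v = 255),
  hue255 = c(h = 255, s = 255, v = 255)
)

hsv_convention_max <- function(convention) {
  if (!convention %in% names(HSV_CONVENTIONS)) {
    abort(paste0("unknown HSV scale convention '", convention, "'; supported: ",
                 paste(names(HSV_CONVENTIONS), collapse = ", ")),
          class = "pdl1ic_config_error")
  }
  HSV_CONVENTIONS[[convention]]
}

#' Create an RGB image patch
#'
#' The unit of scoring: an 8-bit RGB raster with optional physical pixel
#' size. Values must be integers in \[0, 255\].
#'
#' @param pixels numeric H x W x 3 array of 8-bit intensities.
#' @param pixel_size_um optional micrometers-per-pixel metadata.
#' @param source_id optional free-text provenance tag.
#' @return An object of class `rgb_patch`.
#' @export
rgb_patch <- function(pixels, pixel_size_um = NULL, source_id = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    abort("pixels must be an H x W x 3 array", class = "pdl1ic_format_error")
  }
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1) {
    abort("patch must have H >= 1 and W >= 1", class = "pdl1ic_format_error")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("channel values must lie in [0, 255]", class = "pdl1ic_format_error")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um, source_id = source_id),
    class = "rgb_patch"
  )
}

#' @export
dim.rgb_patch <- function(x) dim(x$pixels)[1:2]

#' @export
print.rgb_patch <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_patch %d x %d%s%s>\n", d[1], d[2],
              if (!is.null(x$pixel_size_um))
                sprintf(", %.3f um/px", x$pixel_size_um) else "",
              if (!is.null(x$source_id))
                sprintf(", '%s'", x$source_id) else ""))
  invisible(x)
}

#' Create a binary mask
#'
#' Per-pixel boolean layer with a role tag. All mask algebra in the package
#' operates on these.
#'
#' @param bits logical H x W matrix.
#' @param role one of `"stain"`, `"epithelium"`, `"necrotic"`, `"ic"`,
#'   `"other"`. Fixed at creation.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(bits, role = "other") {
  if (!is.matrix(bits)) abort("bits must be a matrix", class = "pdl1ic_format_error")
  role <- match.arg(role, MASK_ROLES)
  storage.mode(bits) <- "logical"
  if (anyNA(bits)) abort("mask bits must not contain NA", class = "pdl1ic_format_error")
  structure(list(bits = bits, role = role), class = "binary_mask")
}

#' @export
dim.binary_mask <- function(x) dim(x$bits)

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<binary_mask role=%s %d x %d, %d set (%.2f%%)>\n",
              x$role, d[1], d[2], sum(x$bits), 100 * mean(x$bits)))
  invisible(x)
}

#' Area fraction of a binary mask
#'
#' @param mask a `binary_mask`.
#' @return Set-pixel count divided by total pixel count.
#' @export
mask_area_fraction <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  mean(mask$bits)
}

check_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    abort(paste0(what, " dimensions differ: ",
                 paste(dim(a), collapse = "x"), " vs ",
                 paste(dim(b), collapse = "x")),
          class = "pdl1ic_shape_error")
  }
  invisible(TRUE)
}

read_raster <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "pdl1ic_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e) abort(paste0("cannot read TIFF: ", conditionMessage(e)),
                                              class = "pdl1ic_io_error"))
    bits <- attr(img, "bits.per.sample")
  } else {
    img <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) abort(paste0("cannot read PNG: ", conditionMessage(e)),
                                              class = "pdl1ic_io_error"))
    bits <- attr(img, "info")$bit.depth
  }
  if (!is.null(bits) && any(bits != 8)) {
    abort(paste0("image is ", paste(unique(bits), collapse = "/"),
                 "-bit; only 8-bit rasters are supported"),
          class = "pdl1ic_format_error")
  }
  img
}

#' Read an RGB patch from a PNG or TIFF file
#'
#' Only 8-bit rasters are accepted; an alpha channel, if present, is
#' dropped. Single-channel images are rejected (use [read_mask()]).
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @param pixel_size_um optional micrometers-per-pixel metadata to attach.
#' @return An `rgb_patch`.
#' @export
read_patch <- function(path, pixel_size_um = NULL) {
  img <- read_raster(path)
  if (length(dim(img)) != 3 || dim(img)[3] < 3) {
    nch <- if (length(dim(img)) == 2) 1L else dim(img)[3]
    abort(paste0("image has ", nch, " channel(s); expected 3-channel RGB"),
          class = "pdl1ic_format_error")
  }
  px <- round(img[, , 1:3, drop = FALSE] * 255)
  rgb_patch(px, pixel_size_um = pixel_size_um, source_id = basename(path))
}

#' Write an RGB patch to a PNG or TIFF file
#'
#' @param patch an `rgb_patch`.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_patch <- function(patch, path) {
  stopifnot(inherits(patch, "rgb_patch"))
  arr <- patch$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  else png::writePNG(arr, path)
  invisible(path)
}

#' Read a binary mask from a single-channel PNG
#'
#' Masks are stored as single-channel 8-bit PNGs with 0/255 encoding;
#' any value above 127 reads as set.
#'
#' @param path file path.
#' @param role role tag for the resulting mask.
#' @return A `binary_mask`.
#' @export
read_mask <- function(path, role = "other") {
  img <- read_raster(path)
  if (length(dim(img)) == 3) {
    abort(paste0("mask image has ", dim(img)[3],
                 " channels; expected single-channel PNG"),
          class = "pdl1ic_format_error")
  }
  binary_mask(img > 0.5, role = role)
}

#' Write a binary mask to a single-channel PNG (0/255)
#'
#' @param mask a `binary_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$bits * 1.0, path)
  invisible(path)
}

#' Convert an RGB patch to HSV under a named scale convention
#'
#' Standard per-pixel RGB-to-HSV mapping, with channels rescaled to the
#' convention's integer ranges. Under `"hue179"` hue is degrees/2 in 0-179
#' with S and V in 0-255; under `"hue255"` all channels span 0-255.
#'
#' @param patch an `rgb_patch`.
#' @param convention `"hue179"` (default) or `"hue255"`.
#' @return An object of class `hsv_patch` with integer channel matrices
#'   `h`, `s`, `v` and the convention name.
#' @export
rgb_to_hsv_patch <- function(patch, convention = "hue179") {
  stopifnot(inherits(patch, "rgb_patch"))
  mx <- hsv_convention_max(convention)
  d <- dim(patch)
  rgbm <- rbind(as.vector(patch$pixels[, , 1]),
                as.vector(patch$pixels[, , 2]),
                as.vector(patch$pixels[, , 3]))
  hsvf <- rgb2hsv(rgbm, maxColorValue = 255)  # all channels as fractions
  h <- if (mx["h"] == 179) round(hsvf[1, ] * 180) %% 180 else round(hsvf[1, ] * 255)
  s <- round(hsvf[2, ] * mx["s"])
  v <- round(hsvf[3, ] * mx["v"])
  mk <- function(x) {
    m <- matrix(as.integer(x), nrow = d[1], ncol = d[2])
    m
  }
  structure(list(h = mk(h), s = mk(s), v = mk(v), convention = convention),
            class = "hsv_patch")
}

#' @export
dim.hsv_patch <- function(x) dim(x$h)

#' @export
print.hsv_patch <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<hsv_patch %d x %d, convention=%s>\n", d[1], d[2], x$convention))
  invisible(x)
}

#' Overlay a mask on a patch for QC rendering
#'
#' Masked pixels are alpha-blended with `color`; unmasked pixels are
#' untouched. With `alpha = 1` masked pixels become exactly `color`.
#'
#' @param patch an `rgb_patch`.
#' @param mask a `binary_mask` of the same dimensions.
#' @param color RGB triple in \[0, 255\].
#' @param alpha blend weight of the overlay color in \[0, 1\].
#' @return A new `rgb_patch`.
#' @export
render_overlay <- function(patch, mask, color = c(255L, 0L, 0L), alpha = 0.5) {
  stopifnot(inherits(patch, "rgb_patch"), inherits(mask, "binary_mask"))
  check_same_dim(patch, mask, "patch/mask")
  stopifnot(length(color) == 3, alpha >= 0, alpha <= 1)
  px <- patch$pixels
  sel <- mask$bits
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[sel] <- as.integer(round((1 - alpha) * plane[sel] + alpha * color[ch]))
    px[, , ch] <- plane
  }
  rgb_patch(px, pixel_size_um = patch$pixel_size_um, source_id = patch$source_id)
}
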