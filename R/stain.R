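# Stained-pixel detection: HSV threshold box, 95%-coverage calibration,
# and morphological denoising of the raw stain mask.

#' Create an HSV threshold box
#'
#' Six inclusive channel bounds defining stained-pixel membership, expressed
#' in a named HSV scale convention.
#'
#' @param h_lo,h_hi,s_lo,s_hi,v_lo,v_hi channel bounds (lo <= hi), within
#'   the convention's range.
#' @param convention HSV scale convention, see [rgb_to_hsv_patch()].
#' @return An object of class `hsv_box`.
#' @export
hsv_box <- function(h_lo, h_hi, s_lo, s_hi, v_lo, v_hi, convention = "hue179") {
  mx <- hsv_convention_max(convention)
  b <- c(h_lo = h_lo, h_hi = h_hi, s_lo = s_lo, s_hi = s_hi,
         v_lo = v_lo, v_hi = v_hi)
  if (anyNA(b)) abort("threshold bounds must not be NA", class = "pdl1ic_value_error")
  if (h_lo > h_hi || s_lo > s_hi || v_lo > v_hi) {
    abort("threshold box requires lo <= hi on every channel",
          class = "pdl1ic_value_error")
  }
  lims <- c(mx["h"], mx["h"], mx["s"], mx["s"], mx["v"], mx["v"])
  if (any(b < 0) || any(b > lims)) {
    abort(paste0("threshold bounds exceed the '", convention, "' channel ranges"),
          class = "pdl1ic_value_error")
  }
  structure(c(as.list(b), list(convention = convention)), class = "hsv_box")
}

#' @export
print.hsv_box <- function(x, ...) {
  cat(sprintf("<hsv_box h[%g,%g] s[%g,%g] v[%g,%g] (%s)>\n",
              x$h_lo, x$h_hi, x$s_lo, x$s_hi, x$v_lo, x$v_hi, x$convention))
  invisible(x)
}

#' Default SP142 DAB-stain threshold box
#'
#' The hue/saturation/value box \[101, 175\] / \[40, 120\] / \[40, 150\]
#' (hue 0-179, S and V 0-255) used to detect PD-L1 (SP142) stained immune
#' cell pixels.
#'
#' @return An `hsv_box` in the `"hue179"` convention.
#' @export
sp142_threshold_box <- function() {
  hsv_box(101, 175, 40, 120, 40, 150, convention = "hue179")
}

#' Threshold an HSV patch into a stain mask
#'
#' A pixel is set iff all three channel values lie inside the box (bounds
#' inclusive on both ends). Purely per-pixel and deterministic.
#'
#' @param hsv an `hsv_patch`.
#' @param box an `hsv_box` in the same scale convention.
#' @return A `binary_mask` with role `"stain"`.
#' @export
threshold_hsv <- function(hsv, box = sp142_threshold_box()) {
  stopifnot(inherits(hsv, "hsv_patch"), inherits(box, "hsv_box"))
  if (!identical(hsv$convention, box$convention)) {
    abort(paste0("scale convention mismatch: patch is '", hsv$convention,
                 "', box is '", box$convention, "'"),
          class = "pdl1ic_config_error")
  }
  bits <- hsv$h >= box$h_lo & hsv$h <= box$h_hi &
    hsv$s >= box$s_lo & hsv$s <= box$s_hi &
    hsv$v >= box$v_lo & hsv$v <= box$v_hi
  binary_mask(bits, role = "stain")
}

#' Calibrate an HSV threshold box from annotated stained pixels
#'
#' Per channel independently, returns the symmetric-quantile interval
#' \[q\_{(1-c)/2}, q\_{(1+c)/2}\] at coverage `c` (2.5% trimmed from each
#' tail at the default 0.95), using the inverse-ECDF quantile so the box is
#' guaranteed to contain at least the requested fraction of pixels on every
#' channel.
#'
#' @param pixels data frame (or matrix) of annotated stained-pixel HSV
#'   values with columns `h`, `s`, `v`.
#' @param coverage target per-channel coverage fraction in (0, 1\].
#' @param convention scale convention the pixel values are expressed in.
#' @return An `hsv_box`.
#' @export
calibrate_thresholds <- function(pixels, coverage = 0.95, convention = "hue179") {
  if (is.matrix(pixels)) pixels <- as.data.frame(pixels)
  if (!all(c("h", "s", "v") %in% names(pixels))) {
    abort("pixels must have columns h, s, v", class = "pdl1ic_value_error")
  }
  if (nrow(pixels) == 0) {
    abort("cannot calibrate thresholds from an empty pixel collection",
          class = "pdl1ic_value_error")
  }
  if (!(coverage > 0 && coverage <= 1)) {
    abort("coverage must lie in (0, 1]", class = "pdl1ic_value_error")
  }
  lo_p <- (1 - coverage) / 2
  hi_p <- (1 + coverage) / 2
  qs <- function(x) unname(quantile(x, c(lo_p, hi_p), type = 1, names = FALSE))
  h <- qs(pixels$h); s <- qs(pixels$s); v <- qs(pixels$v)
  hsv_box(h[1], h[2], s[1], s[2], v[1], v[2], convention = convention)
}

#' Denoise a stain mask by morphological opening
#'
#' Erosion with `erode_elem` removes small speckle noise; dilation with
#' `dilate_elem` restores the surviving stained regions.
#'
#' @param mask a `binary_mask` with role `"stain"`.
#' @param erode_elem,dilate_elem structuring elements (3x3 square by
#'   default).
#' @return A denoised `binary_mask` with role `"stain"`.
#' @export
denoise_mask <- function(mask,
                         erode_elem = struct_element("square", 3),
                         dilate_elem = struct_element("square", 3)) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask$role != "stain") {
    abort("denoise_mask expects a mask with role 'stain'",
          class = "pdl1ic_value_error")
  }
  dilate_mask(erode_mask(mask, erode_elem), dilate_elem)
}
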