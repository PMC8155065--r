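# IC scoring: mask combination, gap-filling iterative dilation, the IC
# area ratio, and categorical binning.

#' Combine stain and region masks into the effective IC mask
#'
#' A pixel belongs to the immune-cell mask iff it is stained and lies in
#' neither the epithelial nor the necrotic region:
#' `M_IC = M_stain AND NOT (M_epithelium OR M_necrotic)`.
#'
#' @param stain `binary_mask` with role `"stain"`.
#' @param epithelium `binary_mask` with role `"epithelium"`.
#' @param necrotic `binary_mask` with role `"necrotic"`.
#' @return A `binary_mask` with role `"ic"`.
#' @export
combine_masks <- function(stain, epithelium, necrotic) {
  for (m in list(stain, epithelium, necrotic)) stopifnot(inherits(m, "binary_mask"))
  if (stain$role != "stain" || epithelium$role != "epithelium" ||
      necrotic$role != "necrotic") {
    abort("combine_masks requires roles stain / epithelium / necrotic",
          class = "pdl1ic_value_error")
  }
  check_same_dim(stain, epithelium, "stain/epithelium masks")
  check_same_dim(stain, necrotic, "stain/necrotic masks")
  binary_mask(stain$bits & !(epithelium$bits | necrotic$bits), role = "ic")
}

#' Iteratively dilate a mask
#'
#' Applies the kernel dilation `iterations` times; used to fill the space
#' between stained cells so aggregated immune-cell regions are scored by
#' their enclosing area. Zero iterations returns the input unchanged.
#'
#' @param mask a `binary_mask`.
#' @param iterations nonnegative integer.
#' @param elem structuring element (3x3 square by default).
#' @return A `binary_mask` with the same role.
#' @export
iterative_dilate <- function(mask, iterations, elem = struct_element("square", 3)) {
  stopifnot(inherits(mask, "binary_mask"))
  if (length(iterations) != 1 || is.na(iterations) || iterations < 0 ||
      iterations != round(iterations)) {
    abort("iterations must be a single nonnegative integer",
          class = "pdl1ic_value_error")
  }
  out <- mask
  for (i in seq_len(iterations)) out <- dilate_mask(out, elem)
  out
}

#' Choose the dilation iteration count from reference areas
#'
#' Exhaustively searches 0..`max_iter` for the iteration count whose
#' dilated-area fractions best match reference area fractions (mean absolute
#' difference); ties resolve to the smallest count.
#'
#' @param masks list of `binary_mask` objects.
#' @param reference_areas reference area fractions, one per mask.
#' @param elem dilation structuring element.
#' @param max_iter largest iteration count to consider.
#' @return The selected iteration count (integer).
#' @export
calibrate_dilation_iterations <- function(masks, reference_areas,
                                          elem = struct_element("square", 3),
                                          max_iter = 10L) {
  if (length(masks) == 0) {
    abort("calibrate_dilation_iterations needs at least one mask",
          class = "pdl1ic_value_error")
  }
  if (length(masks) != length(reference_areas)) {
    abort("masks and reference_areas must be aligned",
          class = "pdl1ic_shape_error")
  }
  stopifnot(max_iter >= 0)
  cur <- masks
  errs <- numeric(max_iter + 1)
  for (it in 0:max_iter) {
    if (it > 0) cur <- lapply(cur, dilate_mask, elem = elem)
    areas <- vapply(cur, mask_area_fraction, numeric(1))
    errs[it + 1] <- mean(abs(areas - reference_areas))
  }
  as.integer(which.min(errs) - 1L)  # which.min takes the first (smallest) tie
}

#' Compute the continuous IC score from an IC mask
#'
#' The score is the set-pixel count of the iteratively dilated IC mask
#' divided by the total pixel count `N` of the mask (optionally a
#' restricted denominator mask for the guideline-style tumor-area variant).
#'
#' @param ic_mask a `binary_mask` with role `"ic"`.
#' @param iterations dilation iterations used for gap filling.
#' @param elem dilation structuring element.
#' @param denominator_mask optional `binary_mask`; when supplied the score
#'   denominator is its set-pixel count and dilated IC pixels are counted
#'   inside it only.
#' @return An object of class `ic_score_result` with fields `score`
#'   (fraction), `dilation_iterations`, `ic_pixels_after_dilation`,
#'   `total_pixels`, and `component_masks`.
#' @export
compute_ic_score <- function(ic_mask, iterations = 2L,
                             elem = struct_element("square", 3),
                             denominator_mask = NULL) {
  stopifnot(inherits(ic_mask, "binary_mask"))
  if (ic_mask$role != "ic") {
    abort("compute_ic_score expects a mask with role 'ic'",
          class = "pdl1ic_value_error")
  }
  dil <- iterative_dilate(ic_mask, iterations, elem)
  if (is.null(denominator_mask)) {
    num <- sum(dil$bits)
    den <- length(dil$bits)
  } else {
    check_same_dim(ic_mask, denominator_mask, "ic/denominator masks")
    num <- sum(dil$bits & denominator_mask$bits)
    den <- sum(denominator_mask$bits)
    if (den == 0) abort("denominator mask is empty", class = "pdl1ic_value_error")
  }
  new_ic_score_result(
    score = num / den,
    dilation_iterations = as.integer(iterations),
    ic_pixels_after_dilation = as.integer(num),
    total_pixels = as.integer(den),
    component_masks = list(ic = ic_mask, ic_dilated = dil)
  )
}

new_ic_score_result <- function(score, dilation_iterations,
                                ic_pixels_after_dilation, total_pixels,
                                component_masks) {
  structure(list(score = score,
                 dilation_iterations = dilation_iterations,
                 ic_pixels_after_dilation = ic_pixels_after_dilation,
                 total_pixels = total_pixels,
                 component_masks = component_masks),
            class = "ic_score_result")
}

#' @export
print.ic_score_result <- function(x, ...) {
  cat(sprintf("<ic_score_result %.2f%% (%d/%d px, %d dilation iter)>\n",
              100 * x$score, x$ic_pixels_after_dilation, x$total_pixels,
              x$dilation_iterations))
  invisible(x)
}

#' Category schemes for IC scores
#'
#' `scheme_2cat()` is the treatment-stratification scheme: negative below
#' the positivity cutoff (1% by default), positive at or above it.
#' `scheme_4cat()` is the granular scheme with percent intervals
#' \[0,1), \[1,5), \[5,10), \[10,100\]. Bins are half-open on the right with
#' the final bin closed, so exactly 1% is positive.
#'
#' @param positivity_cutoff percent cutoff for the 2-category scheme.
#' @return An object of class `category_scheme`.
#' @export
scheme_2cat <- function(positivity_cutoff = 1) {
  structure(list(edges = c(0, positivity_cutoff, 100),
                 labels = c("<1%", ">=1%"),
                 positivity_cutoff = positivity_cutoff,
                 name = "2cat"),
            class = "category_scheme")
}

#' @rdname scheme_2cat
#' @export
scheme_4cat <- function() {
  structure(list(edges = c(0, 1, 5, 10, 100),
                 labels = c("[0,1)", "[1,5)", "[5,10)", "[10,100]"),
                 positivity_cutoff = 1,
                 name = "4cat"),
            class = "category_scheme")
}

#' @export
print.category_scheme <- function(x, ...) {
  cat(sprintf("<category_scheme %s: %s>\n", x$name,
              paste(x$labels, collapse = " | ")))
  invisible(x)
}

#' Bin a continuous IC score into a category
#'
#' @param score score fraction(s) in \[0, 1\].
#' @param scheme a `category_scheme`.
#' @return Factor of category labels with the scheme's labels as levels.
#' @export
categorize <- function(score, scheme = scheme_4cat()) {
  stopifnot(inherits(scheme, "category_scheme"))
  if (anyNA(score) || any(score < 0) || any(score > 1)) {
    abort("score must lie in [0, 1]", class = "pdl1ic_value_error")
  }
  pct <- score * 100
  idx <- findInterval(pct, scheme$edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(scheme$labels))
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Scoring pipeline configuration
#'
#' @param box HSV threshold box for stain detection.
#' @param convention HSV scale convention.
#' @param denoise_erode,denoise_dilate structuring elements for stain-mask
#'   denoising.
#' @param iterations gap-filling dilation iterations (default 2; use
#'   [calibrate_dilation_iterations()] for a data-driven choice).
#' @param ic_elem structuring element for the gap-filling dilation.
#' @param region_provider a region provider (see
#'   [oracle_region_provider()], [null_region_provider()],
#'   [segmenter_region_provider()]).
#' @param prob_threshold probability threshold for model-based region
#'   prediction.
#' @param denominator `"patch"` (all pixels, the default) or
#'   `"exclude_necrotic"` (guideline-style: necrotic pixels leave the
#'   denominator).
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(box = sp142_threshold_box(),
                           convention = "hue179",
                           denoise_erode = struct_element("square", 3),
                           denoise_dilate = struct_element("square", 3),
                           iterations = 2L,
                           ic_elem = struct_element("square", 3),
                           region_provider = null_region_provider(),
                           prob_threshold = 0.5,
                           denominator = c("patch", "exclude_necrotic")) {
  denominator <- match.arg(denominator)
  structure(list(box = box, convention = convention,
                 denoise_erode = denoise_erode,
                 denoise_dilate = denoise_dilate,
                 iterations = as.integer(iterations), ic_elem = ic_elem,
                 region_provider = region_provider,
                 prob_threshold = prob_threshold,
                 denominator = denominator),
            class = "scoring_config")
}

#' Score a single patch end to end
#'
#' Runs the two-thread pipeline: (1) RGB to HSV, threshold box, morphological
#' denoise; (2) epithelium/necrosis prediction from the configured region
#' provider; then mask combination, gap-filling dilation, and the IC ratio.
#' All intermediate masks are retained on the result.
#'
#' @param patch an `rgb_patch`.
#' @param config a [scoring_config()].
#' @return An `ic_score_result` whose `component_masks` holds `stain_raw`,
#'   `stain`, `epithelium`, `necrotic`, `ic`, and `ic_dilated`.
#' @export
score_patch <- function(patch, config = scoring_config()) {
  stopifnot(inherits(patch, "rgb_patch"), inherits(config, "scoring_config"))
  hsv <- rgb_to_hsv_patch(patch, config$convention)
  stain_raw <- threshold_hsv(hsv, config$box)
  stain <- denoise_mask(stain_raw, config$denoise_erode, config$denoise_dilate)
  regions <- predict_regions(config$region_provider, patch,
                             prob_threshold = config$prob_threshold)
  ic <- combine_masks(stain, regions$epithelium, regions$necrotic)
  denom <- if (config$denominator == "exclude_necrotic") {
    binary_mask(!regions$necrotic$bits, role = "other")
  } else NULL
  res <- compute_ic_score(ic, iterations = config$iterations,
                          elem = config$ic_elem, denominator_mask = denom)
  res$component_masks <- c(list(stain_raw = stain_raw, stain = stain,
                                epithelium = regions$epithelium,
                                necrotic = regions$necrotic),
                           res$component_masks)
  res$source_id <- patch$source_id
  res
}

#' Score a batch of patches into a tidy table
#'
#' @param patches list of `rgb_patch` objects (optionally named).
#' @param config a [scoring_config()].
#' @return A tibble with one row per patch: `patch`, `score_pct`,
#'   `category2`, `category4`, `iterations`, `stain_area_pct`,
#'   `ic_area_pct`.
#' @export
score_patches <- function(patches, config = scoring_config()) {
  ids <- names(patches)
  if (is.null(ids)) ids <- sprintf("patch%03d", seq_along(patches))
  rows <- purrr::map2(patches, ids, function(p, id) {
    r <- score_patch(p, config)
    tibble(
      patch = id,
      score_pct = 100 * r$score,
      category2 = as.character(categorize(r$score, scheme_2cat())),
      category4 = as.character(categorize(r$score, scheme_4cat())),
      iterations = r$dilation_iterations,
      stain_area_pct = 100 * mask_area_fraction(r$component_masks$stain),
      ic_area_pct = 100 * mask_area_fraction(r$component_masks$ic)
    )
  })
  dplyr::bind_rows(rows)
}
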