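# Synthetic IHC patches with ground truth, and synthetic multi-rater score
# tables. Everything is deterministic given the spec seed.

#' Default color boxes for the synthetic patch generator
#'
#' The stain box is the SP142 detection box shrunk by a 2-unit margin so
#' every generated stained pixel stays strictly interior to the detection
#' box after the 8-bit HSV-RGB-HSV round trip. Stroma, epithelium, and
#' necrosis boxes are disjoint from the stain box on the saturation
#' channel (pale eosin-pink stroma, strongly saturated hematoxylin
#' epithelium, desaturated grey necrosis).
#'
#' @name synthetic_color_boxes
#' @return An `hsv_box` in the `"hue179"` convention.
#' @export
synthetic_stain_box <- function() hsv_box(103, 173, 42, 118, 42, 148)

#' @rdname synthetic_color_boxes
#' @export
synthetic_background_box <- function() hsv_box(160, 179, 5, 30, 200, 255)

#' @rdname synthetic_color_boxes
#' @export
synthetic_epithelium_box <- function() hsv_box(120, 150, 130, 200, 80, 180)

#' @rdname synthetic_color_boxes
#' @export
synthetic_necrotic_box <- function() hsv_box(20, 40, 0, 25, 120, 200)

#' Specification of a synthetic IHC patch
#'
#' Describes a DAB/hematoxylin-like patch: smooth random epithelial and
#' necrotic regions, disc-shaped stained immune cells scattered or
#' aggregated in the stroma at a known ground-truth IC fraction, and
#' optional non-specific staining of epithelial pixels.
#'
#' @param height,width patch dimensions in pixels.
#' @param target_ic_fraction ground-truth raw IC pixel fraction of the
#'   whole patch, in \[0, 1\].
#' @param pattern `"scattered"`, `"aggregated"`, or `"mixed"`.
#' @param mixed_weight fraction of cells placed as aggregated clusters when
#'   `pattern = "mixed"`.
#' @param cell_radius_px nominal immune-cell disc radius (jittered by
#'   1 px). The default 7 px matches a 7-10 um lymphocyte at the 0.524
#'   um/px scale the patches carry.
#' @param epithelium_fraction,necrotic_fraction area fractions of the two
#'   excluded regions.
#' @param stain_hsv_box HSV box stained pixels are drawn from.
#' @param background_hsv_box stroma color box; must be disjoint from the
#'   stain box on at least one channel.
#' @param epithelium_hsv_box,necrotic_hsv_box base color boxes of the two
#'   regions.
#' @param epithelium_stained_fraction fraction of epithelial pixels also
#'   colored from the stain box (models non-specific tumor-cell staining).
#' @param cluster_sd Gaussian spread (px) of offspring cells around a
#'   cluster parent in the aggregated pattern.
#' @param cells_per_cluster mean offspring per cluster parent.
#' @param hull_close_radius disc radius (px) of the morphological closing
#'   that defines the aggregation-hull IC area.
#' @param seed RNG seed; fixed seed implies bit-identical output.
#' @return A `synthetic_patch_spec` list.
#' @export
synthetic_patch_spec <- function(height = 256L, width = 256L,
                                 target_ic_fraction = 0.05,
                                 pattern = c("scattered", "aggregated", "mixed"),
                                 mixed_weight = 0.5,
                                 cell_radius_px = 7L,
                                 epithelium_fraction = 0.30,
                                 necrotic_fraction = 0.05,
                                 stain_hsv_box = synthetic_stain_box(),
                                 background_hsv_box = synthetic_background_box(),
                                 epithelium_hsv_box = synthetic_epithelium_box(),
                                 necrotic_hsv_box = synthetic_necrotic_box(),
                                 epithelium_stained_fraction = 0.02,
                                 cluster_sd = 4 * cell_radius_px,
                                 cells_per_cluster = 8,
                                 hull_close_radius = 2L * cell_radius_px,
                                 seed = 1L) {
  pattern <- match.arg(pattern)
  fr <- c(target_ic_fraction, epithelium_fraction, necrotic_fraction,
          epithelium_stained_fraction, mixed_weight)
  if (any(fr < 0) || any(fr > 1)) {
    abort("all fractions must lie in [0, 1]", class = "pdl1ic_value_error")
  }
  disjoint <- stain_hsv_box$h_lo > background_hsv_box$h_hi ||
    stain_hsv_box$h_hi < background_hsv_box$h_lo ||
    stain_hsv_box$s_lo > background_hsv_box$s_hi ||
    stain_hsv_box$s_hi < background_hsv_box$s_lo ||
    stain_hsv_box$v_lo > background_hsv_box$v_hi ||
    stain_hsv_box$v_hi < background_hsv_box$v_lo
  if (!disjoint) {
    abort("stain and background boxes must be disjoint on at least one channel",
          class = "pdl1ic_value_error")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 target_ic_fraction = target_ic_fraction, pattern = pattern,
                 mixed_weight = mixed_weight,
                 cell_radius_px = as.integer(cell_radius_px),
                 epithelium_fraction = epithelium_fraction,
                 necrotic_fraction = necrotic_fraction,
                 stain_hsv_box = stain_hsv_box,
                 background_hsv_box = background_hsv_box,
                 epithelium_hsv_box = epithelium_hsv_box,
                 necrotic_hsv_box = necrotic_hsv_box,
                 epithelium_stained_fraction = epithelium_stained_fraction,
                 cluster_sd = cluster_sd, cells_per_cluster = cells_per_cluster,
                 hull_close_radius = as.integer(hull_close_radius),
                 seed = as.integer(seed)),
            class = "synthetic_patch_spec")
}

# Smooth random region of an exact pixel count: threshold a blurred
# Gaussian field at the matching order statistic, restricted to `allowed`.
smooth_region <- function(h, w, n_pixels, allowed, blur_sigma) {
  field <- matrix(rnorm(h * w), h, w)
  field <- EBImage::imageData(EBImage::gblur(EBImage::Image(field), sigma = blur_sigma))
  field[!allowed] <- -Inf
  out <- matrix(FALSE, h, w)
  if (n_pixels > 0) {
    thr <- sort(field[allowed], decreasing = TRUE)[n_pixels]
    out <- field >= thr
    # resolve ties at the threshold to the exact count
    if (sum(out) > n_pixels) {
      extra <- which(out & field == thr)
      out[extra[seq_len(sum(out) - n_pixels)]] <- FALSE
    }
  }
  out
}

# Uniform integer HSV draws inside a box, converted to 8-bit RGB rows.
draw_box_colors <- function(n, box) {
  h <- sample(box$h_lo:box$h_hi, n, replace = TRUE)
  s <- sample(box$s_lo:box$s_hi, n, replace = TRUE)
  v <- sample(box$v_lo:box$v_hi, n, replace = TRUE)
  t(col2rgb(hsv(h / 180, s / 255, v / 255)))
}

disc_offsets <- function(r) {
  g <- expand.grid(di = -r:r, dj = -r:r)
  g <- g[g$di^2 + g$dj^2 <= r^2 + 0.5, ]
  ord <- order(g$di^2 + g$dj^2)
  g[ord, , drop = FALSE]
}

#' Generate a synthetic IHC patch with ground-truth layers
#'
#' Places epithelium and necrosis as smooth random regions of the requested
#' area fractions, scatters or clusters disc-shaped stained immune cells in
#' the stroma until the requested IC fraction is met exactly (the final
#' disc is trimmed nearest-first), optionally stains a fraction of
#' epithelial pixels, and returns the colored patch plus all ground-truth
#' masks.
#'
#' @param spec a [synthetic_patch_spec()].
#' @return A `synthetic_patch_bundle`: `patch` (`rgb_patch`),
#'   `truth_stain`, `truth_epithelium`, `truth_necrotic`, `truth_ic`
#'   (`binary_mask`s), `true_ic_fraction_raw` (set-pixel basis), and
#'   `true_ic_fraction_hull` (aggregation-hull basis).
#' @export
generate_patch <- function(spec) {
  stopifnot(inherits(spec, "synthetic_patch_spec"))
  h <- spec$height; w <- spec$width
  with_local_seed(spec$seed, {
    all_px <- matrix(TRUE, h, w)
    epi <- smooth_region(h, w, round(spec$epithelium_fraction * h * w),
                         all_px, blur_sigma = h / 10)
    nec <- smooth_region(h, w, round(spec$necrotic_fraction * h * w),
                         !epi, blur_sigma = h / 12)
    stroma <- !(epi | nec)

    target_n <- round(spec$target_ic_fraction * h * w)
    if (target_n > 0.8 * sum(stroma)) {
      abort(paste0("infeasible spec: requested IC fraction ",
                   spec$target_ic_fraction,
                   " exceeds available stroma (", sum(stroma), " px)"),
            class = "pdl1ic_value_error")
    }

    ic <- matrix(FALSE, h, w)
    n_ic <- 0L
    stroma_idx <- which(stroma)
    cluster_centers <- NULL
    place_center <- function(aggregated) {
      if (aggregated) {
        if (is.null(cluster_centers) ||
            (runif(1) < 1 / spec$cells_per_cluster)) {
          k <- stroma_idx[sample.int(length(stroma_idx), 1)]
          cluster_centers <<- c((k - 1L) %% h + 1L, (k - 1L) %/% h + 1L)
        }
        round(cluster_centers + rnorm(2, sd = spec$cluster_sd))
      } else {
        k <- stroma_idx[sample.int(length(stroma_idx), 1)]
        c((k - 1L) %% h + 1L, (k - 1L) %/% h + 1L)
      }
    }
    attempts <- 0L
    max_attempts <- 200L + 60L * ceiling(target_n / max(1, spec$cell_radius_px^2))
    while (n_ic < target_n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort("infeasible spec: could not place enough immune cells in the stroma",
              class = "pdl1ic_value_error")
      }
      aggregated <- switch(spec$pattern,
                           scattered = FALSE,
                           aggregated = TRUE,
                           mixed = runif(1) < spec$mixed_weight)
      ctr <- place_center(aggregated)
      r <- max(1L, spec$cell_radius_px + sample(-1:1, 1))
      off <- disc_offsets(r)
      ii <- ctr[1] + off$di; jj <- ctr[2] + off$dj
      ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
      ii <- ii[ok]; jj <- jj[ok]
      lin <- (jj - 1L) * h + ii
      lin <- lin[stroma[lin] & !ic[lin]]
      if (length(lin) == 0) next
      need <- target_n - n_ic
      if (length(lin) > need) lin <- lin[seq_len(need)]  # nearest-first trim
      ic[lin] <- TRUE
      n_ic <- n_ic + length(lin)
    }

    # non-specific staining inside the epithelium: cell-sized discs, not
    # salt-and-pepper, so it survives denoising like real tumor-cell stain
    epi_idx <- which(epi)
    n_epi_stain <- round(spec$epithelium_stained_fraction * length(epi_idx))
    epi_stained <- matrix(FALSE, h, w)
    n_es <- 0L; es_attempts <- 0L
    while (n_es < n_epi_stain && es_attempts < 50L * max(1L, n_epi_stain)) {
      es_attempts <- es_attempts + 1L
      k <- epi_idx[sample.int(length(epi_idx), 1)]
      ctr <- c((k - 1L) %% h + 1L, (k - 1L) %/% h + 1L)
      r <- max(1L, spec$cell_radius_px + sample(-1:1, 1))
      off <- disc_offsets(r)
      ii <- ctr[1] + off$di; jj <- ctr[2] + off$dj
      ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
      lin <- (jj[ok] - 1L) * h + ii[ok]
      lin <- lin[epi[lin] & !epi_stained[lin]]
      if (length(lin) == 0) next
      need <- n_epi_stain - n_es
      if (length(lin) > need) lin <- lin[seq_len(need)]
      epi_stained[lin] <- TRUE
      n_es <- n_es + length(lin)
    }
    stain <- ic | epi_stained

    # color the canvas layer by layer
    px <- array(0L, dim = c(h, w, 3))
    paint <- function(px, sel, box) {
      n <- sum(sel)
      if (n == 0) return(px)
      cols <- draw_box_colors(n, box)
      for (ch in 1:3) {
        plane <- px[, , ch]; plane[sel] <- cols[, ch]; px[, , ch] <- plane
      }
      px
    }
    px <- paint(px, stroma & !ic, spec$background_hsv_box)
    px <- paint(px, epi & !epi_stained, spec$epithelium_hsv_box)
    px <- paint(px, nec, spec$necrotic_hsv_box)
    px <- paint(px, stain, spec$stain_hsv_box)

    ic_mask <- binary_mask(ic, "ic")
    hull <- close_mask(ic_mask, disc_element(max(1L, spec$hull_close_radius)))
    structure(list(
      patch = rgb_patch(px, pixel_size_um = 0.524,
                        source_id = sprintf("synthetic-seed%d", spec$seed)),
      truth_stain = binary_mask(stain, "stain"),
      truth_epithelium = binary_mask(epi, "epithelium"),
      truth_necrotic = binary_mask(nec, "necrotic"),
      truth_ic = ic_mask,
      true_ic_fraction_raw = n_ic / (h * w),
      true_ic_fraction_hull = mean(hull$bits),
      spec = spec
    ), class = "synthetic_patch_bundle")
  })
}

#' @export
print.synthetic_patch_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_patch_bundle %dx%d, %s, raw IC %.3f%%, hull IC %.3f%%>\n",
              x$spec$height, x$spec$width, x$spec$pattern,
              100 * x$true_ic_fraction_raw, 100 * x$true_ic_fraction_hull))
  invisible(x)
}

# ---- Synthetic raters -------------------------------------------------------

#' Specification of a synthetic multi-rater ring study
#'
#' Rater `r` scores image `i` in every round as
#' `clip(true_i + bias_r + noise, 0, 1)` with `bias_r ~ N(0, rater_bias_sd^2)`
#' fixed per rater and fresh `noise ~ N(0, (m_g * rater_noise_sd)^2)` per
#' cell, where `m_g` is the rater's experience-group noise multiplier.
#' Defaults mirror the shape of a 31-pathologist, 109-image, 3-round ring
#' study with senior/intermediate/junior groups of 11/10/10.
#'
#' @param n_raters,n_images,n_rounds counts, all >= 1.
#' @param true_scores per-image true score fractions (length `n_images`);
#'   drawn from a skewed mixture typical of IC scores when `NULL`.
#' @param rater_bias_sd,rater_noise_sd score-scale standard deviations.
#' @param experience_groups optional character vector of group labels, one
#'   per rater.
#' @param group_noise_multipliers named multipliers applied to
#'   `rater_noise_sd` per group.
#' @param seed RNG seed.
#' @return A `rater_sim_spec` list.
#' @export
rater_sim_spec <- function(n_raters = 31L, n_images = 109L, n_rounds = 3L,
                           true_scores = NULL,
                           rater_bias_sd = 0.01, rater_noise_sd = 0.02,
                           experience_groups = NULL,
                           group_noise_multipliers = NULL,
                           seed = 1L) {
  if (n_raters < 1 || n_images < 1 || n_rounds < 1) {
    abort("counts must be >= 1", class = "pdl1ic_value_error")
  }
  if (rater_bias_sd < 0 || rater_noise_sd < 0) {
    abort("standard deviations must be >= 0", class = "pdl1ic_value_error")
  }
  if (!is.null(true_scores) && length(true_scores) != n_images) {
    abort("true_scores must have length n_images", class = "pdl1ic_shape_error")
  }
  if (is.null(experience_groups)) {
    experience_groups <- if (n_raters == 31L) {
      rep(c("senior", "intermediate", "junior"), times = c(11, 10, 10))
    } else {
      rep_len(c("senior", "intermediate", "junior"), n_raters)
    }
  }
  if (length(experience_groups) != n_raters) {
    abort("experience_groups must have length n_raters", class = "pdl1ic_shape_error")
  }
  if (is.null(group_noise_multipliers)) {
    group_noise_multipliers <- stats::setNames(
      rep(1, length(unique(experience_groups))), unique(experience_groups))
  }
  structure(list(n_raters = as.integer(n_raters),
                 n_images = as.integer(n_images),
                 n_rounds = as.integer(n_rounds),
                 true_scores = true_scores,
                 rater_bias_sd = rater_bias_sd,
                 rater_noise_sd = rater_noise_sd,
                 experience_groups = experience_groups,
                 group_noise_multipliers = group_noise_multipliers,
                 seed = as.integer(seed)),
            class = "rater_sim_spec")
}

# Skewed true-score mixture: most images near or below the 1% cutoff, a
# tail of strongly positive ones.
draw_true_scores <- function(n) {
  bucket <- sample(1:3, n, replace = TRUE, prob = c(0.55, 0.3, 0.15))
  ifelse(bucket == 1, runif(n, 0, 0.02),
         ifelse(bucket == 2, runif(n, 0.02, 0.1), runif(n, 0.1, 0.4)))
}

#' Generate a synthetic multi-rater score table
#'
#' @param spec a [rater_sim_spec()].
#' @return A tibble in long format: `rater`, `group`, `image`, `round`,
#'   `true_score`, `score` (fractions in \[0, 1\]). The per-rater biases
#'   are attached as attribute `"rater_bias"` and the true scores as
#'   `"true_scores"`.
#' @export
generate_rater_table <- function(spec) {
  stopifnot(inherits(spec, "rater_sim_spec"))
  with_local_seed(spec$seed, {
    true_scores <- spec$true_scores %||% draw_true_scores(spec$n_images)
    raters <- sprintf("R%02d", seq_len(spec$n_raters))
    images <- sprintf("img%03d", seq_len(spec$n_images))
    rounds <- sprintf("RS%d", seq_len(spec$n_rounds))
    bias <- rnorm(spec$n_raters, sd = spec$rater_bias_sd)
    mult <- spec$group_noise_multipliers[spec$experience_groups]
    grid <- expand.grid(rater_i = seq_len(spec$n_raters),
                        image_i = seq_len(spec$n_images),
                        round_i = seq_len(spec$n_rounds))
    noise <- rnorm(nrow(grid)) * spec$rater_noise_sd * mult[grid$rater_i]
    raw <- true_scores[grid$image_i] + bias[grid$rater_i] + noise
    tbl <- tibble(
      rater = raters[grid$rater_i],
      group = spec$experience_groups[grid$rater_i],
      image = images[grid$image_i],
      round = rounds[grid$round_i],
      true_score = true_scores[grid$image_i],
      score = unname(pmin(pmax(raw, 0), 1))
    )
    attr(tbl, "rater_bias") <- stats::setNames(bias, raters)
    attr(tbl, "true_scores") <- stats::setNames(true_scores, images)
    tbl
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
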