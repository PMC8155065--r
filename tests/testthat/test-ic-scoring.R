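test_that("combine_masks implements the exclusion identity", {
  ones <- matrix(1, 3, 3); zeros <- matrix(0, 3, 3)
  ic <- combine_masks(mk_mask(ones, "stain"), mk_mask(zeros, "epithelium"),
                      mk_mask(zeros, "necrotic"))
  expect_true(all(ic$bits))
  expect_equal(ic$role, "ic")

  ic2 <- combine_masks(mk_mask(ones, "stain"), mk_mask(ones, "epithelium"),
                       mk_mask(zeros, "necrotic"))
  expect_false(any(ic2$bits))

  # 2x2 toy forced by Boolean algebra
  stain <- mk_mask(matrix(c(1, 1, 1, 0), 2, byrow = TRUE), "stain")
  epi <- mk_mask(matrix(c(1, 0, 0, 0), 2, byrow = TRUE), "epithelium")
  nec <- mk_mask(matrix(c(0, 0, 1, 0), 2, byrow = TRUE), "necrotic")
  out <- combine_masks(stain, epi, nec)
  expect_identical(out$bits, matrix(c(0, 1, 0, 0), 2, byrow = TRUE) == 1)

  expect_error(combine_masks(epi, epi, nec), class = "pdl1ic_value_error")
  expect_error(combine_masks(stain, mk_mask(matrix(0, 3, 3), "epithelium"), nec),
               class = "pdl1ic_shape_error")
})

test_that("mask exclusion invariants hold on fuzzed triples", {
  set.seed(10)
  for (rep in 1:50) {
    stain <- random_mask(12, 12, runif(1, 0.1, 0.9), "stain")
    epi <- random_mask(12, 12, runif(1, 0, 0.5), "epithelium")
    nec <- random_mask(12, 12, runif(1, 0, 0.4), "necrotic")
    ic <- combine_masks(stain, epi, nec)
    expect_false(any(ic$bits & epi$bits))
    expect_false(any(ic$bits & nec$bits))
    expect_true(all(!ic$bits | stain$bits))  # M_IC subset of M_stain
  }
})

test_that("iterative_dilate matches closed forms and composition", {
  m <- random_mask(10, 10, 0.3, "ic")
  expect_identical(iterative_dilate(m, 0)$bits, m$bits)
  expect_error(iterative_dilate(m, -1), class = "pdl1ic_value_error")

  # two pixels two apart: one dilation closes the gap
  row <- matrix(0, 5, 7); row[3, 3] <- 1; row[3, 5] <- 1
  out <- iterative_dilate(mk_mask(row, "ic"), 1)
  expect_true(out$bits[3, 4])

  # k iterated 3x3 dilations equal one dilation with the k-fold kernel
  set.seed(11)
  elem <- struct_element("square", 3)
  m2 <- matrix(runif(14 * 14) < 0.15, 14, 14)
  for (k in 1:3) {
    kern <- matrix(1, 3, 3)
    big <- matrix(1, 2 * k + 1, 2 * k + 1)  # k-fold dilation of a 3x3 box
    iter <- iterative_dilate(binary_mask(m2, "ic"), k, elem)$bits
    expect_identical(iter, brute_dilate(m2, big))
  }
})

test_that("calibrate_dilation_iterations finds the discrete optimum", {
  set.seed(12)
  masks <- lapply(1:4, function(i) random_mask(20, 20, 0.08, "ic"))
  areas0 <- sapply(masks, mask_area_fraction)
  expect_equal(calibrate_dilation_iterations(masks, areas0), 0L)
  areas1 <- sapply(masks, function(m) mask_area_fraction(dilate_mask(m)))
  expect_equal(calibrate_dilation_iterations(masks, areas1), 1L)
  expect_error(calibrate_dilation_iterations(list(), numeric(0)),
               class = "pdl1ic_value_error")

  # exhaustive search oracle on arbitrary reference areas
  refs <- runif(4, 0.2, 0.6)
  errs <- sapply(0:6, function(it) {
    mean(abs(sapply(masks, function(m)
      mask_area_fraction(iterative_dilate(m, it))) - refs))
  })
  expect_equal(calibrate_dilation_iterations(masks, refs, max_iter = 6L),
               as.integer(which.min(errs) - 1))
})

test_that("compute_ic_score matches counting closed forms", {
  set.seed(13)
  scatter <- matrix(0, 10, 10)
  scatter[cbind(sample(1:10, 10, TRUE), sample(1:10, 10, TRUE))] <- 1
  n_set <- sum(scatter)
  r0 <- compute_ic_score(mk_mask(scatter, "ic"), iterations = 0)
  expect_equal(r0$score, n_set / 100)
  expect_equal(r0$total_pixels, 100L)

  full <- compute_ic_score(mk_mask(matrix(1, 6, 6), "ic"), iterations = 3)
  expect_equal(full$score, 1)

  center <- matrix(0, 100, 100); center[50, 50] <- 1
  one <- compute_ic_score(mk_mask(center, "ic"), iterations = 1)
  expect_equal(one$score, 9 / 10000)

  expect_error(compute_ic_score(mk_mask(scatter, "stain")),
               class = "pdl1ic_value_error")
})

test_that("score is monotone in iterations and added pixels, bounded in [0,1]", {
  set.seed(14)
  for (rep in 1:10) {
    m <- random_mask(16, 16, runif(1, 0, 0.5), "ic")
    scores <- sapply(0:3, function(it) compute_ic_score(m, it)$score)
    expect_true(all(diff(scores) >= 0))
    expect_true(all(scores >= 0 & scores <= 1))
    extra <- m$bits
    extra[sample(length(extra), 5)] <- TRUE
    expect_gte(compute_ic_score(binary_mask(extra, "ic"), 1)$score,
               compute_ic_score(m, 1)$score)
  }
})

test_that("categorize applies half-open bins with the 1% cutoff positive", {
  expect_equal(as.character(categorize(0.005, scheme_2cat())), "<1%")
  expect_equal(as.character(categorize(0.01, scheme_2cat())), ">=1%")
  expect_equal(as.character(categorize(0.07, scheme_4cat())), "[5,10)")
  expect_equal(as.character(categorize(0, scheme_4cat())), "[0,1)")
  expect_equal(as.character(categorize(0.01, scheme_4cat())), "[1,5)")
  expect_equal(as.character(categorize(0.10, scheme_4cat())), "[10,100]")
  expect_equal(as.character(categorize(1, scheme_4cat())), "[10,100]")
  expect_error(categorize(1.2, scheme_4cat()), class = "pdl1ic_value_error")
})

test_that("score_patch composes the full pipeline", {
  blank <- solid_patch(32, 32, c(255, 255, 255))
  expect_equal(score_patch(blank)$score, 0)

  # synthetic patch with oracle regions recovers the known ratio
  b <- generate_patch(synthetic_patch_spec(target_ic_fraction = 0.05, seed = 21))
  cfg <- scoring_config(
    region_provider = oracle_region_provider(b$truth_epithelium, b$truth_necrotic),
    iterations = 0L)
  r <- score_patch(b$patch, cfg)
  expect_lt(abs(r$score - 0.05), 0.01)
  expect_named(r$component_masks,
               c("stain_raw", "stain", "epithelium", "necrotic", "ic", "ic_dilated"))

  # stained pixels confined to the epithelium score zero
  b2 <- generate_patch(synthetic_patch_spec(
    target_ic_fraction = 0, epithelium_stained_fraction = 0.1, seed = 22))
  cfg2 <- scoring_config(
    region_provider = oracle_region_provider(b2$truth_epithelium, b2$truth_necrotic),
    iterations = 0L)
  expect_equal(score_patch(b2$patch, cfg2)$score, 0)
})

test_that("calibrated dilation recovers the aggregation-hull area", {
  bundles <- lapply(1:6, function(i) generate_patch(synthetic_patch_spec(
    target_ic_fraction = 0.04, pattern = "aggregated", seed = 30 + i)))
  masks <- lapply(bundles, function(b) b$truth_ic)
  hulls <- sapply(bundles, function(b) b$true_ic_fraction_hull)
  it <- calibrate_dilation_iterations(masks, hulls, max_iter = 8L)
  achieved <- mean(abs(sapply(masks, function(m)
    mask_area_fraction(iterative_dilate(m, it))) - hulls))
  # within one dilation step of the hull area: better than both neighbors'
  # mean error or at most one step's area increment away
  step_sizes <- sapply(masks, function(m) {
    mask_area_fraction(iterative_dilate(m, it + 1)) -
      mask_area_fraction(iterative_dilate(m, it))
  })
  expect_lte(achieved, max(mean(step_sizes), 0.005))
})

test_that("tidy and glance summarise scoring results", {
  b <- generate_patch(synthetic_patch_spec(height = 64, width = 64,
                                           target_ic_fraction = 0.03, seed = 40))
  cfg <- scoring_config(
    region_provider = oracle_region_provider(b$truth_epithelium, b$truth_necrotic),
    iterations = 0L)
  r <- score_patch(b$patch, cfg)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$score_pct, 100 * r$score)
  expect_equal(td$category4,
               as.character(categorize(r$score, scheme_4cat())))
  expect_identical(glance(r), td)
})
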