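# Independent ANOVA oracle: mean squares assembled from aov() sums of
# squares on the long data, kept separate from the package's own
# decomposition.
aov_ms <- function(m) {
  long <- data.frame(score = as.vector(m),
                     image = factor(rep(seq_len(nrow(m)), ncol(m))),
                     rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  fit <- summary(stats::aov(score ~ image + rater, data = long))[[1]]
  list(msr = fit["image", "Mean Sq"], msc = fit["rater", "Mean Sq"],
       mse = fit["Residuals", "Mean Sq"])
}

long_table <- function(m, round = "RS1") {
  data.frame(score = as.vector(m),
             image = sprintf("img%02d", rep(seq_len(nrow(m)), ncol(m))),
             rater = sprintf("R%02d", rep(seq_len(ncol(m)), each = nrow(m))),
             round = round)
}

test_that("icc31 is exact on degenerate agreement patterns", {
  m <- matrix(rep(c(0.1, 0.3, 0.5, 0.7, 0.2, 0.9), 3), ncol = 3)
  expect_equal(icc31(long_table(m))$estimate, 1.0)
  # consistency ignores a fixed offset
  m2 <- cbind(m[, 1], m[, 1] + 0.05, m[, 1] + 0.1)
  expect_equal(icc31(long_table(m2))$estimate, 1.0)
})

test_that("icc31 matches the aov mean-squares oracle on seeded tables", {
  set.seed(80)
  for (rep in 1:5) {
    m <- matrix(runif(18), nrow = 6, ncol = 3)
    ms <- aov_ms(m)
    k <- 3
    expected <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    got <- icc31(long_table(m))
    expect_equal(got$estimate, expected, tolerance = 1e-10)
    expect_lte(got$ci_low, got$estimate)
    expect_gte(got$ci_high, got$estimate)
  }
  expect_error(icc31(long_table(matrix(runif(4), 4, 1))),
               class = "pdl1ic_value_error")
})

test_that("icc21 penalizes offsets and matches the aov oracle", {
  a <- c(0.1, 0.25, 0.4, 0.6, 0.8, 0.05)
  expect_equal(icc21(a, a)$estimate, 1.0)
  off <- icc21(a, a + 0.1)
  expect_lt(off$estimate, 1.0)

  set.seed(81)
  for (rep in 1:5) {
    x <- runif(8); y <- x + rnorm(8, sd = 0.1)
    ms <- aov_ms(cbind(x, y))
    n <- 8; k <- 2
    expected <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
    expect_equal(icc21(x, y)$estimate, expected, tolerance = 1e-10)
  }
  expect_error(icc21(1:3 / 10, 1:4 / 10), class = "pdl1ic_shape_error")
})

test_that("icc31 and icc21 coincide when rater means are equal", {
  set.seed(82)
  x <- runif(30, 0.2, 0.8)
  y <- x + rnorm(30, sd = 0.05)
  y <- y - mean(y) + mean(x)  # equalize means, keep noise
  m <- cbind(x, y)
  i31 <- icc31(long_table(m))$estimate
  i21 <- icc21(x, y)$estimate
  expect_equal(i31, i21, tolerance = 0.02)
})

test_that("fleiss_kappa matches the direct-formula oracle on a toy table", {
  set.seed(83)
  x <- matrix(sample(1:3, 10 * 5, replace = TRUE), nrow = 10, ncol = 5)
  # direct formula, spreadsheet style
  n <- 10; m <- 5
  counts <- t(apply(x, 1, function(r) tabulate(r, 3)))
  p_j <- colSums(counts) / (n * m)
  P_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  expected <- (mean(P_i) - sum(p_j^2)) / (1 - sum(p_j^2))
  got <- fleiss_kappa(x)
  expect_equal(got$estimate, expected, tolerance = 1e-12)
  expect_lte(got$ci_low, got$estimate)
  expect_gte(got$ci_high, got$estimate)
})

test_that("fleiss_kappa hits exact limits and rejects degenerate tables", {
  perfect <- matrix(rep(c(1, 2, 1, 3, 2), 4), nrow = 5)
  expect_equal(fleiss_kappa(perfect)$estimate, 1.0)
  expect_error(fleiss_kappa(matrix(1, 5, 3)), class = "pdl1ic_value_error")

  # independent uniform assignments: kappa ~ 0 in expectation
  set.seed(84)
  ks <- replicate(20, fleiss_kappa(matrix(sample(1:4, 60 * 6, TRUE), 60))$estimate)
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("fleiss_kappa is invariant to category relabeling", {
  set.seed(85)
  x <- matrix(sample(1:4, 12 * 4, replace = TRUE), nrow = 12)
  perm <- c(3, 1, 4, 2)
  expect_equal(fleiss_kappa(matrix(perm[x], nrow = 12))$estimate,
               fleiss_kappa(x)$estimate, tolerance = 1e-12)
  # bootstrap CI brackets the estimate too
  bt <- fleiss_kappa(x, ci = "bootstrap", n_boot = 200, seed = 5)
  expect_lte(bt$ci_low, bt$estimate)
  expect_gte(bt$ci_high, bt$estimate)
})

test_that("interpretation bands reproduce the published readings", {
  expect_equal(interpret_icc(0.674), "moderate")
  expect_equal(interpret_icc(0.736), "moderate")
  expect_equal(interpret_icc(0.95), "excellent")
  expect_equal(interpret_icc(0.75), "good")
  expect_equal(interpret_icc(0.3), "poor")
  expect_equal(interpret_icc(-0.1), "poor")
  expect_equal(interpret_icc(1), "excellent")

  expect_equal(interpret_fks(0.856), "strong")
  expect_equal(interpret_fks(0.471), "weak")
  expect_equal(interpret_fks(0.431), "weak")
  expect_equal(interpret_fks(0.628), "moderate")
  expect_equal(interpret_fks(0.2), "below weak")
  expect_equal(interpret_fks(0.95), "near perfect")
})

test_that("accuracy_metrics matches hand-computed confusion arithmetic", {
  s4 <- scheme_4cat()
  labs <- s4$labels
  gold <- labs[c(1, 1, 1, 1, 2, 2, 2, 3, 3, 4)]
  expect_equal(accuracy_metrics(gold, gold, s4)$accuracy, 1)
  expect_equal(accuracy_metrics(gold, gold, s4)$weighted_f1, 1)

  s2 <- scheme_2cat()
  g2 <- s2$labels[c(1, 2, 1, 2)]
  flipped <- s2$labels[c(2, 1, 2, 1)]
  expect_equal(accuracy_metrics(flipped, g2, s2)$accuracy, 0)

  # 20-item toy confusion, metrics computed by hand:
  # gold: 8 of class1, 6 of class2, 4 of class3, 2 of class4
  pred <- labs[c(1, 1, 1, 1, 1, 1, 2, 2,   # class1: 6 right, 2 -> class2
                 2, 2, 2, 2, 1, 3,         # class2: 4 right, 1 -> c1, 1 -> c3
                 3, 3, 3, 4,               # class3: 3 right, 1 -> c4
                 4, 4)]                    # class4: 2 right
  gold20 <- labs[rep(1:4, c(8, 6, 4, 2))]
  got <- accuracy_metrics(pred, gold20, s4)
  expect_equal(got$accuracy, 15 / 20)
  f1_1 <- 2 * 6 / (2 * 6 + 1 + 2)       # tp=6 fp=1 fn=2
  f1_2 <- 2 * 4 / (2 * 4 + 2 + 2)       # tp=4 fp=2 fn=2
  f1_3 <- 2 * 3 / (2 * 3 + 1 + 1)       # tp=3 fp=1 fn=1
  f1_4 <- 2 * 2 / (2 * 2 + 1 + 0)       # tp=2 fp=1 fn=0
  expect_equal(got$weighted_f1,
               (8 * f1_1 + 6 * f1_2 + 4 * f1_3 + 2 * f1_4) / 20)
  expect_error(accuracy_metrics(c("bad"), gold20[1], s4),
               class = "pdl1ic_value_error")
})

test_that("binary one-vs-rest AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  s2 <- scheme_2cat()
  set.seed(86)
  gold <- s2$labels[(runif(40) < 0.4) + 1]
  pred <- s2$labels[(runif(40) < 0.5) + 1]
  got <- accuracy_metrics(pred, gold, s2)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = gold == s2$labels[2],
    predictor = as.numeric(factor(pred, levels = s2$labels)),
    quiet = TRUE, direction = "<")))
  # both one-vs-rest AUCs of a binary task equal the same number
  expect_equal(got$auc, ref, tolerance = 1e-12)
})

test_that("acceptance_analysis applies the 1%/5% same-category rules", {
  rs <- data.frame(rater = rep(c("A", "B"), each = 3),
                   image = rep(c("i1", "i2", "i3"), 2),
                   score = c(0.02, 0.06, 0.15, 0.02, 0.06, 0.15))
  ai <- data.frame(image = c("i1", "i2", "i3"), score = c(0.02, 0.06, 0.15))
  perfect <- acceptance_analysis(rs, ai)
  expect_equal(perfect$overall$fully_accepted, 1)
  expect_equal(perfect$overall$almost_accepted, 1)
  expect_equal(perfect$overall$cat2_accepted, 1)
  expect_equal(perfect$overall$cat4_accepted, 1)

  # uniform +3% shift within the same 4-category bin: almost but not fully
  rs2 <- data.frame(rater = "A", image = c("i1", "i2"), score = c(0.15, 0.27))
  ai2 <- data.frame(image = c("i1", "i2"), score = c(0.12, 0.24))
  shifted <- acceptance_analysis(rs2, ai2)
  expect_equal(shifted$overall$fully_accepted, 0)
  expect_equal(shifted$overall$almost_accepted, 1)

  expect_error(acceptance_analysis(rs, ai[1:2, ]), class = "pdl1ic_value_error")
})

test_that("acceptance analysis matches an exhaustive per-cell recount", {
  tbl <- generate_rater_table(rater_sim_spec(n_raters = 6, n_images = 30,
                                             n_rounds = 1, seed = 90))
  ai <- tibble::tibble(image = names(attr(tbl, "true_scores")),
                       score = unname(attr(tbl, "true_scores")))
  res <- acceptance_analysis(tbl, ai)
  # brute-force recount
  merged <- merge(as.data.frame(tbl), data.frame(image = ai$image, ai = ai$score))
  d <- abs(merged$score - merged$ai)
  same4 <- as.character(categorize(merged$score, scheme_4cat())) ==
    as.character(categorize(merged$ai, scheme_4cat()))
  expect_equal(res$overall$fully_accepted, mean(d < 0.01 & same4))
  expect_equal(res$overall$almost_accepted, mean(d < 0.05 & same4))
  expect_equal(nrow(res$by_rater), 6)
  expect_true(all(res$by_rater$fully_accepted <= res$by_rater$almost_accepted))
})

test_that("fully <= almost on fuzzed acceptance inputs", {
  set.seed(91)
  for (rep in 1:20) {
    n <- 15
    rs <- data.frame(rater = "A", image = sprintf("i%02d", 1:n),
                     score = runif(n))
    ai <- data.frame(image = rs$image, score = pmin(pmax(
      rs$score + rnorm(n, sd = 0.03), 0), 1))
    res <- acceptance_analysis(rs, ai)
    expect_lte(res$overall$fully_accepted, res$overall$almost_accepted)
  }
})

test_that("binary disagreement counting over two rounds", {
  m <- matrix(c(0.005, 0.02, 0.10, 0.002), ncol = 1)
  tbl <- rbind(long_table(m, "RS1"), long_table(m, "RS2"))
  expect_equal(binary_disagreement_count(tbl)$count, 0)

  flip <- long_table(matrix(c(0.02, 0.005, 0.002, 0.10), ncol = 1), "RS2")
  tbl2 <- rbind(long_table(m, "RS1"), flip)
  res <- binary_disagreement_count(tbl2)
  expect_equal(res$count, 4)
  expect_equal(res$fraction, 1)
  expect_equal(res$total, 4)
})

test_that("concordance_report assembles all ring-study statistics", {
  tbl <- generate_rater_table(rater_sim_spec(n_raters = 5, n_images = 25,
                                             n_rounds = 2, seed = 92))
  truth <- attr(tbl, "true_scores")
  gold <- tibble::tibble(
    image = names(truth),
    category2 = as.character(categorize(unname(truth), scheme_2cat())),
    category4 = as.character(categorize(unname(truth), scheme_4cat())))
  ai <- tibble::tibble(image = names(truth), score = unname(truth))
  rep_tbl <- concordance_report(tbl, gold = gold, ai = ai)
  expect_true(all(c("ICC31", "FKS_2cat", "FKS_4cat", "ICC21_mean") %in%
                    rep_tbl$statistic))
  expect_true(all(rep_tbl$estimate[rep_tbl$statistic == "ICC31"] > 0.5))
  acc <- attr(rep_tbl, "accuracy")
  expect_s3_class(acc, "tbl_df")
  expect_true(all(acc$accuracy >= 0 & acc$accuracy <= 1))
  expect_s3_class(attr(rep_tbl, "acceptance"), "acceptance_result")
})

test_that("confidence intervals bracket estimates on fuzzed tables", {
  set.seed(93)
  for (rep in 1:10) {
    m <- matrix(runif(40), nrow = 10, ncol = 4)
    r31 <- icc31(long_table(m))
    expect_lte(r31$ci_low, r31$estimate)
    expect_gte(r31$ci_high, r31$estimate)
    r21 <- icc21(m[, 1], m[, 2])
    if (!is.na(r21$ci_low)) {
      expect_lte(r21$ci_low, r21$estimate)
      expect_gte(r21$ci_high, r21$estimate)
    }
    fk <- fleiss_kappa(matrix(sample(1:3, 30, TRUE), nrow = 10))
    expect_lte(fk$ci_low, fk$estimate)
    expect_gte(fk$ci_high, fk$estimate)
  }
})
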