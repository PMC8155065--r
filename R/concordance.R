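# Ring-study statistics: ICC(3,1), ICC(2,1), Fleiss' kappa, interpretation
# bands, categorical accuracy metrics, AI-acceptance analysis, and the
# binary intra-rater disagreement count.
#
# ICC estimates follow the standard two-way ANOVA taxonomy with the
# canonical F-based 95% confidence intervals (Shrout-Fleiss / McGraw-Wong
# forms).

new_concordance_result <- function(statistic, estimate, ci_low, ci_high,
                                   band, n_items, n_raters) {
  out <- tibble(statistic = statistic, estimate = estimate,
                ci_low = ci_low, ci_high = ci_high, band = band,
                n_items = n_items, n_raters = n_raters)
  class(out) <- c("concordance_result", class(out))
  out
}

# Two-way ANOVA mean squares for an items x raters matrix.
twoway_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

# Long data frame -> items x raters matrix for one round, listwise-deleting
# items with missing cells.
scores_to_matrix <- function(data, image = "image", rater = "rater",
                             score = "score", round = NULL, round_col = "round") {
  df <- as.data.frame(data)
  if (!is.null(round)) df <- df[df[[round_col]] == round, , drop = FALSE]
  if (nrow(df) == 0) abort("no rows to analyse", class = "pdl1ic_value_error")
  wide <- tapply(df[[score]], list(df[[image]], df[[rater]]), mean)
  keep <- complete.cases(wide)
  wide <- wide[keep, , drop = FALSE]
  if (nrow(wide) < 2 || ncol(wide) < 2) {
    abort("need at least 2 raters and 2 images after listwise deletion",
          class = "pdl1ic_value_error")
  }
  wide
}

#' Inter-rater ICC(3,1): two-way mixed effects, consistency, single measure
#'
#' Consistency ignores fixed rater offsets, so a rater who is uniformly
#' higher than the others does not lower the estimate. The 95% CI is the
#' standard F interval on `MSR/MSE`.
#'
#' @param data long-format data frame of scores.
#' @param image,rater,score column names.
#' @param round optional value of `round_col` to restrict to one round.
#' @param round_col column holding the round labels.
#' @param conf_level confidence level for the interval.
#' @return A one-row `concordance_result` tibble: `statistic`, `estimate`,
#'   `ci_low`, `ci_high`, `band`, `n_items`, `n_raters`.
#' @export
icc31 <- function(data, image = "image", rater = "rater", score = "score",
                  round = NULL, round_col = "round", conf_level = 0.95) {
  m <- scores_to_matrix(data, image, rater, score, round, round_col)
  ms <- twoway_ms(m)
  n <- ms$n; k <- ms$k
  est <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
  alpha <- 1 - conf_level
  f_obs <- ms$msr / ms$mse
  fl <- f_obs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  fu <- f_obs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  lo <- (fl - 1) / (fl + k - 1)
  hi <- (fu - 1) / (fu + k - 1)
  new_concordance_result("ICC31", est, lo, hi, interpret_icc(est), n, k)
}

#' Intra-rater ICC(2,1): two-way random effects, absolute agreement, single
#' measure
#'
#' Absolute agreement penalizes systematic offsets between the two
#' measurements; used for test-retest concordance of one rater across two
#' rounds. The CI uses the McGraw-Wong Satterthwaite construction.
#'
#' @param scores_a,scores_b paired score vectors over the same items.
#' @param conf_level confidence level.
#' @return A one-row `concordance_result` tibble.
#' @export
icc21 <- function(scores_a, scores_b, conf_level = 0.95) {
  if (length(scores_a) != length(scores_b)) {
    abort("paired score vectors must have equal length",
          class = "pdl1ic_shape_error")
  }
  m <- cbind(scores_a, scores_b)
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2) abort("need at least 2 paired items", class = "pdl1ic_value_error")
  ms <- twoway_ms(m)
  n <- ms$n; k <- ms$k
  est <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
  alpha <- 1 - conf_level
  if (est >= 1 || !is.finite(est)) {
    return(new_concordance_result("ICC21", est, NA_real_, NA_real_,
                                  interpret_icc(est), n, k))
  }
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (ms$msr - fl * ms$mse) /
    (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  hi <- n * (fu * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
  new_concordance_result("ICC21", est, lo, hi, interpret_icc(est), n, k)
}

#' Per-rater intra-rater concordance between two rounds
#'
#' Applies [icc21()] to each rater's paired scores across two rounds.
#'
#' @inheritParams icc31
#' @param round_a,round_b round labels to compare.
#' @return A tibble with one `concordance_result` row per rater plus a
#'   `rater` column.
#' @export
intra_rater_icc <- function(data, round_a = "RS1", round_b = "RS2",
                            image = "image", rater = "rater",
                            score = "score", round_col = "round") {
  df <- as.data.frame(data)
  a <- df[df[[round_col]] == round_a, c(rater, image, score)]
  b <- df[df[[round_col]] == round_b, c(rater, image, score)]
  names(a) <- c("rater", "image", "a")
  names(b) <- c("rater", "image", "b")
  merged <- merge(a, b, by = c("rater", "image"))
  rows <- lapply(split(merged, merged$rater), function(d) {
    res <- icc21(d$a, d$b)
    res$rater <- d$rater[1]
    res
  })
  dplyr::bind_rows(rows)
}

#' Fleiss' kappa for multi-rater categorical agreement
#'
#' The classic chance-corrected statistic
#' `kappa = (Pbar - Pe) / (1 - Pe)` for `n` items each assigned to one of
#' `k` categories by the same number `m` of raters. The 95% CI uses the
#' asymptotic standard error of the classic formulation with a normal
#' approximation; a seeded bootstrap over items is available instead.
#'
#' @param assignments items x raters matrix (or data frame) of category
#'   labels.
#' @param k_categories number of categories; inferred from the data when
#'   `NULL`.
#' @param conf_level confidence level.
#' @param ci `"asymptotic"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return A one-row `concordance_result` tibble with the FKS band label.
#' @export
fleiss_kappa <- function(assignments, k_categories = NULL, conf_level = 0.95,
                         ci = c("asymptotic", "bootstrap"), n_boot = 2000L,
                         seed = 1L) {
  ci <- match.arg(ci)
  x <- as.matrix(assignments)
  if (anyNA(x)) abort("assignments must not contain NA", class = "pdl1ic_value_error")
  n <- nrow(x); m <- ncol(x)
  if (m < 2) abort("need at least 2 raters per item", class = "pdl1ic_value_error")
  levels_all <- sort(unique(as.vector(x)))
  if (!is.null(k_categories) && length(levels_all) > k_categories) {
    abort("more distinct categories than k_categories", class = "pdl1ic_value_error")
  }
  counts <- t(apply(x, 1, function(row) table(factor(row, levels = levels_all))))
  if (length(levels_all) == 1) counts <- matrix(m, n, 1)

  kappa_from_counts <- function(cnt) {
    mm <- unique(rowSums(cnt))
    stopifnot(length(mm) == 1)
    p_j <- colSums(cnt) / (nrow(cnt) * mm)
    pe <- sum(p_j^2)
    if (pe >= 1) {
      abort("degenerate table: all assignments in a single category",
            class = "pdl1ic_value_error")
    }
    p_i <- (rowSums(cnt^2) - mm) / (mm * (mm - 1))
    pbar <- mean(p_i)
    list(kappa = (pbar - pe) / (1 - pe), p_j = p_j, pe = pe)
  }
  k0 <- kappa_from_counts(counts)
  est <- k0$kappa
  alpha <- 1 - conf_level
  if (ci == "asymptotic") {
    p_j <- k0$p_j; pe <- k0$pe
    se <- sqrt(2 / (n * m * (m - 1))) *
      sqrt(pe - (2 * m - 3) * pe^2 + 2 * (m - 2) * sum(p_j^3)) / (1 - pe)
    z <- qnorm(1 - alpha / 2)
    lo <- est - z * se; hi <- est + z * se
  } else {
    boots <- with_local_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        tryCatch(kappa_from_counts(counts[idx, , drop = FALSE])$kappa,
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    qs <- quantile(boots, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  lo <- min(lo, est); hi <- max(hi, est)
  new_concordance_result("FleissKappa", est, lo, hi, interpret_fks(est), n, m)
}

#' Interpretation bands for ICC and Fleiss' kappa values
#'
#' ICC: "poor" below 0.5, "moderate" in \[0.5, 0.75), "good" in
#' \[0.75, 0.9), "excellent" in \[0.9, 1\]. Fleiss' kappa: "below weak"
#' under 0.4, then "weak", "moderate" (0.6), "strong" (0.8), "near perfect"
#' (\[0.9, 1\]). Bands are half-open on the right with the top value in the
#' top band; negative ICC estimates map to "poor".
#'
#' @param value statistic value.
#' @return Character band label.
#' @export
interpret_icc <- function(value) {
  vapply(value, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v < 0.5) "poor"
    else if (v < 0.75) "moderate"
    else if (v < 0.9) "good"
    else "excellent"
  }, character(1))
}

#' @rdname interpret_icc
#' @export
interpret_fks <- function(value) {
  vapply(value, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v < 0.4) "below weak"
    else if (v < 0.6) "weak"
    else if (v < 0.8) "moderate"
    else if (v < 0.9) "strong"
    else "near perfect"
  }, character(1))
}

# Rank-based one-vs-rest AUC of numeric decision values for a binary truth.
binary_auc <- function(truth, value) {
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(value)
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Categorical accuracy metrics against a gold standard
#'
#' Accuracy is the exact-match fraction; weighted F1 averages per-class F1
#' with gold-class support weights; AUC is one-vs-rest, using the ordered
#' category index as the decision value, support-weighted over the classes
#' present in the gold labels.
#'
#' @param predicted,gold category label vectors (factors or characters) on
#'   the scheme's labels.
#' @param scheme the `category_scheme` defining the labels and their order.
#' @return A one-row tibble: `accuracy`, `weighted_f1`, `auc`, `n`.
#' @export
accuracy_metrics <- function(predicted, gold, scheme = scheme_4cat()) {
  stopifnot(inherits(scheme, "category_scheme"))
  if (length(predicted) != length(gold) || length(gold) == 0) {
    abort("predicted and gold must be aligned, nonempty vectors",
          class = "pdl1ic_shape_error")
  }
  p <- factor(as.character(predicted), levels = scheme$labels)
  g <- factor(as.character(gold), levels = scheme$labels)
  if (anyNA(p) || anyNA(g)) {
    abort("labels outside the scheme", class = "pdl1ic_value_error")
  }
  acc <- mean(p == g)
  conf <- table(gold = g, predicted = p)
  support <- rowSums(conf)
  f1 <- vapply(scheme$labels, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  wf1 <- sum(f1 * support) / sum(support)
  # one-vs-rest decision value for class j from a hard ordinal label:
  # proximity of the predicted category index to j
  p_idx <- as.integer(p)
  aucs <- vapply(seq_along(scheme$labels), function(j) {
    binary_auc(g == scheme$labels[j], -abs(p_idx - j))
  }, numeric(1))
  present <- support > 0 & !is.na(aucs)
  auc <- if (any(present)) sum(aucs[present] * support[present]) / sum(support[present])
  else NA_real_
  tibble(accuracy = acc, weighted_f1 = wf1, auc = auc, n = length(g))
}

#' Acceptance analysis of AI scores by raters
#'
#' Per (rater, image) cell: the AI score is *fully accepted* when the
#' absolute score difference is below `full_thresh` (1% by default) and
#' both scores fall in the same 4-category bin; *almost accepted* when the
#' difference is below `almost_thresh` (5%) with the same-bin requirement;
#' *categorically accepted* per scheme when both scores share a bin.
#'
#' @param rater_scores data frame with columns `rater`, `image`, `score`
#'   (fractions) and optionally `group`.
#' @param ai_scores data frame with columns `image`, `score` (fractions),
#'   or a named numeric vector keyed by image.
#' @param full_thresh,almost_thresh absolute score-difference thresholds
#'   (fractions).
#' @return An `acceptance_result` list of tibbles: `overall`, `by_rater`,
#'   and `by_group` (when a `group` column is present), each with
#'   `fully_accepted`, `almost_accepted`, `cat2_accepted`, `cat4_accepted`
#'   fractions.
#' @export
acceptance_analysis <- function(rater_scores, ai_scores,
                                full_thresh = 0.01, almost_thresh = 0.05) {
  rs <- as_tibble(rater_scores)
  if (is.numeric(ai_scores) && !is.null(names(ai_scores))) {
    ai_scores <- tibble(image = names(ai_scores), ai_score = unname(ai_scores))
  } else {
    ai_scores <- as_tibble(ai_scores)
    names(ai_scores)[names(ai_scores) == "score"] <- "ai_score"
  }
  missing_imgs <- setdiff(unique(rs$image), ai_scores$image)
  if (length(missing_imgs) > 0) {
    abort(paste0("missing AI score for image(s): ",
                 paste(head(missing_imgs, 5), collapse = ", ")),
          class = "pdl1ic_value_error")
  }
  df <- dplyr::inner_join(rs, ai_scores, by = "image")
  s4 <- scheme_4cat(); s2 <- scheme_2cat()
  df <- df |>
    mutate(
      diff = abs(.data$score - .data$ai_score),
      same4 = categorize(.data$score, s4) == categorize(.data$ai_score, s4),
      same2 = categorize(.data$score, s2) == categorize(.data$ai_score, s2),
      fully = .data$diff < full_thresh & .data$same4,
      almost = .data$diff < almost_thresh & .data$same4
    )
  agg <- function(d) {
    summarise(d,
              fully_accepted = mean(.data$fully),
              almost_accepted = mean(.data$almost),
              cat2_accepted = mean(.data$same2),
              cat4_accepted = mean(.data$same4),
              n = dplyr::n())
  }
  out <- list(overall = agg(df),
              by_rater = agg(group_by(df, .data$rater)) |> ungroup())
  if ("group" %in% names(df)) {
    out$by_group <- agg(group_by(df, .data$group)) |> ungroup()
  }
  structure(out, class = "acceptance_result")
}

#' @export
print.acceptance_result <- function(x, ...) {
  o <- x$overall
  cat(sprintf(paste0("<acceptance_result: fully %.1f%%, almost %.1f%%, ",
                     "2-cat %.1f%%, 4-cat %.1f%% (n=%d)>\n"),
              100 * o$fully_accepted, 100 * o$almost_accepted,
              100 * o$cat2_accepted, 100 * o$cat4_accepted, o$n))
  invisible(x)
}

#' Binary scoring disagreements between two rounds
#'
#' Binarizes both rounds at a percent cutoff and counts (rater, image)
#' cells whose binary label differs.
#'
#' @param data long-format data frame of scores (fractions).
#' @param round_a,round_b round labels to compare.
#' @param cutoff positivity cutoff in percent.
#' @param image,rater,score,round_col column names.
#' @return A one-row tibble: `count`, `total`, `fraction`.
#' @export
binary_disagreement_count <- function(data, round_a = "RS1", round_b = "RS2",
                                      cutoff = 1, image = "image",
                                      rater = "rater", score = "score",
                                      round_col = "round") {
  df <- as.data.frame(data)
  a <- df[df[[round_col]] == round_a, c(rater, image, score)]
  b <- df[df[[round_col]] == round_b, c(rater, image, score)]
  names(a) <- c("rater", "image", "a")
  names(b) <- c("rater", "image", "b")
  merged <- merge(a, b, by = c("rater", "image"))
  if (nrow(merged) == 0 || nrow(merged) < nrow(a) || nrow(merged) < nrow(b)) {
    abort("rounds must share identical (rater, image) keys",
          class = "pdl1ic_value_error")
  }
  pos_a <- merged$a * 100 >= cutoff
  pos_b <- merged$b * 100 >= cutoff
  cnt <- sum(pos_a != pos_b)
  tibble(count = cnt, total = nrow(merged), fraction = cnt / nrow(merged))
}

#' Full concordance report for a ring-study score table
#'
#' Computes ICC(3,1) per round, mean intra-rater ICC(2,1) between the first
#' two rounds, and Fleiss' kappa per categorical scheme per round;
#' optionally accuracy metrics against a per-image gold category and an
#' acceptance analysis against per-image AI scores.
#'
#' @param data long-format score table (`rater`, `image`, `round`, `score`
#'   fractions, optional `group`).
#' @param gold optional data frame (`image`, `category2`, `category4`) of
#'   gold-standard labels.
#' @param ai optional data frame (`image`, `score`) of AI scores.
#' @return A tibble of statistics (`statistic`, `round`, `estimate`,
#'   `ci_low`, `ci_high`, `band`), with any accuracy/acceptance tables
#'   attached as attributes `"accuracy"` and `"acceptance"`.
#' @export
concordance_report <- function(data, gold = NULL, ai = NULL) {
  df <- as_tibble(data)
  rounds <- sort(unique(df$round))
  rows <- list()
  for (r in rounds) {
    res <- icc31(df, round = r)
    rows[[length(rows) + 1]] <- tibble(statistic = "ICC31", round = r,
                                       estimate = res$estimate,
                                       ci_low = res$ci_low, ci_high = res$ci_high,
                                       band = res$band)
    for (sch in list(scheme_2cat(), scheme_4cat())) {
      sub <- df[df$round == r, ]
      m <- tapply(as.character(categorize(sub$score, sch)),
                  list(sub$image, sub$rater), function(x) x[1])
      m <- m[complete.cases(m), , drop = FALSE]
      fk <- fleiss_kappa(m)
      rows[[length(rows) + 1]] <- tibble(statistic = paste0("FKS_", sch$name),
                                         round = r, estimate = fk$estimate,
                                         ci_low = fk$ci_low, ci_high = fk$ci_high,
                                         band = fk$band)
    }
  }
  if (length(rounds) >= 2) {
    intra <- intra_rater_icc(df, rounds[1], rounds[2])
    rows[[length(rows) + 1]] <- tibble(statistic = "ICC21_mean",
                                       round = paste(rounds[1], rounds[2], sep = "-"),
                                       estimate = mean(intra$estimate),
                                       ci_low = NA_real_, ci_high = NA_real_,
                                       band = interpret_icc(mean(intra$estimate)))
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(gold)) {
    accs <- lapply(rounds, function(r) {
      sub <- dplyr::inner_join(df[df$round == r, ], as_tibble(gold), by = "image")
      a4 <- accuracy_metrics(as.character(categorize(sub$score, scheme_4cat())),
                             sub$category4, scheme_4cat())
      a2 <- accuracy_metrics(as.character(categorize(sub$score, scheme_2cat())),
                             sub$category2, scheme_2cat())
      tibble(round = r,
             scheme = c("2cat", "4cat"),
             accuracy = c(a2$accuracy, a4$accuracy),
             weighted_f1 = c(a2$weighted_f1, a4$weighted_f1),
             auc = c(a2$auc, a4$auc))
    })
    attr(out, "accuracy") <- dplyr::bind_rows(accs)
  }
  if (!is.null(ai)) {
    last <- rounds[length(rounds)]
    attr(out, "acceptance") <- acceptance_analysis(df[df$round == last, ], ai)
  }
  out
}
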