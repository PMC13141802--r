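test_that("design tables align codings with responses", {
  cfg <- sim_config(seed = 33, n_subjects_per_group = 3, n_bins = 40)
  tab <- simulate_change_table(cfg)
  resp <- simulate_responses(tab, cfg)
  des <- build_designs(tab, resp)

  expect_equal(nrow(des$count), 6 * 40) # subjects x bins
  expect_equal(nrow(des$types), 6 * 40)
  # n_changes equals the sum of flags row by row
  joined <- dplyr::inner_join(des$count, des$types,
    by = c("subject_id", "bin", "group", "response")
  )
  flags <- c("character", "character_character", "character_object", "temporal",
             "space_large", "space_small", "cause", "goal", "scene")
  expect_equal(joined$n_changes, as.integer(rowSums(joined[, flags])))

  # a subject with no responses is retained with an all-zero column
  resp0 <- dplyr::mutate(resp,
    response = ifelse(.data$subject_id == "S001", 0L, .data$response)
  )
  des0 <- build_designs(tab, resp0)
  expect_equal(sum(des0$count$response[des0$count$subject_id == "S001"]), 0)
  expect_equal(dplyr::n_distinct(des0$count$subject_id), 6)

  expect_error(build_designs(tab[1:10, ], resp), "misaligned")
})

test_that("odds ratios are exact exponentials and fits recover a no-ranef model", {
  cfg <- sim_config(
    seed = 34, n_subjects_per_group = 8, n_bins = 250,
    random_intercept_sd = 0, beta0 = -2.2, beta_count = 0.5,
    beta_group_interaction = 0
  )
  tab <- simulate_change_table(cfg)
  des <- build_designs(tab, simulate_responses(tab, cfg))
  fit <- fit_mixed_logit(des$count)

  expect_equal(fit$coefficients$odds_ratio, exp(fit$coefficients$estimate))
  expect_equal(fit$coefficients$or_low, exp(fit$coefficients$conf_low))

  # with a zero generating intercept SD, glmer and plain glm agree
  ref <- stats::glm(response ~ n_changes * group, data = des$count, family = binomial())
  for (term in c("n_changes", "n_changes:group")) {
    expect_lt(
      abs(fit$coefficients$estimate[fit$coefficients$term == term] -
            coef(ref)[[term]]),
      2 * summary(ref)$coefficients[term, 2]
    )
  }
  expect_true(fit$converged)
  expect_equal(glance(fit)$n_subjects, 16)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_segmentation_curve(fit), "ggplot")
  # broom-style exponentiated tidy output
  td <- tidy(fit, exponentiate = TRUE)
  expect_equal(td$estimate, td$odds_ratio)
})

test_that("null interaction intervals cover one across replicates", {
  covered <- vapply(1:5, function(r) {
    cfg <- sim_config(
      seed = 40 + r, n_subjects_per_group = 6, n_bins = 200,
      beta_group_interaction = 0
    )
    tab <- simulate_change_table(cfg)
    fit <- fit_mixed_logit(build_designs(tab, simulate_responses(tab, cfg))$count)
    row <- fit$coefficients[fit$coefficients$term == "n_changes:group", ]
    row$or_low <= 1 && 1 <= row$or_high
  }, logical(1))
  expect_gte(sum(covered), 4)
})

test_that("mean event length and its group test behave as defined", {
  expect_equal(mean_event_length(seq(0, 1799, by = 30), 1800), 30)
  expect_error(mean_event_length(numeric(), 1800), "undefined")

  streams <- tibble::tibble(
    subject_id = rep(c("a", "b", "c", "d"), each = 3),
    group = rep(c(0, 0, 1, 1), each = 3),
    time = runif(12, 0, 100)
  )
  res <- event_length_test(streams, 1800)
  expect_equal(res$statistic, 0) # identical counts -> identical lengths
  expect_equal(res$df, 2)

  set.seed(35)
  streams2 <- tibble::tibble(
    subject_id = c(
      rep(sprintf("s%02d", 1:5), times = sample(8:14, 5, replace = TRUE)),
      rep(sprintf("s%02d", 6:10), times = sample(16:24, 5, replace = TRUE))
    ),
    group = as.integer(subject_id > "s05"),
    time = runif(length(subject_id), 0, 1800)
  )
  streams2 <- dplyr::arrange(streams2, subject_id, time)
  res2 <- event_length_test(streams2, 1800)
  # longhand pooled t on the per-subject mean lengths
  lens <- 1800 / table(streams2$subject_id)
  g <- tapply(streams2$group, streams2$subject_id, max)
  a <- lens[g == 0]
  b <- lens[g == 1]
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / (length(a) + length(b) - 2)
  t_long <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(res2$statistic, unname(t_long))
})

test_that("summary-statistic t tests reproduce a printed demographics table", {
  # mean (SD) rows with group sizes implied by the printed dfs
  rows <- list(
    list(96.7, 14.5, 30, 101.5, 16.7, 30, -1.20),
    list(108.7, 12.9, 30, 104.8, 19.5, 30, 0.90),
    list(3.8, 2.4, 29, 18.7, 8.1, 22, -9.41),
    list(1.0, 0.9, 29, 7.7, 4.0, 22, -8.82),
    list(1.9, 1.9, 29, 6.5, 2.8, 22, -6.92),
    list(0.8, 1.3, 29, 4.1, 2.6, 22, -6.10),
    list(51.8, 4.3, 29, 62.9, 9.6, 20, -5.51),
    list(53.1, 4.0, 29, 56.5, 6.8, 20, -2.19),
    list(51.7, 3.9, 29, 56.7, 7.7, 20, -2.98),
    list(50.8, 3.4, 29, 66.0, 8.4, 20, -8.71),
    list(51.0, 2.7, 29, 65.1, 11.9, 20, -6.15),
    list(51.3, 3.5, 29, 63.0, 8.6, 20, -6.54),
    list(52.3, 5.5, 29, 55.6, 6.3, 20, -1.95),
    list(51.0, 3.6, 29, 58.4, 7.9, 20, -4.39)
  )
  for (r in rows) {
    res <- t_from_summary(r[[1]], r[[2]], r[[3]], r[[4]], r[[5]], r[[6]])
    expect_equal(res$df, r[[3]] + r[[6]] - 2)
    expect_lt(abs(res$statistic - r[[7]]) / abs(r[[7]]), 0.03)
  }
  expect_equal(t_from_summary(5, 1, 10, 5, 1, 10)$statistic, 0)

  # random inputs against a longhand textbook evaluation
  set.seed(36)
  for (i in 1:10) {
    m1 <- rnorm(1); m2 <- rnorm(1); s1 <- runif(1, 0.5, 3); s2 <- runif(1, 0.5, 3)
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    expect_equal(
      t_from_summary(m1, s1, n1, m2, s2, n2)$statistic,
      (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    )
  }
})

test_that("chi-square recomputation matches the printed education comparison", {
  # counts reconstructed from printed percentages of 60 parents per group,
  # dropping the no-information category
  edu <- rbind(nt = c(9, 26, 12, 12, 0), asd = c(2, 17, 6, 19, 2))
  res <- chisq_from_table(edu)
  expect_equal(res$n, 105)
  expect_equal(res$df, 4)
  expect_equal(res$statistic, 10.47, tolerance = 0.005)
  expect_lt(res$p_value, 0.05)

  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(chisq_from_table(prop)$statistic, 0)

  tab22 <- rbind(c(12, 5), c(7, 16))
  n <- sum(tab22)
  num <- (tab22[1, 1] * tab22[2, 2] - tab22[1, 2] * tab22[2, 1])^2 * n
  den <- prod(rowSums(tab22)) * prod(colSums(tab22))
  expect_equal(chisq_from_table(tab22)$statistic, num / den)

  expect_error(chisq_from_table(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("the exclusion cascade reproduces the final sample size", {
  casc <- exclusion_cascade()
  expect_equal(casc$total[casc$step == "matched"], 64)
  final <- casc[nrow(casc), ]
  expect_equal(final$asd, 30)
  expect_equal(final$nt, 30)
  expect_equal(final$total, 60)
})
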