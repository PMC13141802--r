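#' Build design tables for the segmentation-probability models
#'
#' Joins the per-bin situational-change coding to each subject's per-bin
#' responses, yielding one row per subject x bin. Two designs are returned:
#' the count model (`response ~ n_changes * group`) and the type model
#' (`response ~ (each of the nine change flags) * group`), both fit with a
#' subject-level random intercept. Change counts enter linearly, as in the
#' single-slope model.
#'
#' @param change_table A `change_table` ([simulate_change_table()] or read
#'   from TSV) with `bin`, the nine flag columns and `n_changes`.
#' @param responses A tibble with `subject_id`, `group`, `bin`, `response`
#'   (e.g. from [simulate_responses()]); subjects with no responses are
#'   retained with an all-zero response column.
#' @return A list with tibbles `count` and `types`, each one row per
#'   subject x bin.
#' @export
build_designs <- function(change_table, responses) {
  flags <- intersect(change_type_names(), names(change_table))
  if (length(flags) != 9L) abort("`change_table` must carry the nine change-type columns.")
  need <- c("subject_id", "group", "bin", "response")
  if (!all(need %in% names(responses))) {
    abort("`responses` must have subject_id, group, bin, response.")
  }
  n_sub <- dplyr::n_distinct(responses$subject_id)
  if (nrow(responses) != n_sub * nrow(change_table) ||
      !setequal(unique(responses$bin), change_table$bin)) {
    abort("Bins of `responses` and `change_table` are misaligned.")
  }
  joined <- dplyr::inner_join(
    dplyr::select(responses, dplyr::all_of(need)),
    change_table[, c("bin", flags, "n_changes")],
    by = "bin"
  )
  joined <- dplyr::arrange(joined, .data$subject_id, .data$bin)
  list(
    count = dplyr::select(
      joined, "subject_id", "group", "bin", "response", "n_changes"
    ),
    types = dplyr::select(
      joined, "subject_id", "group", "bin", "response", dplyr::all_of(flags)
    )
  )
}

#' Fit a mixed-effects logistic segmentation model
#'
#' Maximum-likelihood (Laplace) fit of a logistic regression with a Gaussian
#' subject-level random intercept, via [lme4::glmer()]. The count model is
#' `response ~ n_changes * group + (1 | subject_id)`; the type model replaces
#' `n_changes` with the nine change-type flags (each interacting with group).
#' Wald 95% intervals are reported as the frequentist analogue of credible
#' intervals, and odds ratios are the exponentiated estimates. Non-convergence
#' is flagged on the result, not raised.
#'
#' @param design A design tibble from [build_designs()] (`$count` or
#'   `$types`).
#' @param model `"count"` or `"types"` (auto-detected from the columns when
#'   missing).
#' @param ... Passed to [lme4::glmer()].
#' @return An object of class `seg_glmm`: list with `coefficients` (tibble:
#'   `term`, `estimate`, `std_error`, `conf_low`, `conf_high`, `odds_ratio`,
#'   `or_low`, `or_high`), `ranef_sd`, `converged`, `model`, `n_obs`,
#'   `n_subjects`, and the underlying `fit`.
#' @export
fit_mixed_logit <- function(design, model = NULL, ...) {
  flags <- intersect(change_type_names(), names(design))
  if (is.null(model)) {
    model <- if ("n_changes" %in% names(design)) "count" else "types"
  }
  model <- match.arg(model, c("count", "types"))
  if (dplyr::n_distinct(design$subject_id) < 2L) abort("At least 2 subjects are required.")
  if (dplyr::n_distinct(design$response) < 2L) {
    abort("Both response classes must be present.")
  }
  rhs <- if (model == "count") {
    "n_changes * group"
  } else {
    paste0("(", paste(flags, collapse = " + "), ") * group")
  }
  form <- stats::as.formula(paste("response ~", rhs, "+ (1 | subject_id)"))
  fit <- suppressMessages(lme4::glmer(form, data = design, family = stats::binomial(), ...))
  # boundary (singular) fits are legitimate when the true intercept SD is ~0;
  # only genuine optimizer failures are flagged
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  conv <- length(msgs) == 0L && fit@optinfo$conv$opt == 0L

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  coefs <- tibble::tibble(
    term = names(est),
    estimate = as.numeric(est),
    std_error = as.numeric(se),
    conf_low = .data$estimate - 1.96 * .data$std_error,
    conf_high = .data$estimate + 1.96 * .data$std_error,
    odds_ratio = exp(.data$estimate),
    or_low = exp(.data$conf_low),
    or_high = exp(.data$conf_high)
  )
  structure(
    list(
      coefficients = coefs,
      ranef_sd = sqrt(as.numeric(lme4::VarCorr(fit)$subject_id)),
      converged = conv,
      model = model,
      n_obs = nrow(design),
      n_subjects = dplyr::n_distinct(design$subject_id),
      fit = fit
    ),
    class = "seg_glmm"
  )
}

#' @export
print.seg_glmm <- function(x, ...) {
  cat(sprintf(
    "<seg_glmm> %s model, %d obs, %d subjects, ranef sd = %.3f%s\n",
    x$model, x$n_obs, x$n_subjects, x$ranef_sd,
    if (x$converged) "" else " [did not converge]"
  ))
  print(x$coefficients, ...)
  invisible(x)
}

#' Tidy a fitted segmentation model
#'
#' @param x A `seg_glmm`.
#' @param exponentiate Return odds ratios in `estimate` instead of log-odds.
#' @param ... Unused.
#' @return `tidy()`: one row per fixed effect. `glance()`: a one-row model
#'   summary.
#' @export
tidy.seg_glmm <- function(x, exponentiate = FALSE, ...) {
  out <- x$coefficients
  if (exponentiate) {
    out <- dplyr::mutate(
      out,
      estimate = .data$odds_ratio, conf_low = .data$or_low, conf_high = .data$or_high
    )
  }
  out
}

#' @rdname tidy.seg_glmm
#' @export
glance.seg_glmm <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_obs = x$n_obs,
    n_subjects = x$n_subjects,
    ranef_sd = x$ranef_sd,
    converged = x$converged,
    logLik = as.numeric(stats::logLik(x$fit)),
    AIC = stats::AIC(x$fit)
  )
}

#' Forest plot of fitted odds ratios
#'
#' @param object A `seg_glmm`.
#' @param ... Unused.
#' @return A ggplot object (odds ratios with 95% Wald intervals, log x scale).
#' @export
autoplot.seg_glmm <- function(object, ...) {
  df <- dplyr::filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$or_low, xmax = .data$or_high)
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Odds ratio (95% Wald interval)", y = NULL,
      title = "Segmentation-probability model"
    ) +
    ggplot2::theme_minimal()
}

#' Predicted segmentation probability by number of changes
#'
#' Population-level predicted probability curves (random intercept at 0) per
#' group from a fitted count model, in the style of the behavioural results
#' figure.
#'
#' @param fit A `seg_glmm` count model.
#' @param max_changes Largest change count to display.
#' @return A ggplot object.
#' @export
plot_segmentation_curve <- function(fit, max_changes = 5L) {
  stopifnot(inherits(fit, "seg_glmm"), fit$model == "count")
  cf <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  grid <- tidyr::expand_grid(n_changes = 0:max_changes, group = c(0, 1))
  grid$prob <- plogis(
    cf[["(Intercept)"]] + cf[["n_changes"]] * grid$n_changes +
      cf[["group"]] * grid$group +
      cf[["n_changes:group"]] * grid$n_changes * grid$group
  )
  grid$group <- factor(grid$group, levels = c(0, 1), labels = c("NT", "ASD"))
  ggplot2::ggplot(grid, ggplot2::aes(
    x = .data$n_changes, y = .data$prob, colour = .data$group
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Situational changes per 2-s bin", y = "P(event boundary)",
      colour = NULL, title = "Segmentation probability by change count"
    ) +
    ggplot2::theme_minimal()
}

#' Mean segmented event length
#'
#' The movie duration divided by a subject's number of responses.
#'
#' @param times Response times (s) of one subject.
#' @param duration Movie duration (s).
#' @return Mean event length in seconds.
#' @export
#' @examples
#' mean_event_length(seq(0, 1770, by = 30), 1800)
mean_event_length <- function(times, duration) {
  check_number(duration, "duration", lower = 1e-12)
  if (length(times) == 0L) abort("Mean event length is undefined without responses.")
  duration / length(times)
}

#' Compare mean event length between groups
#'
#' Computes each subject's mean event length and compares groups with a
#' pooled-variance two-sample t test.
#'
#' @param streams Response streams tibble (`subject_id`, `group`, `time`),
#'   e.g. from [response_streams()].
#' @param duration Movie duration (s).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_nt`,
#'   `mean_asd`.
#' @export
event_length_test <- function(streams, duration) {
  per_sub <- dplyr::summarise(
    dplyr::group_by(streams, .data$subject_id, .data$group),
    length = mean_event_length(.data$time, duration), .groups = "drop"
  )
  a <- per_sub$length[per_sub$group == 0]
  b <- per_sub$length[per_sub$group == 1]
  res <- t_from_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
  dplyr::mutate(res, mean_nt = mean(a), mean_asd = mean(b))
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance two-sample t with `df = n1 + n2 - 2`, computed from group
#' means, SDs and sizes — as needed to recompute printed group comparisons
#' from a demographics table.
#'
#' @param m1,sd1,n1 Mean, SD, size of group 1.
#' @param m2,sd2,n2 Mean, SD, size of group 2.
#' @return A one-row tibble: `statistic` (t, sign follows `m1 - m2`), `df`,
#'   `p_value`.
#' @export
#' @examples
#' t_from_summary(3.8, 2.4, 29, 18.7, 8.1, 22) # t = -9.40
t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  check_number(n1, "n1", lower = 2, integerish = TRUE)
  check_number(n2, "n2", lower = 2, integerish = TRUE)
  check_number(sd1, "sd1", lower = 0)
  check_number(sd2, "sd2", lower = 0)
  if (sd1 == 0 && sd2 == 0 && m1 == m2) {
    return(tibble::tibble(statistic = 0, df = n1 + n2 - 2, p_value = 1))
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble::tibble(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square with `df = (r - 1)(c - 1)` and no continuity
#' correction, via [stats::chisq.test()].
#'
#' @param counts An r x c matrix of non-negative integer counts.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n`.
#' @export
#' @examples
#' edu <- rbind(nt = c(9, 26, 12, 12, 0), asd = c(2, 17, 6, 19, 2))
#' chisq_from_table(edu) # chi-square = 10.47, df = 4, N = 105
chisq_from_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9)) {
    abort("`counts` must be non-negative integers.")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("Zero row or column marginal.")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(
    statistic = as.numeric(res$statistic),
    df = as.integer(res$parameter),
    p_value = as.numeric(res$p.value),
    n = sum(counts)
  )
}

#' Participant exclusion cascade
#'
#' Applies a sequence of exclusion steps to initial group sizes and returns
#' the running sample sizes. The default arguments encode the study's flow:
#' 36 ASD recruits lose 2 to recent medication and 2 to technical issues; the
#' remaining 32 are pair-matched by an equal number of NT adolescents drawn
#' from a pool of 90; 1 ASD behavioural outlier, 1 NT EEG-quality exclusion
#' and one subject per group without valid responses leave 30 per group.
#'
#' @param asd_initial,nt_pool Initial recruit counts.
#' @param asd_pre_matching Exclusions applied to the ASD group before
#'   matching (named integer vector).
#' @param post_matching Exclusions after matching: named list with `asd` and
#'   `nt` named integer vectors.
#' @return A tibble with columns `step`, `asd`, `nt`, `total`; the last row
#'   is the final sample.
#' @export
#' @examples
#' tail(exclusion_cascade(), 1) # 30 + 30 = 60
exclusion_cascade <- function(asd_initial = 36L,
                              nt_pool = 90L,
                              asd_pre_matching = c(medication = 2L, technical = 2L),
                              post_matching = list(
                                asd = c(behavioural_outlier = 1L, no_valid_responses = 1L),
                                nt = c(eeg_quality = 1L, no_valid_responses = 1L)
                              )) {
  asd <- asd_initial
  steps <- tibble::tibble(
    step = "recruited", asd = asd_initial, nt = nt_pool, total = asd_initial + nt_pool
  )
  for (nm in names(asd_pre_matching)) {
    asd <- asd - asd_pre_matching[[nm]]
    steps <- dplyr::bind_rows(steps, tibble::tibble(
      step = paste0("asd_", nm), asd = asd, nt = nt_pool, total = asd + nt_pool
    ))
  }
  nt <- asd # optimal pair matching selects an equal number of NT subjects
  steps <- dplyr::bind_rows(steps, tibble::tibble(
    step = "matched", asd = asd, nt = nt, total = asd + nt
  ))
  take <- function(v, nm) if (!is.null(v) && nm %in% names(v)) v[[nm]] else 0L
  all_steps <- unique(c(names(post_matching$asd), names(post_matching$nt)))
  for (nm in all_steps) {
    asd <- asd - take(post_matching$asd, nm)
    nt <- nt - take(post_matching$nt, nm)
    steps <- dplyr::bind_rows(steps, tibble::tibble(
      step = nm, asd = asd, nt = nt, total = asd + nt
    ))
  }
  steps
}
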