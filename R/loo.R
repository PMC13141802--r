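#' Leave-one-out jackknife distributions of CBPT cluster metrics
#'
#' Reruns the full cluster-based permutation test once per omitted group
#' member. For iteration `i` the test is run on all subjects but `i`, and two
#' metrics are recorded from the significant clusters of the dominant sign
#' (the sign of the largest absolute significant `t_sum`): `size`, the total
#' number of significant voxels, and `rel_t_sum`, the summed t values of those
#' voxels divided by `size` (the relative modulation strength; signed, so
#' down-modulations are negative). Iterations without a significant cluster
#' contribute `(0, 0)`. A group of `n` subjects yields exactly `n` iterations.
#'
#' @inheritParams cbpt
#' @param seed_policy `"fixed"` reuses `seed` for every iteration's
#'   permutation draws; `"per-iteration"` derives a distinct sub-seed per
#'   iteration.
#' @return A tibble of class `loo_metrics`: `iteration`, `left_out`, `size`,
#'   `rel_t_sum`, `any_significant`.
#' @export
loo_cbpt_metrics <- function(power_bi, power_nbi, adjacency, n_perm = 1000L,
                             alpha = 0.05, alpha_form = 0.05, seed = 1L,
                             seed_policy = c("fixed", "per-iteration")) {
  seed_policy <- match.arg(seed_policy)
  power_bi <- as.matrix(power_bi)
  power_nbi <- as.matrix(power_nbi)
  n <- nrow(power_bi)
  if (n < 3L) abort("Leave-one-out requires at least 3 subjects.")
  iter_seeds <- if (seed_policy == "fixed") rep(seed, n) else derive_seeds(seed, n)

  rows <- purrr::map_dfr(seq_len(n), function(i) {
    res <- tryCatch(
      cbpt(power_bi[-i, , drop = FALSE], power_nbi[-i, , drop = FALSE],
           adjacency, n_perm = n_perm, alpha = alpha,
           alpha_form = alpha_form, seed = iter_seeds[i]),
      error = function(e) {
        abort(sprintf("CBPT failed in leave-one-out iteration %d: %s", i,
                      conditionMessage(e)))
      }
    )
    sig <- dplyr::filter(res$clusters, .data$significant)
    if (nrow(sig) == 0L) {
      return(tibble::tibble(
        iteration = i, left_out = i, size = 0L, rel_t_sum = 0,
        any_significant = FALSE
      ))
    }
    dom_sign <- sig$sign[which.max(abs(sig$t_sum))]
    sig <- dplyr::filter(sig, .data$sign == dom_sign)
    size <- sum(sig$n_voxels)
    tibble::tibble(
      iteration = i, left_out = i, size = as.integer(size),
      rel_t_sum = sum(sig$t_sum) / size, any_significant = TRUE
    )
  })
  class(rows) <- c("loo_metrics", class(rows))
  rows
}

#' Wilcoxon-Mann-Whitney rank-sum test with effect size r
#'
#' Two-sample rank-sum comparison using midranks for ties. The standardized
#' statistic is `z = (U - n1 n2 / 2) / sd(U)` with the tie-corrected variance
#' `n1 n2 / 12 * ((N + 1) - sum(t^3 - t) / (N (N - 1)))`; the effect size is
#' `r = |z| / sqrt(n1 + n2)`. The two-sided p value uses the normal
#' approximation, except that with `n1 + n2 <= 12` and no ties it is computed
#' by exhaustive enumeration of all rank assignments. `z > 0` means `x` tends
#' to be larger than `y`. When every value in both samples is identical the
#' result is `z = 0, p = 1`.
#'
#' @param x,y Numeric samples.
#' @param metric Optional metric label carried into the output.
#' @return A one-row tibble: `metric`, `n1`, `n2`, `u`, `z`, `p_value`, `r`,
#'   `method`.
#' @export
#' @examples
#' wilcoxon_mann_whitney(c(1, 2, 3), c(4, 5, 6)) # exact p = 0.1
wilcoxon_mann_whitney <- function(x, y, metric = NA_character_) {
  if (!length(x) || !length(y)) abort("Both samples must be non-empty.")
  if (any(!is.finite(c(x, y)))) abort("Samples must be finite.")
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled) # midranks
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  tie_sizes <- table(pooled)
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))

  if (v <= 0) { # all values identical across both samples
    out <- tibble::tibble(
      metric = metric, n1 = n1, n2 = n2, u = U, z = 0, p_value = 1, r = 0,
      method = "degenerate"
    )
    return(out)
  }
  z <- (U - mu) / sqrt(v)

  if (N <= 12L && tie_term == 0) {
    # exhaustive: distribution of U over all choose(N, n1) rank assignments
    combos <- utils::combn(N, n1)
    all_u <- colSums(matrix(seq_len(N)[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(all_u - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  tibble::tibble(
    metric = metric, n1 = n1, n2 = n2, u = U, z = z,
    p_value = min(p, 1), r = abs(z) / sqrt(N), method = method
  )
}

#' Rank-sum effect size from a standardized statistic
#'
#' `r = |z| / sqrt(n)`, the conventional effect size of a rank-sum comparison
#' of `n = n1 + n2` observations.
#'
#' @param z Standardized rank-sum statistic.
#' @param n Total number of observations across both samples.
#' @return Effect size in `[0, 1]` (values above 1 cannot arise from a true
#'   rank-sum z at this n).
#' @export
#' @examples
#' rank_sum_r(6.85, 60) # 0.88
rank_sum_r <- function(z, n) {
  check_number(n, "n", lower = 2, integerish = TRUE)
  abs(z) / sqrt(n)
}

#' Compare jackknife cluster metrics between two groups
#'
#' One rank-sum comparison per metric (`size` and `rel_t_sum`), with `z > 0`
#' when group `a`'s values tend to be larger. Jackknife iterations are
#' statistically dependent; the rank-sum test is applied to them regardless,
#' which matches the analysis convention, and the dependency caveat is
#' documented. Set `magnitude = TRUE` to compare `|rel_t_sum|` instead of the
#' signed values.
#'
#' @param a,b `loo_metrics` tibbles from [loo_cbpt_metrics()].
#' @param magnitude Compare absolute `rel_t_sum` values.
#' @return A tibble of class `loo_comparison` with one row per metric:
#'   `metric`, `n1`, `n2`, `u`, `z`, `p_value`, `r`, `method`.
#' @export
compare_group_metrics <- function(a, b, magnitude = FALSE) {
  for (m in list(a, b)) {
    if (!all(c("size", "rel_t_sum") %in% names(m)) || nrow(m) == 0L) {
      abort("Both groups need leave-one-out iterations with `size` and `rel_t_sum`.")
    }
  }
  rel_a <- if (magnitude) abs(a$rel_t_sum) else a$rel_t_sum
  rel_b <- if (magnitude) abs(b$rel_t_sum) else b$rel_t_sum
  out <- dplyr::bind_rows(
    wilcoxon_mann_whitney(a$size, b$size, metric = "size"),
    wilcoxon_mann_whitney(rel_a, rel_b,
      metric = if (magnitude) "abs_rel_t_sum" else "rel_t_sum"
    )
  )
  class(out) <- c("loo_comparison", class(out))
  out
}

#' Plot jackknife metric distributions for two groups
#'
#' @param object A `loo_metrics` tibble (group A).
#' @param other A second `loo_metrics` tibble (group B); when omitted only
#'   one group is shown.
#' @param ... Unused.
#' @return A ggplot object: one panel per metric, jackknife iterations as
#'   points over boxplots.
#' @export
autoplot.loo_metrics <- function(object, other = NULL, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object), group = "group 1")
  if (!is.null(other)) {
    df <- dplyr::bind_rows(
      df, dplyr::mutate(tibble::as_tibble(other), group = "group 2")
    )
  }
  long <- tidyr::pivot_longer(
    dplyr::select(df, "group", "size", "rel_t_sum"),
    cols = c("size", "rel_t_sum"), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "Leave-one-out CBPT cluster metrics"
    ) +
    ggplot2::theme_minimal()
}
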