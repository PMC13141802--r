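#' Dependent-samples t map for a paired condition contrast
#'
#' Per voxel, the paired t statistic of the subject-wise BI - NBI differences:
#' `t = mean(d) / (sd(d) / sqrt(n))`.
#'
#' @param power_bi,power_nbi Numeric subject x voxel matrices, same subjects
#'   in the same row order.
#' @return Numeric vector of per-voxel t values.
#' @export
paired_t_map <- function(power_bi, power_nbi) {
  power_bi <- as.matrix(power_bi)
  power_nbi <- as.matrix(power_nbi)
  if (!identical(dim(power_bi), dim(power_nbi))) {
    abort("Conditions must have identical subject x voxel dimensions.")
  }
  n <- nrow(power_bi)
  if (n < 2L) abort("At least 2 subjects are required for a paired t map.")
  d <- power_bi - power_nbi
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  t <- ifelse(v > 0, m / sqrt(v / n), 0)
  as.numeric(t)
}

#' Form signed suprathreshold clusters
#'
#' Thresholds the t map at the two-sided critical value of a dependent-samples
#' t distribution at `alpha_form`, then finds connected components among
#' suprathreshold voxels separately for positive and negative signs. The
#' cluster statistic is `t_sum`, the sum of member t values.
#'
#' @param t_map Per-voxel t values.
#' @param adjacency A [build_adjacency()] graph over the same voxels.
#' @param df Degrees of freedom of the t map (`n - 1` for paired data).
#' @param alpha_form Two-sided cluster-forming alpha.
#' @return A tibble with one row per cluster: `cluster_id`, `sign` ("+"/"-"),
#'   `n_voxels`, `t_sum`, `voxels` (list column of voxel ids), sorted by
#'   `|t_sum|` descending. Zero rows when nothing is suprathreshold.
#' @export
form_clusters <- function(t_map, adjacency, df, alpha_form = 0.05) {
  stopifnot(inherits(adjacency, "voxel_adjacency"))
  check_number(df, "df", lower = 1)
  check_number(alpha_form, "alpha_form", lower = 1e-12, upper = 1 - 1e-12)
  if (length(t_map) != length(adjacency$neighbors)) {
    abort("`t_map` and `adjacency` must cover the same voxels.")
  }
  thr <- qt(1 - alpha_form / 2, df = df)
  labels <- cluster_labels_cpp(as.numeric(t_map), thr, adjacency$ptr, adjacency$idx)
  ids <- sort(unique(labels[labels > 0L]))
  out <- purrr::map_dfr(ids, function(id) {
    vox <- which(labels == id)
    ts <- sum(t_map[vox])
    tibble::tibble(
      cluster_id = id,
      sign = if (ts >= 0) "+" else "-",
      n_voxels = length(vox),
      t_sum = ts,
      voxels = list(adjacency$voxel_id[vox])
    )
  })
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      cluster_id = integer(), sign = character(), n_voxels = integer(),
      t_sum = numeric(), voxels = list()
    )
  }
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$t_sum)))
  out$cluster_id <- seq_len(nrow(out))
  out
}

#' Cluster-based permutation test for a paired BI vs NBI power contrast
#'
#' Nonparametric family-wise-corrected test: the observed dependent-samples t
#' map is thresholded and clustered ([form_clusters()]); a permutation null is
#' built by independently flipping each subject's condition labels (the 2^n
#' sign-flip scheme, sampled, or exhausted when `exhaustive = TRUE`),
#' recomputing the t map and recording the maximum absolute cluster `t_sum`.
#' Each observed cluster's Monte-Carlo p value is
#' `(1 + #\{perm max >= |t_sum|\}) / (n_perm + 1)`, which cannot drop below
#' `1 / (n_perm + 1)`. Correction uses the max over both signs, i.e. two-sided
#' family-wise control, with positive and negative clusters reported
#' separately.
#'
#' @inheritParams paired_t_map
#' @inheritParams form_clusters
#' @param n_perm Number of sign-flip permutations.
#' @param alpha Cluster-level significance threshold.
#' @param alpha_form Two-sided cluster-forming alpha.
#' @param seed Integer seed for the permutation draws.
#' @param exhaustive Enumerate all `2^n` sign patterns instead of sampling
#'   (requires `n <= 20`); `n_perm` is then ignored.
#' @return An object of class `cbpt_result`: list with `clusters` (the
#'   [form_clusters()] tibble plus `p_value` and `significant`), `t_map`,
#'   `null_max` (permutation distribution), `n_perm`, `alpha`, `alpha_form`,
#'   `df`, `seed`.
#' @export
#' @examples
#' grid <- make_grid(c(4, 4, 2))
#' adj <- build_adjacency(grid)
#' set.seed(1)
#' bi <- matrix(rnorm(8 * nrow(grid)), 8)
#' nbi <- matrix(rnorm(8 * nrow(grid)), 8)
#' res <- cbpt(bi, nbi, adj, n_perm = 99, seed = 1)
#' tidy(res)
cbpt <- function(power_bi, power_nbi, adjacency, n_perm = 1000L,
                 alpha = 0.05, alpha_form = 0.05, seed = 1L,
                 exhaustive = FALSE) {
  stopifnot(inherits(adjacency, "voxel_adjacency"))
  check_number(n_perm, "n_perm", lower = 1, integerish = TRUE)
  check_number(alpha, "alpha", lower = 1e-12, upper = 1)
  check_number(seed, "seed", integerish = TRUE)
  power_bi <- as.matrix(power_bi)
  power_nbi <- as.matrix(power_nbi)
  n <- nrow(power_bi)
  t_obs <- paired_t_map(power_bi, power_nbi)
  df <- n - 1L
  clusters <- form_clusters(t_obs, adjacency, df = df, alpha_form = alpha_form)

  if (exhaustive) {
    if (n > 20L) abort("Exhaustive enumeration is limited to n <= 20 subjects.")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    dimnames(signs) <- NULL
    n_perm <- nrow(signs)
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  D <- power_bi - power_nbi
  thr <- qt(1 - alpha_form / 2, df = df)
  null_max <- perm_max_tsum_cpp(D, signs, thr, adjacency$ptr, adjacency$idx)

  if (nrow(clusters)) {
    clusters$p_value <- vapply(
      clusters$t_sum,
      function(ts) (1 + sum(null_max >= abs(ts))) / (n_perm + 1),
      numeric(1)
    )
    clusters$significant <- clusters$p_value <= alpha
  } else {
    clusters$p_value <- numeric()
    clusters$significant <- logical()
  }

  structure(
    list(
      clusters = clusters, t_map = t_obs, null_max = null_max,
      n_perm = as.integer(n_perm), alpha = alpha, alpha_form = alpha_form,
      df = df, seed = as.integer(seed), exhaustive = exhaustive
    ),
    class = "cbpt_result"
  )
}

#' @export
print.cbpt_result <- function(x, ...) {
  cat(sprintf(
    "<cbpt_result> %d cluster(s), %d significant at alpha = %g (%d permutations)\n",
    nrow(x$clusters), sum(x$clusters$significant), x$alpha, x$n_perm
  ))
  if (nrow(x$clusters)) {
    print(dplyr::select(x$clusters, -"voxels"), ...)
  }
  invisible(x)
}

#' Tidy a cluster-based permutation test result
#'
#' @param x A `cbpt_result`.
#' @param ... Unused.
#' @return `tidy()`: one row per cluster (`cluster_id`, `sign`, `n_voxels`,
#'   `t_sum`, `p_value`, `significant`, `voxels` list column). `glance()`:
#'   a one-row summary.
#' @export
tidy.cbpt_result <- function(x, ...) {
  x$clusters
}

#' @rdname tidy.cbpt_result
#' @export
glance.cbpt_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    min_p = if (nrow(x$clusters)) min(x$clusters$p_value) else NA_real_,
    max_abs_t_sum = if (nrow(x$clusters)) max(abs(x$clusters$t_sum)) else NA_real_,
    n_perm = x$n_perm,
    alpha = x$alpha,
    alpha_form = x$alpha_form,
    df = x$df
  )
}

#' Plot the permutation null against observed cluster statistics
#'
#' Histogram of the permutation distribution of the maximum absolute cluster
#' `t_sum`, with vertical lines at the observed cluster statistics (solid for
#' significant clusters).
#'
#' @param object A `cbpt_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cbpt_result <- function(object, ...) {
  null_df <- tibble::tibble(max_t_sum = object$null_max)
  p <- ggplot2::ggplot(null_df, ggplot2::aes(x = .data$max_t_sum)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::labs(
      x = "Permutation max |t_sum|", y = "Count",
      title = "Cluster-based permutation null",
      subtitle = sprintf("%d permutations, cluster-forming alpha = %g",
                         object$n_perm, object$alpha_form)
    ) +
    ggplot2::theme_minimal()
  if (nrow(object$clusters)) {
    obs <- dplyr::mutate(object$clusters, abs_t_sum = abs(.data$t_sum))
    p <- p + ggplot2::geom_vline(
      data = obs,
      ggplot2::aes(xintercept = .data$abs_t_sum, linetype = !.data$significant),
      colour = "firebrick", show.legend = FALSE
    )
  }
  p
}
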