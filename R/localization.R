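#' Select the top percentage of condition-difference voxels
#'
#' Ranks non-cerebellar voxels by the BI - NBI power difference in the
#' requested direction (`"negative"` for down-modulations picks the most
#' negative differences, `"positive"` the most positive) and keeps
#' `ceiling(pct / 100 * n_remaining)` of them. Ties at the cutoff are broken
#' by ascending voxel id, making the selection deterministic.
#'
#' @param diff A tibble with `voxel_id` and `difference` (per-voxel BI - NBI
#'   average power), or a numeric vector aligned to the grid.
#' @param grid Grid tibble ([make_grid()]) supplying coordinates.
#' @param atlas Atlas tibble with `voxel_id` and `is_cerebellum`
#'   ([make_toy_atlas()]).
#' @param pct Percentage of eligible voxels to keep, in (0, 100].
#' @param direction `"negative"` or `"positive"`.
#' @return A tibble of the selected voxels: `voxel_id`, `x`, `y`, `z`,
#'   `difference`, ordered by strength of the difference.
#' @export
select_top_voxels <- function(diff, grid, atlas, pct = 1,
                              direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  check_number(pct, "pct", lower = 1e-12, upper = 100)
  if (is.numeric(diff) && is.null(dim(diff))) {
    if (length(diff) != nrow(grid)) abort("`diff` must align with the grid.")
    diff <- tibble::tibble(voxel_id = grid$voxel_id, difference = as.numeric(diff))
  }
  stopifnot(all(c("voxel_id", "difference") %in% names(diff)))
  if (any(!is.finite(diff$difference))) abort("Differences must be finite.")

  tab <- dplyr::inner_join(diff, grid, by = "voxel_id")
  tab <- dplyr::inner_join(tab, atlas[, c("voxel_id", "is_cerebellum")], by = "voxel_id")
  tab <- dplyr::filter(tab, !.data$is_cerebellum)
  if (nrow(tab) == 0L) abort("No voxels remain after cerebellum exclusion.")

  key <- if (direction == "negative") tab$difference else -tab$difference
  ord <- order(key, tab$voxel_id) # ties at the cutoff resolved by voxel id
  k <- ceiling(pct / 100 * nrow(tab))
  sel <- tab[ord[seq_len(k)], ]
  dplyr::select(sel, "voxel_id", "x", "y", "z", "difference")
}

#' Density-based spatial clustering (DBSCAN)
#'
#' From-scratch DBSCAN over 3-D points: a point is a core point iff its
#' closed eps-ball (the point itself included) contains at least `min_pts`
#' points; clusters are grown to completion from unvisited core points in
#' ascending point-id order, each claiming every density-reachable point;
#' points reachable from no core are noise. Border points (non-core points
#' within `eps` of a core) are claimed by the first cluster whose expansion
#' reaches them — the expansion-order semantics of the original algorithm,
#' fully deterministic given the point order.
#'
#' @param points A matrix or tibble of coordinates (columns `x`, `y`, `z` or a
#'   numeric matrix); rows must be distinct.
#' @param eps Neighbourhood radius (same units as the coordinates; 0.75 cm
#'   pairs with a 0.5 cm lattice as 1.5 x grid size, connecting face and edge
#'   neighbours but not cube-diagonal ones).
#' @param min_pts Minimum neighbourhood size (self included) for a core point.
#' @return A tibble: `point_id` (row number), `cluster` (1, 2, ... in order of
#'   creation; 0 = noise), `is_core`.
#' @export
#' @examples
#' pts <- rbind(matrix(rnorm(30, 0), 10), matrix(rnorm(30, 10), 10))
#' dbscan_cluster(pts, eps = 2, min_pts = 5)
dbscan_cluster <- function(points, eps = 0.75, min_pts = 5L) {
  check_number(eps, "eps", lower = 1e-12)
  check_number(min_pts, "min_pts", lower = 1, integerish = TRUE)
  if (is.data.frame(points)) {
    cols <- intersect(c("x", "y", "z"), names(points))
    if (length(cols) < 2L) abort("`points` needs coordinate columns x, y(, z).")
    points <- as.matrix(points[, cols])
  }
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) {
    return(tibble::tibble(point_id = integer(), cluster = integer(), is_core = logical()))
  }
  if (anyDuplicated(points)) abort("Points must be distinct.")

  eps2 <- eps^2 + 1e-12
  nb <- lapply(seq_len(n), function(i) {
    d2 <- colSums((t(points) - points[i, ])^2)
    which(d2 <= eps2) # includes i itself
  })
  is_core <- lengths(nb) >= min_pts

  cluster <- integer(n) # 0 = unassigned / noise
  next_id <- 0L
  for (i in seq_len(n)) {
    if (cluster[i] != 0L || !is_core[i]) next
    next_id <- next_id + 1L
    cluster[i] <- next_id
    queue <- setdiff(nb[[i]], i)
    while (length(queue)) {
      j <- queue[1L]
      queue <- queue[-1L]
      if (cluster[j] == 0L) {
        cluster[j] <- next_id
        if (is_core[j]) queue <- c(queue, nb[[j]][cluster[nb[[j]]] == 0L])
      }
    }
  }
  tibble::tibble(point_id = seq_len(n), cluster = cluster, is_core = is_core)
}

#' Label clusters with atlas regions
#'
#' Maps each cluster's voxels to region labels and tabulates member counts per
#' region, sorted descending. Voxels without an atlas entry are reported as
#' `"unlabeled"`, never dropped. Noise points (cluster 0) are summarised
#' separately.
#'
#' @param clusters A tibble with `voxel_id` and `cluster` (e.g. the
#'   [dbscan_cluster()] output joined back to voxel ids).
#' @param atlas Atlas tibble with `voxel_id`, `region_label`.
#' @return A tibble of class `labeled_clusters`: `cluster`, `region_label`,
#'   `n_voxels`, sorted by cluster then count descending.
#' @export
label_clusters <- function(clusters, atlas) {
  stopifnot(all(c("voxel_id", "cluster") %in% names(clusters)))
  if (is.null(atlas) || !all(c("voxel_id", "region_label") %in% names(atlas))) {
    abort("`atlas` must provide voxel_id and region_label.")
  }
  tab <- dplyr::left_join(
    clusters, atlas[, c("voxel_id", "region_label")], by = "voxel_id"
  )
  tab$region_label[is.na(tab$region_label)] <- "unlabeled"
  out <- dplyr::count(tab, .data$cluster, .data$region_label, name = "n_voxels")
  out <- dplyr::arrange(out, .data$cluster, dplyr::desc(.data$n_voxels), .data$region_label)
  class(out) <- c("labeled_clusters", class(out))
  out
}

#' Localize the strongest condition differences on the source grid
#'
#' Convenience pipeline: select the top `pct` percent of non-cerebellar
#' BI - NBI differences in the requested direction, cluster them spatially
#' with DBSCAN and label the clusters with atlas regions.
#'
#' @inheritParams select_top_voxels
#' @inheritParams dbscan_cluster
#' @return A list of class `localization`: `voxels` (selected voxels with
#'   their cluster assignment), `labels` (the [label_clusters()] table) and
#'   the parameters used.
#' @export
localize_modulation <- function(diff, grid, atlas, pct = 1,
                                direction = c("negative", "positive"),
                                eps = 0.75, min_pts = 5L) {
  direction <- match.arg(direction)
  sel <- select_top_voxels(diff, grid, atlas, pct = pct, direction = direction)
  cl <- dbscan_cluster(sel[, c("x", "y", "z")], eps = eps, min_pts = min_pts)
  sel$cluster <- cl$cluster
  sel$is_core <- cl$is_core
  labels <- label_clusters(sel[sel$cluster > 0L, c("voxel_id", "cluster")], atlas)
  structure(
    list(
      voxels = sel, labels = labels,
      pct = pct, direction = direction, eps = eps, min_pts = min_pts
    ),
    class = "localization"
  )
}

#' @export
print.localization <- function(x, ...) {
  n_cl <- length(setdiff(unique(x$voxels$cluster), 0L))
  cat(sprintf(
    "<localization> top %g%% voxels (%s direction): %d cluster(s), %d noise point(s)\n",
    x$pct, x$direction, n_cl, sum(x$voxels$cluster == 0L)
  ))
  print(x$labels, ...)
  invisible(x)
}

#' Plot a localization result as lattice slices
#'
#' Axial (z) slices of the selected voxels, coloured by DBSCAN cluster; noise
#' points in grey.
#'
#' @param object A `localization` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.localization <- function(object, ...) {
  df <- dplyr::mutate(
    object$voxels,
    cluster = factor(ifelse(.data$cluster == 0L, "noise", paste0("cluster ", .data$cluster)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$cluster)) +
    ggplot2::geom_tile(width = 0.45, height = 0.45) +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_brewer(palette = "Set2", na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (cm)", y = "y (cm)",
      title = sprintf("DBSCAN clusters of the top %g%% condition differences", object$pct)
    ) +
    ggplot2::theme_minimal()
}
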