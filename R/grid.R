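#' Regular source grids and toy atlases
#'
#' `make_grid()` builds a regular 3-D lattice of voxels, the abstract stand-in
#' for the 0.5-cm source grid used in source reconstruction. `make_toy_atlas()`
#' assigns each voxel a coarse anatomical label by cutting the lattice into
#' octant-style blocks and marks the inferior-posterior block as cerebellum so
#' the cerebellum-exclusion step can be exercised.
#'
#' @param grid_shape Integer vector of length 3 (voxels per axis).
#' @param spacing Lattice spacing in cm.
#'
#' @return `make_grid()`: a tibble with columns `voxel_id`, `x`, `y`, `z`
#'   (cm). Voxel ids are 1-based and run fastest along x.
#' @export
#' @examples
#' g <- make_grid(c(4, 4, 4), spacing = 0.5)
#' atlas <- make_toy_atlas(g)
#' dplyr::count(atlas, region_label)
make_grid <- function(grid_shape = c(10L, 10L, 10L), spacing = 0.5) {
  if (length(grid_shape) != 3L || any(grid_shape < 1)) {
    abort("`grid_shape` must be three positive integers.")
  }
  check_number(spacing, "spacing", lower = 1e-12)
  ix <- expand.grid(
    x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]), z = seq_len(grid_shape[3])
  )
  tibble::tibble(
    voxel_id = seq_len(nrow(ix)),
    x = (ix$x - 1) * spacing,
    y = (ix$y - 1) * spacing,
    z = (ix$z - 1) * spacing
  )
}

#' @rdname make_grid
#' @param grid A grid tibble from [make_grid()].
#' @param n_regions Approximate number of non-cerebellar regions.
#' @return `make_toy_atlas()`: a tibble with columns `voxel_id`,
#'   `region_label`, `is_cerebellum`.
#' @export
make_toy_atlas <- function(grid, n_regions = 7L) {
  stopifnot(all(c("voxel_id", "x", "y", "z") %in% names(grid)))
  check_number(n_regions, "n_regions", lower = 1, integerish = TRUE)
  # cerebellum: inferior (low z), posterior (low y) corner of the lattice
  z_cut <- quantile(grid$z, 0.25)
  y_cut <- quantile(grid$y, 0.35)
  cereb <- grid$z <= z_cut & grid$y <= y_cut
  # remaining voxels: block labels along x/y/z terciles
  cutter <- function(v, k) as.integer(cut(v, breaks = k, include.lowest = TRUE))
  k <- max(1L, ceiling(n_regions^(1 / 3)))
  block <- paste0(
    "region_",
    cutter(grid$x, k), cutter(grid$y, k), cutter(grid$z, k)
  )
  block <- as.integer(factor(block))
  block <- ((block - 1L) %% n_regions) + 1L
  tibble::tibble(
    voxel_id = grid$voxel_id,
    region_label = ifelse(cereb, "cerebellum", sprintf("region_%02d", block)),
    is_cerebellum = cereb
  )
}

#' Read and write grid / atlas tables as TSV
#'
#' Plain-text interchange for grid definitions and label maps. A combined
#' table carries `voxel_id, x_cm, y_cm, z_cm, region_label, is_cerebellum`.
#'
#' @param grid Grid tibble ([make_grid()]).
#' @param atlas Atlas tibble ([make_toy_atlas()]).
#' @param path File path.
#' @return `read_grid_tsv()` returns a list with elements `grid` and `atlas`.
#' @export
write_grid_tsv <- function(grid, atlas, path) {
  tab <- dplyr::inner_join(grid, atlas, by = "voxel_id")
  tab <- dplyr::rename(tab, x_cm = "x", y_cm = "y", z_cm = "z")
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_grid_tsv
#' @export
read_grid_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  list(
    grid = tibble::tibble(
      voxel_id = tab$voxel_id, x = tab$x_cm, y = tab$y_cm, z = tab$z_cm
    ),
    atlas = tibble::tibble(
      voxel_id = tab$voxel_id,
      region_label = tab$region_label,
      is_cerebellum = as.logical(tab$is_cerebellum)
    )
  )
}
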