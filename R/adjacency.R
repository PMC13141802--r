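#' Build a voxel adjacency graph on a regular grid
#'
#' Default rule is orthogonal 6-connectivity at the lattice spacing; the
#' radius rule instead connects voxels whose Euclidean distance is at most
#' `radius`. The graph is symmetric with no self-edges.
#'
#' @param grid Grid tibble with `voxel_id`, `x`, `y`, `z` ([make_grid()]).
#' @param rule `"lattice"` (6-connectivity) or `"radius"`.
#' @param spacing Lattice spacing in cm; inferred from the grid when `NULL`.
#' @param radius Neighbourhood radius in cm (radius rule only).
#' @return An object of class `voxel_adjacency`: `neighbors` (list of integer
#'   neighbour ids per voxel) plus a 0-based CSR form (`ptr`, `idx`) used by
#'   the compiled clustering routines.
#' @export
build_adjacency <- function(grid, rule = c("lattice", "radius"),
                            spacing = NULL, radius = NULL) {
  rule <- match.arg(rule)
  stopifnot(all(c("voxel_id", "x", "y", "z") %in% names(grid)))
  n <- nrow(grid)
  coords <- as.matrix(grid[, c("x", "y", "z")])
  if (anyDuplicated(coords)) abort("Duplicate voxel coordinates.")
  if (is.null(spacing)) {
    ux <- sort(unique(coords[, 1]))
    spacing <- if (length(ux) > 1) min(diff(ux)) else 0.5
  }

  if (rule == "lattice") {
    ii <- round(sweep(coords, 2, apply(coords, 2, min)) / spacing)
    key <- function(m) m[, 1] + (m[, 2] + m[, 3] * (max(ii[, 2]) + 2)) * (max(ii[, 1]) + 2)
    lookup <- setNames(seq_len(n), key(ii))
    offs <- rbind(
      c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)
    )
    neighbors <- vector("list", n)
    for (o in seq_len(nrow(offs))) {
      shifted <- sweep(ii, 2, -offs[o, ])
      hit <- lookup[as.character(key(shifted))]
      ok <- !is.na(hit)
      for (v in which(ok)) neighbors[[v]] <- c(neighbors[[v]], hit[[v]])
    }
    neighbors <- lapply(neighbors, function(x) sort(unique(x)))
  } else {
    check_number(radius, "radius", lower = 1e-12)
    neighbors <- vector("list", n)
    d2max <- radius^2 + 1e-12
    for (v in seq_len(n)) {
      d2 <- colSums((t(coords) - coords[v, ])^2)
      nb <- which(d2 <= d2max)
      neighbors[[v]] <- nb[nb != v]
    }
  }

  lens <- lengths(neighbors)
  structure(
    list(
      voxel_id = grid$voxel_id,
      neighbors = neighbors,
      ptr = c(0L, cumsum(lens)),
      idx = as.integer(unlist(neighbors, use.names = FALSE) - 1L),
      rule = rule, spacing = spacing, radius = radius
    ),
    class = "voxel_adjacency"
  )
}

#' @export
print.voxel_adjacency <- function(x, ...) {
  cat(sprintf(
    "<voxel_adjacency> %d voxels, %d edges, rule = %s\n",
    length(x$neighbors), length(x$idx) / 2, x$rule
  ))
  invisible(x)
}
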