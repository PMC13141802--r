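# Independent oracles used across the suite. These deliberately re-derive
# results by brute force rather than reusing package internals.

# Recursive formulation of the minimum-gap scan rule.
prune_oracle <- function(times, gap) {
  if (length(times) == 0L) return(numeric())
  first <- times[1L]
  c(first, prune_oracle(times[times >= first + gap], gap))
}

# Connected components among `members` (voxel indices) via plain BFS over a
# neighbour list; returns a list of sorted integer vectors.
flood_fill_components <- function(members, neighbors) {
  members <- sort(members)
  seen <- logical(length(neighbors))
  comps <- list()
  for (v in members) {
    if (seen[v]) next
    comp <- integer()
    queue <- v
    seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[1L]
      queue <- queue[-1L]
      comp <- c(comp, u)
      nb <- intersect(neighbors[[u]], members)
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, integer(1)))]
}

# Brute-force density-reachability closure for DBSCAN's unique structure:
# core points and their eps-graph components. Border/noise membership is
# checked against it separately (border assignment is the only
# order-dependent part of DBSCAN).
dbscan_closure_oracle <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  d2 <- as.matrix(dist(pts))^2
  eps2 <- eps^2 + 1e-12
  within <- d2 <= eps2
  is_core <- rowSums(within) >= min_pts # diagonal counts the point itself
  core_ids <- which(is_core)
  comp <- rep(NA_integer_, n)
  if (length(core_ids)) {
    nb <- lapply(seq_len(n), function(i) setdiff(which(within[i, ]), i))
    comps <- flood_fill_components(core_ids, lapply(nb, intersect, core_ids))
    for (k in seq_along(comps)) comp[comps[[k]]] <- k
  }
  reach <- function(i) unique(stats::na.omit(comp[which(within[i, ]) ]))
  list(is_core = is_core, core_component = comp, reachable = reach)
}

# Partition equality up to label permutation, with noise matched exactly.
same_partition <- function(a, b, noise_a = 0L, noise_b = 0L) {
  if (length(a) != length(b)) return(FALSE)
  na <- a == noise_a
  nb <- b == noise_b
  if (!identical(na, nb)) return(FALSE)
  a <- a[!na]
  b <- b[!nb]
  if (!length(a)) return(TRUE)
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Random point clouds (a few Gaussian blobs) for clustering checks.
random_point_sets <- function(n_sets, seed) {
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    n <- sample(30:90, 1)
    k <- sample(1:3, 1)
    centers <- matrix(runif(3 * k, 0, 6), k)
    pts <- do.call(rbind, lapply(seq_len(k), function(j) {
      m <- ceiling(n / k)
      matrix(rnorm(3 * m, mean = rep(centers[j, ], each = m), sd = 0.5), ncol = 3)
    }))
    pts <- unique(round(pts, 6))
    list(pts = pts, eps = runif(1, 0.5, 1.2), min_pts = sample(3:6, 1))
  })
}

# Run the scikit-learn DBSCAN on a list of point sets via one python call;
# returns a list of integer label vectors (-1 = noise).
sklearn_dbscan <- function(sets) {
  csv_in <- tempfile(fileext = ".csv")
  csv_out <- tempfile(fileext = ".csv")
  df <- do.call(rbind, lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    data.frame(
      set = i, x = s$pts[, 1], y = s$pts[, 2], z = s$pts[, 3],
      eps = s$eps, min_pts = s$min_pts
    )
  }))
  utils::write.csv(df, csv_in, row.names = FALSE)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, pandas as pd",
    "from sklearn.cluster import DBSCAN",
    "df = pd.read_csv(sys.argv[1])",
    "rows = []",
    "for s, g in df.groupby('set'):",
    "    lab = DBSCAN(eps=g.eps.iloc[0], min_samples=int(g.min_pts.iloc[0])).fit(",
    "        g[['x', 'y', 'z']].values).labels_",
    "    for i, l in enumerate(lab):",
    "        rows.append((s, i + 1, int(l)))",
    "pd.DataFrame(rows, columns=['set', 'point_id', 'label']).to_csv(sys.argv[2], index=False)"
  ), py)
  status <- system2("python", c(py, csv_in, csv_out))
  stopifnot(status == 0)
  ref <- utils::read.csv(csv_out)
  lapply(seq_along(sets), function(i) ref$label[ref$set == i])
}

# Small paired power fixture on a compact grid.
tiny_power_data <- function(n = 8, grid_shape = c(4, 4, 2), delta = 0,
                            planted = integer(), seed = 1) {
  grid <- make_grid(grid_shape)
  set.seed(seed)
  v <- nrow(grid)
  shift <- numeric(v)
  shift[planted] <- delta
  bi <- matrix(rnorm(n * v), n, v) + matrix(shift, n, v, byrow = TRUE)
  nbi <- matrix(rnorm(n * v), n, v)
  list(grid = grid, adj = build_adjacency(grid), bi = bi, nbi = nbi)
}
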