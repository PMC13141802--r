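#' Simulate a situational-change coding table
#'
#' Generates the per-bin coding of a movie: for each 2-s bin, nine binary
#' indicators mark whether a situational change of each type (character,
#' character-character, character-object, temporal, large/small spatial,
#' cause, goal, scene) occurs. Flags are independent Bernoulli draws with the
#' per-type probabilities in `config`; `n_changes` is their row sum. Real
#' codings have temporal structure that this generator deliberately omits —
#' independence is sufficient for exercising the downstream regression.
#'
#' @param config A [sim_config()].
#' @return A tibble with `bin` (0-based), one 0/1 column per change type and
#'   `n_changes`, of class `change_table`.
#' @export
#' @examples
#' tab <- simulate_change_table(sim_config(seed = 7, n_bins = 20))
#' head(tab)
simulate_change_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 4L)
  set.seed(seeds[1L])
  flags <- vapply(
    config$change_probs,
    function(p) rbinom(config$n_bins, 1L, p),
    integer(config$n_bins)
  )
  flags <- matrix(flags, nrow = config$n_bins,
                  dimnames = list(NULL, names(config$change_probs)))
  out <- tibble::as_tibble(flags)
  out <- dplyr::mutate(out,
    bin = seq_len(config$n_bins) - 1L,
    n_changes = as.integer(rowSums(flags)),
    .before = 1L
  )
  class(out) <- c("change_table", class(out))
  out
}

#' Simulate button-press response streams
#'
#' Generates two groups of subjects responding to the situational changes in
#' `table` under the mixed logistic model of [sim_config()]: subject `s` in
#' group `g` responds in bin `b` with probability
#' `plogis(beta0 + u_s + (beta_count + g * beta_group_interaction) * n_changes_b)`,
#' `u_s ~ N(0, random_intercept_sd)`. A response is placed at a uniformly
#' random offset inside its bin (within-bin timing is not modelled).
#'
#' @param table A `change_table` from [simulate_change_table()].
#' @param config The same [sim_config()] used to build `table`.
#' @return A tibble with one row per subject x bin: `subject_id`, `group`
#'   (0 = NT, 1 = ASD), `bin`, `n_changes`, `response` (0/1) and `time`
#'   (seconds of the button press, `NA` when `response == 0`), of class
#'   `response_table`.
#' @seealso [response_streams()] to extract per-subject time vectors.
#' @export
simulate_responses <- function(table, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(table) != config$n_bins) {
    abort("`table` and `config` disagree on the number of bins.")
  }
  seeds <- derive_seeds(config$seed, 4L)
  set.seed(seeds[2L])

  n_sub <- 2L * config$n_subjects_per_group
  group <- rep(c(0L, 1L), each = config$n_subjects_per_group)
  u <- rnorm(n_sub, 0, config$random_intercept_sd)

  slope <- config$beta_count + group * config$beta_group_interaction
  # eta: n_bins x n_sub
  eta <- outer(table$n_changes, slope) +
    matrix(config$beta0 + u, nrow = config$n_bins, ncol = n_sub, byrow = TRUE)
  resp <- matrix(
    rbinom(length(eta), 1L, plogis(as.vector(eta))),
    nrow = config$n_bins
  )
  offset <- matrix(runif(length(eta), 0, config$bin_width), nrow = config$n_bins)

  out <- tibble::tibble(
    subject_id = rep(sprintf("S%03d", seq_len(n_sub)), each = config$n_bins),
    group = rep(group, each = config$n_bins),
    bin = rep(table$bin, n_sub),
    n_changes = rep(table$n_changes, n_sub),
    response = as.integer(as.vector(resp)),
    time = ifelse(as.vector(resp) == 1L,
      rep(table$bin, n_sub) * config$bin_width + as.vector(offset),
      NA_real_
    )
  )
  attr(out, "bin_width") <- config$bin_width
  attr(out, "duration") <- config$duration
  class(out) <- c("response_table", class(out))
  out
}

#' Extract per-subject response-time streams
#'
#' @param responses A `response_table` from [simulate_responses()] (or any
#'   tibble with `subject_id`, `group`, `response`, `time`).
#' @return A tibble `subject_id`, `group`, `time` with one row per button
#'   press, times strictly increasing within subject.
#' @export
response_streams <- function(responses) {
  out <- dplyr::filter(responses, .data$response == 1L)
  out <- dplyr::arrange(out, .data$subject_id, .data$time)
  dplyr::select(out, "subject_id", "group", "time")
}

#' Simulate paired-condition voxel power datasets for two groups
#'
#' Builds the fixture for the source-space statistics: per subject and
#' condition (BI = boundary interval, NBI = no-boundary interval), log power
#' on a regular voxel grid is `baseline + effect_delta * planted * is_BI +`
#' i.i.d. Gaussian noise. Group 2 receives a planted region whose extent and
#' shift are scaled by `spec$group_scale`.
#'
#' @param spec A [source_sim_spec()].
#' @param n_per_group Subjects per group.
#' @param seed Integer seed.
#' @return A list of class `power_sim` with elements `groups` (each a list
#'   with `bi` and `nbi` subject x voxel matrices and `planted` voxel ids),
#'   `grid` and `spec`.
#' @export
simulate_power_dataset <- function(spec, n_per_group = 15L, seed = 1L) {
  stopifnot(inherits(spec, "source_sim_spec"))
  check_number(n_per_group, "n_per_group", lower = 1, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  n_vox <- nrow(spec$grid)
  if (n_vox == 0L) abort("Empty grid.")

  planted1 <- spec$planted_voxels
  n2 <- ceiling(length(planted1) * spec$group_scale)
  planted2 <- planted1[seq_len(min(n2, length(planted1)))]
  delta <- c(spec$effect_delta, spec$effect_delta * spec$group_scale)
  planted <- list(planted1, planted2)

  set.seed(seed)
  groups <- lapply(1:2, function(g) {
    shift <- numeric(n_vox)
    shift[planted[[g]]] <- delta[g]
    noise <- function() {
      matrix(rnorm(n_per_group * n_vox, 0, spec$noise_sd), n_per_group, n_vox)
    }
    bi <- spec$baseline + matrix(shift, n_per_group, n_vox, byrow = TRUE) + noise()
    nbi <- spec$baseline + noise()
    list(bi = bi, nbi = nbi, planted = planted[[g]])
  })
  names(groups) <- c("group1", "group2")
  structure(
    list(groups = groups, grid = spec$grid, spec = spec, seed = as.integer(seed)),
    class = "power_sim"
  )
}

#' Simulate a random free-orientation leadfield
#'
#' Draws, for each voxel, three orthonormal sensor gain columns scaled to a
#' common norm — an abstract stand-in for a volume-conductor forward model.
#' Orthonormal columns keep voxels comparably "visible" to the beamformer so
#' localization behaviour can be tested without forward-model physics.
#'
#' @param n_sensors Number of sensors.
#' @param n_voxels Number of voxels.
#' @param seed Integer seed.
#' @return An `n_sensors x 3 x n_voxels` array.
#' @export
simulate_leadfield <- function(n_sensors = 40L, n_voxels = 64L, seed = 1L) {
  check_number(n_sensors, "n_sensors", lower = 4, integerish = TRUE)
  check_number(n_voxels, "n_voxels", lower = 1, integerish = TRUE)
  set.seed(seed)
  lf <- array(0, dim = c(n_sensors, 3L, n_voxels))
  for (v in seq_len(n_voxels)) {
    lf[, , v] <- qr.Q(qr(matrix(rnorm(n_sensors * 3L), n_sensors, 3L)))
  }
  lf
}

#' Simulate band-limited oscillatory sensor segments
#'
#' Generates `n_segments` segments of sensor data from a single oscillatory
#' source: a sinusoid at a frequency drawn once from `source_band` (snapped to
#' the segment's Fourier resolution), with a fixed random dipole orientation
#' and an independent uniform random phase per segment, projected through the
#' active voxel's leadfield, plus white sensor noise. Random per-segment
#' phases make the band cross-spectral density nonzero with rank <= 3.
#'
#' @param spec A [sensor_sim_spec()].
#' @param seed Integer seed.
#' @return An array `n_segments x n_sensors x n_samples` of class
#'   `sensor_segments`, with the sampling rate, source frequency, orientation
#'   and generating voxel attached as attributes.
#' @export
simulate_sensor_segments <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sensor_sim_spec"))
  check_number(seed, "seed", integerish = TRUE)
  set.seed(seed)

  n_samp <- round(spec$segment_secs * spec$sampling_rate)
  n_sens <- dim(spec$leadfield)[1]
  t_sec <- (seq_len(n_samp) - 1) / spec$sampling_rate
  df <- 1 / spec$segment_secs

  # snap the source frequency to the FFT grid so band selection is exact
  f0 <- runif(1, spec$source_band[1], spec$source_band[2])
  f0 <- round(f0 / df) * df
  f0 <- min(max(f0, spec$source_band[1]), spec$source_band[2])

  orient <- rnorm(3)
  orient <- orient / sqrt(sum(orient^2))
  gain <- spec$leadfield[, , spec$active_voxel] %*% orient # n_sens x 1

  segs <- array(0, dim = c(spec$n_segments, n_sens, n_samp))
  for (k in seq_len(spec$n_segments)) {
    phase <- runif(1, 0, 2 * pi)
    s <- spec$amplitude * sin(2 * pi * f0 * t_sec + phase)
    segs[k, , ] <- gain %*% matrix(s, nrow = 1) +
      matrix(rnorm(n_sens * n_samp, 0, spec$noise_sd), n_sens, n_samp)
  }
  structure(
    segs,
    class = c("sensor_segments", "array"),
    sampling_rate = spec$sampling_rate,
    source_freq = f0,
    orientation = orient,
    active_voxel = spec$active_voxel
  )
}

#' Write / read a change table as TSV
#'
#' Columns: `bin` (0-based), the nine change-type flags, `n_changes`.
#'
#' @param table A `change_table`.
#' @param path File path.
#' @export
write_change_table_tsv <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_change_table_tsv
#' @export
read_change_table_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  flags <- intersect(change_type_names(), names(out))
  if (length(flags) != 9L || !"bin" %in% names(out)) {
    abort("Not a change table: expected `bin` plus the nine change-type columns.")
  }
  if (!"n_changes" %in% names(out)) {
    out$n_changes <- as.integer(rowSums(out[, flags]))
  }
  if (!all(out$n_changes == rowSums(out[, flags]))) {
    abort("`n_changes` does not equal the sum of the change flags.")
  }
  class(out) <- c("change_table", class(out))
  out
}
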