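#' Simulation configuration for the behavioural generator
#'
#' Bundles the design constants of a movie event-segmentation study (bin
#' width, movie duration, clip boundaries) with the parameters of the
#' generative segmentation model: per-bin situational changes occur as
#' independent Bernoulli draws per change type, and a subject presses the
#' response button in a bin with probability
#' `plogis(beta0 + u_s + beta_count * n_changes + group * beta_group_interaction * n_changes)`
#' where `u_s ~ Normal(0, random_intercept_sd)` is a subject-level random
#' intercept and `group` codes the clinical group (0 = NT, 1 = ASD).
#'
#' Defaults reproduce the study conditions: 30 subjects per group, a 30-min
#' movie in three 10-min clips cut into 900 bins of 2 s, a log-odds intercept
#' of -3.26, a count slope of 0.30 and a group-by-count interaction of -0.09
#' (the fitted behavioural coefficients), and a subject intercept SD of 0.5.
#' Per-type change probabilities are chosen so that per-bin change counts
#' rarely exceed 5; they are a modelling default, not a claim about any
#' particular stimulus.
#'
#' @param seed Integer seed controlling every random draw downstream.
#' @param n_subjects_per_group Subjects per group (two groups are generated).
#' @param n_bins Number of consecutive analysis bins covering the movie.
#' @param bin_width Bin width in seconds.
#' @param clip_boundaries Increasing vector of clip edges in seconds, from 0
#'   to the movie duration (`n_bins * bin_width`).
#' @param change_probs Probability that each of the nine situational change
#'   types occurs in a bin. Named or unnamed length-9 numeric in `[0, 1]`.
#' @param beta0 Log-odds intercept of the response model.
#' @param beta_count Log-odds increase per situational change (group 0 slope).
#' @param beta_group_interaction Additional log-odds per change for group 1.
#' @param random_intercept_sd SD of the subject-level random intercept
#'   (log-odds scale, must be >= 0).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_subjects_per_group = 4, n_bins = 60)
#' cfg$change_probs
sim_config <- function(seed = 1L,
                       n_subjects_per_group = 30L,
                       n_bins = 900L,
                       bin_width = 2,
                       clip_boundaries = NULL,
                       change_probs = c(
                         character = 0.10, character_character = 0.08,
                         character_object = 0.08, temporal = 0.05,
                         space_large = 0.12, space_small = 0.15,
                         cause = 0.05, goal = 0.06, scene = 0.18
                       ),
                       beta0 = -3.26,
                       beta_count = 0.30,
                       beta_group_interaction = -0.09,
                       random_intercept_sd = 0.5) {
  check_number(seed, "seed", integerish = TRUE)
  check_number(n_subjects_per_group, "n_subjects_per_group", lower = 1, integerish = TRUE)
  check_number(n_bins, "n_bins", lower = 1, integerish = TRUE)
  check_number(bin_width, "bin_width", lower = 1e-12)
  if (length(change_probs) != 9L || !is.numeric(change_probs)) {
    abort("`change_probs` must be a numeric vector of length 9.")
  }
  if (any(!is.finite(change_probs)) || any(change_probs < 0) || any(change_probs > 1)) {
    abort("`change_probs` must lie in [0, 1].")
  }
  if (is.null(names(change_probs))) {
    names(change_probs) <- change_type_names()
  }
  check_number(beta0, "beta0")
  check_number(beta_count, "beta_count")
  check_number(beta_group_interaction, "beta_group_interaction")
  check_number(random_intercept_sd, "random_intercept_sd", lower = 0)

  duration <- n_bins * bin_width
  if (is.null(clip_boundaries)) {
    clip_boundaries <- seq(0, duration, length.out = 4L)
  }
  if (length(clip_boundaries) < 2L || is.unsorted(clip_boundaries, strictly = TRUE) ||
      abs(clip_boundaries[1L]) > 1e-9 ||
      abs(clip_boundaries[length(clip_boundaries)] - duration) > 1e-9) {
    abort("`clip_boundaries` must increase strictly from 0 to n_bins * bin_width.")
  }

  structure(
    list(
      seed = as.integer(seed),
      n_subjects_per_group = as.integer(n_subjects_per_group),
      n_bins = as.integer(n_bins),
      bin_width = bin_width,
      duration = duration,
      clip_boundaries = as.numeric(clip_boundaries),
      change_probs = change_probs,
      beta0 = beta0,
      beta_count = beta_count,
      beta_group_interaction = beta_group_interaction,
      random_intercept_sd = random_intercept_sd
    ),
    class = "sim_config"
  )
}

change_type_names <- function() {
  c(
    "character", "character_character", "character_object", "temporal",
    "space_large", "space_small", "cause", "goal", "scene"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d subjects/group, %d bins x %g s (%g s movie), %d clips\n",
    x$n_subjects_per_group, x$n_bins, x$bin_width, x$duration,
    length(x$clip_boundaries) - 1L
  ))
  cat(sprintf(
    "  logit model: %.2f + u + %.2f * n_changes %+.2f * group * n_changes, sd(u) = %.2f\n",
    x$beta0, x$beta_count, x$beta_group_interaction, x$random_intercept_sd
  ))
  invisible(x)
}

#' Specification of a planted source-power effect on a voxel grid
#'
#' Describes the voxel-grid fixture used to exercise the source-space
#' statistics: a regular lattice, a connected set of "planted" voxels whose
#' log power is shifted by `effect_delta` in the boundary (BI) condition, and
#' i.i.d. Gaussian log-power noise. Group 2's planted extent and shift are
#' both scaled by `group_scale`, emulating a group with a weaker, more focal
#' modulation.
#'
#' @param grid_shape Integer vector of length 3: lattice dimensions.
#' @param grid_spacing Lattice spacing in cm.
#' @param planted_voxels Integer voxel ids forming the planted region. By
#'   default a compact, connected region of `n_planted` voxels grown from the
#'   grid centre.
#' @param n_planted Size of the default planted region.
#' @param effect_delta Log-power shift added to planted voxels in the BI
#'   condition, in units of `noise_sd`.
#' @param group_scale Multiplier applied to group 2's planted extent and
#'   shift (0.5 halves both).
#' @param noise_sd SD of the log-power noise.
#' @param baseline Baseline log power.
#'
#' @return An object of class `source_sim_spec`.
#' @export
source_sim_spec <- function(grid_shape = c(10L, 10L, 10L),
                            grid_spacing = 0.5,
                            planted_voxels = NULL,
                            n_planted = 20L,
                            effect_delta = 1,
                            group_scale = 1,
                            noise_sd = 1,
                            baseline = 0) {
  if (length(grid_shape) != 3L || any(grid_shape < 1)) {
    abort("`grid_shape` must be three positive integers.")
  }
  check_number(grid_spacing, "grid_spacing", lower = 1e-12)
  check_number(n_planted, "n_planted", lower = 0, integerish = TRUE)
  check_number(effect_delta, "effect_delta")
  check_number(group_scale, "group_scale", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(baseline, "baseline")

  grid <- make_grid(grid_shape, grid_spacing)
  if (is.null(planted_voxels)) {
    planted_voxels <- grow_planted_region(grid, n_planted)
  }
  planted_voxels <- as.integer(planted_voxels)
  if (length(planted_voxels) && (min(planted_voxels) < 1 || max(planted_voxels) > nrow(grid))) {
    abort("`planted_voxels` must be voxel ids inside the grid.")
  }

  structure(
    list(
      grid = grid, grid_shape = as.integer(grid_shape),
      grid_spacing = grid_spacing, planted_voxels = planted_voxels,
      effect_delta = effect_delta, group_scale = group_scale,
      noise_sd = noise_sd, baseline = baseline
    ),
    class = "source_sim_spec"
  )
}

# Compact connected region: order voxels by distance to the grid centre and
# keep the n closest (ties by voxel id). On a regular lattice this ball is
# connected under 6-connectivity.
grow_planted_region <- function(grid, n) {
  if (n == 0L) return(integer())
  centre <- vapply(grid[, c("x", "y", "z")], function(v) mean(range(v)), numeric(1))
  d2 <- (grid$x - centre[1])^2 + (grid$y - centre[2])^2 + (grid$z - centre[3])^2
  ord <- order(d2, grid$voxel_id)
  sort(grid$voxel_id[ord[seq_len(min(n, nrow(grid)))]])
}

#' Specification of band-limited oscillatory sensor segments
#'
#' Describes a single oscillatory source for the sensor-level fixture: the
#' source oscillates at a frequency inside `band` with a fixed (random)
#' dipole orientation and an independent random phase per 2-s segment, is
#' projected to the sensors through the voxel's leadfield columns, and white
#' sensor noise is added.
#'
#' @param leadfield Numeric array `n_sensors x 3 x n_voxels` (free-orientation
#'   gains), e.g. from [simulate_leadfield()].
#' @param active_voxel Index of the generating voxel.
#' @param source_band Length-2 Hz interval the source frequency is drawn from.
#' @param amplitude Source amplitude (arbitrary units).
#' @param noise_sd SD of white sensor noise.
#' @param n_segments Number of 2-s segments to generate.
#' @param sampling_rate Sampling rate in Hz.
#' @param segment_secs Segment duration in seconds.
#'
#' @return An object of class `sensor_sim_spec`.
#' @export
sensor_sim_spec <- function(leadfield,
                            active_voxel = 1L,
                            source_band = c(8, 12),
                            amplitude = 1,
                            noise_sd = 0.1,
                            n_segments = 60L,
                            sampling_rate = 300,
                            segment_secs = 2) {
  if (!is.array(leadfield) || length(dim(leadfield)) != 3L || dim(leadfield)[2] != 3L) {
    abort("`leadfield` must be an n_sensors x 3 x n_voxels array.")
  }
  if (any(!is.finite(leadfield))) abort("`leadfield` must be finite.")
  check_number(active_voxel, "active_voxel", lower = 1, upper = dim(leadfield)[3], integerish = TRUE)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(n_segments, "n_segments", lower = 1, integerish = TRUE)
  check_number(sampling_rate, "sampling_rate", lower = 1e-9)
  check_number(segment_secs, "segment_secs", lower = 1e-9)
  if (length(source_band) != 2L || source_band[1] <= 0 || source_band[1] >= source_band[2]) {
    abort("`source_band` must be an increasing positive Hz interval.")
  }
  if (source_band[2] >= sampling_rate / 2) {
    abort("`source_band` must lie below the Nyquist frequency.")
  }

  structure(
    list(
      leadfield = leadfield, active_voxel = as.integer(active_voxel),
      source_band = as.numeric(source_band), amplitude = amplitude,
      noise_sd = noise_sd, n_segments = as.integer(n_segments),
      sampling_rate = sampling_rate, segment_secs = segment_secs
    ),
    class = "sensor_sim_spec"
  )
}
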