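#' Frequency band specification
#'
#' The three bands of interest follow the standard EEG conventions used in
#' the analysis: theta 4-7 Hz, alpha 8-12 Hz, beta 15-30 Hz.
#'
#' @param name One of "theta", "alpha", "beta", or any label when `lo`/`hi`
#'   are given explicitly.
#' @param lo,hi Band edges in Hz (defaults follow `name`).
#' @return A list of class `band_spec` with `name`, `lo`, `hi`.
#' @export
#' @examples
#' band_spec("alpha")
band_spec <- function(name = c("theta", "alpha", "beta"), lo = NULL, hi = NULL) {
  if (is.null(lo) || is.null(hi)) {
    name <- match.arg(name)
    edges <- switch(name, theta = c(4, 7), alpha = c(8, 12), beta = c(15, 30))
    lo <- lo %||% edges[1]
    hi <- hi %||% edges[2]
  }
  check_number(lo, "lo", lower = 0)
  check_number(hi, "hi", lower = 0)
  if (lo >= hi) abort("`lo` must be below `hi`.")
  structure(list(name = as.character(name)[1], lo = lo, hi = hi), class = "band_spec")
}

#' Band-limited cross-spectral density of sensor segments
#'
#' Per segment, each channel is Hann-tapered and Fourier-transformed; the
#' complex coefficients at every FFT bin inside `[lo, hi]` (2-s segments give
#' a 0.5-Hz resolution, matching the 0.5-Hz smoothing box) form rank-1 outer
#' products that are averaged over segments and in-band bins into one
#' Hermitian sensor-by-sensor cross-spectral density matrix.
#'
#' @param segments `n_segments x n_sensors x n_samples` array (e.g. from
#'   [simulate_sensor_segments()]).
#' @param band A [band_spec()].
#' @param sampling_rate Sampling rate in Hz (taken from the segments attribute
#'   when present).
#' @return A list of class `csd_matrix`: `values` (complex Hermitian matrix),
#'   `band`, `n_segments`, `freqs` (the averaged FFT bins, Hz).
#' @export
compute_band_csd <- function(segments, band, sampling_rate = NULL) {
  stopifnot(inherits(band, "band_spec"))
  if (length(dim(segments)) != 3L) {
    abort("`segments` must be an n_segments x n_sensors x n_samples array.")
  }
  sampling_rate <- sampling_rate %||% attr(segments, "sampling_rate")
  if (is.null(sampling_rate)) abort("`sampling_rate` is required.")
  n_seg <- dim(segments)[1]
  n_sens <- dim(segments)[2]
  n_samp <- dim(segments)[3]
  if (band$hi >= sampling_rate / 2) abort("Band must lie below the Nyquist frequency.")

  freqs <- (seq_len(n_samp) - 1) * sampling_rate / n_samp
  sel <- which(freqs >= band$lo - 1e-9 & freqs <= band$hi + 1e-9 & freqs <= sampling_rate / 2)
  if (length(sel) == 0L) abort("No FFT bin falls inside the requested band.")

  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_samp) - 1) / (n_samp - 1)) # Hann taper
  scale <- 1 / (sum(w^2) * sampling_rate)

  csd <- matrix(0 + 0i, n_sens, n_sens)
  for (k in seq_len(n_seg)) {
    seg <- segments[k, , , drop = TRUE]
    if (n_sens == 1L) seg <- matrix(seg, nrow = 1L)
    tapered <- seg * matrix(w, n_sens, n_samp, byrow = TRUE)
    coefs <- t(apply(tapered, 1L, fft)) # n_sens x n_samp complex
    if (n_sens == 1L) coefs <- matrix(coefs, nrow = 1L)
    for (f in sel) {
      x <- coefs[, f]
      csd <- csd + x %*% Conj(t(x))
    }
  }
  csd <- csd * scale / (n_seg * length(sel))
  csd <- (csd + Conj(t(csd))) / 2 # enforce exact Hermitian symmetry
  structure(
    list(values = csd, band = band, n_segments = n_seg, freqs = freqs[sel]),
    class = "csd_matrix"
  )
}

#' Compute DICS-style spatial filters from a common cross-spectral density
#'
#' For each voxel with free-orientation leadfield `L` (sensors x 3), the
#' unit-gain minimum-variance filter is
#' `W = (L' Cr^-1 L)^-1 L' Cr^-1`, where
#' `Cr = Re(C) + lambda * (tr(Re(C)) / n_sensors) * I` is the real part of the
#' common-condition CSD regularized by a fraction `lambda` of its mean sensor
#' power (the conventional 5% default). The common CSD must be computed from
#' the appended segments of both conditions so the identical filter set is
#' applied to each condition. The 3-column leadfield realizes the rank-3
#' free-orientation source model.
#'
#' @param csd_common A `csd_matrix` from the appended BI + NBI segments.
#' @param leadfield `n_sensors x 3 x n_voxels` array.
#' @param lambda Regularization fraction (default 0.05).
#' @return A list of class `spatial_filter_set`: `filters`
#'   (`3 x n_sensors x n_voxels` array), `lambda`, `band`.
#' @export
compute_dics_filters <- function(csd_common, leadfield, lambda = 0.05) {
  stopifnot(inherits(csd_common, "csd_matrix"))
  check_number(lambda, "lambda", lower = 0)
  if (!is.array(leadfield) || length(dim(leadfield)) != 3L || dim(leadfield)[2] != 3L) {
    abort("`leadfield` must be an n_sensors x 3 x n_voxels array.")
  }
  n_sens <- nrow(csd_common$values)
  if (dim(leadfield)[1] != n_sens) {
    abort("Sensor count of leadfield and CSD disagree.")
  }
  C <- Re(csd_common$values)
  Cr <- C + lambda * (sum(diag(C)) / n_sens) * diag(n_sens)
  Cinv <- tryCatch(solve(Cr), error = function(e) {
    abort("Regularized CSD is singular; increase `lambda`.")
  })
  n_vox <- dim(leadfield)[3]
  filters <- array(0, dim = c(3L, n_sens, n_vox))
  for (v in seq_len(n_vox)) {
    L <- leadfield[, , v]
    M <- crossprod(L, Cinv)     # 3 x n_sens
    A <- M %*% L                # 3 x 3
    if (rcond(A) < 1e-14) {
      abort(sprintf("Degenerate leadfield at voxel %d (singular L' C^-1 L).", v))
    }
    filters[, , v] <- solve(A, M)
  }
  structure(
    list(filters = filters, lambda = lambda, band = csd_common$band),
    class = "spatial_filter_set"
  )
}

#' Project condition-specific power onto the source grid
#'
#' Applies a common spatial filter set to a condition's CSD: per voxel the
#' 3x3 source cross-spectrum is `S = W Re(C) W'` and the reported power is
#' its largest eigenvalue (dominant-orientation convention) or its trace.
#'
#' @param filters A `spatial_filter_set` from [compute_dics_filters()].
#' @param csd_condition A `csd_matrix` for one condition.
#' @param summary `"eigenvalue"` (default) or `"trace"`.
#' @param condition Optional condition label stored on the output.
#' @return A tibble of class `power_map`: `voxel_id`, `power` (>= 0), with
#'   `condition` and band attached as attributes.
#' @export
project_source_power <- function(filters, csd_condition,
                                 summary = c("eigenvalue", "trace"),
                                 condition = NA_character_) {
  stopifnot(inherits(filters, "spatial_filter_set"), inherits(csd_condition, "csd_matrix"))
  summary <- match.arg(summary)
  C <- Re(csd_condition$values)
  if (ncol(C) != dim(filters$filters)[2]) abort("Sensor dimension mismatch.")
  n_vox <- dim(filters$filters)[3]
  power <- vapply(seq_len(n_vox), function(v) {
    W <- filters$filters[, , v]
    S <- W %*% C %*% t(W)
    S <- (S + t(S)) / 2
    if (summary == "trace") sum(diag(S)) else max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  power <- pmax(power, 0)
  out <- tibble::tibble(voxel_id = seq_len(n_vox), power = power)
  attr(out, "condition") <- condition
  attr(out, "band") <- filters$band
  attr(out, "summary") <- summary
  class(out) <- c("power_map", class(out))
  out
}
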