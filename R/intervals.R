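#' Prune response times closer than a minimum gap
#'
#' Greedy left-to-right scan: a response is kept iff it occurs at least
#' `min_gap` seconds after the last kept response. With 2-s analysis segments
#' a 4-s gap guarantees that realigned boundary windows never overlap.
#'
#' @param times Sorted ascending numeric vector of response times (s).
#' @param min_gap Minimum allowed gap in seconds.
#' @return The kept subset of `times`.
#' @export
#' @examples
#' prune_responses(c(10, 12.5, 20)) # drops 12.5
#' prune_responses(c(0, 3, 6, 9))   # keeps 0 and 6
prune_responses <- function(times, min_gap = 4) {
  check_number(min_gap, "min_gap", lower = 0)
  if (length(times) == 0L) return(numeric())
  if (is.unsorted(times)) abort("`times` must be sorted ascending.")
  kept <- times[1L]
  last <- times[1L]
  for (t in times[-1L]) {
    if (t - last >= min_gap) {
      kept <- c(kept, t)
      last <- t
    }
  }
  kept
}

#' Classify analysis bins as boundary or no-boundary intervals
#'
#' Cuts `[0, duration)` into half-open bins `[b * width, (b + 1) * width)`
#' (0-based) and labels a bin `BI` iff at least one (pruned) response falls
#' inside, else `NBI`. A response exactly on an edge belongs to the later bin.
#'
#' @param responses Numeric vector of (pruned) response times in seconds.
#' @param duration Movie duration in seconds; must be a multiple of `width`.
#' @param width Bin width in seconds.
#' @return A tibble `bin` (0-based), `start`, `end`, `label` ("BI"/"NBI").
#' @export
classify_bins <- function(responses, duration, width = 2) {
  check_number(duration, "duration", lower = 1e-12)
  check_number(width, "width", lower = 1e-12)
  n_bins <- duration / width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    abort("`duration` must be a multiple of `width`.")
  }
  n_bins <- as.integer(round(n_bins))
  if (length(responses) && (any(responses < 0) || any(responses >= duration))) {
    abort("Responses must lie in [0, duration).")
  }
  hit <- rep(FALSE, n_bins)
  if (length(responses)) {
    hit[floor(responses / width) + 1L] <- TRUE
  }
  tibble::tibble(
    bin = seq_len(n_bins) - 1L,
    start = (seq_len(n_bins) - 1L) * width,
    end = seq_len(n_bins) * width,
    label = ifelse(hit, "BI", "NBI")
  )
}

#' Build paired, realigned boundary / no-boundary intervals
#'
#' Implements the interval-construction procedure for one subject: responses
#' are pruned with the 4-s rule; each movie clip's 2-s bins are labelled BI
#' (contains a response) or NBI; per clip, as many NBI bins as there are BI
#' are sampled without replacement (seeded), both lists are sorted by time and
#' paired in order; each BI's within-bin marker offset is copied to its paired
#' NBI as a virtual marker; finally every segment is realigned so the (virtual)
#' marker is centred, giving windows `[marker - 1, marker + 1]`.
#'
#' BI whose realigned window would cross a clip edge are dropped with a
#' warning. NBI candidates must contain no response anywhere in
#' `(bin_start - 1, bin_end + 1)`, so the realigned window is response-free for
#' any marker offset, and must lie at least 1 s inside the clip.
#'
#' @param responses Numeric vector of response times (s) for one subject
#'   (pruning is applied internally).
#' @param clips A tibble with columns `clip_id`, `start`, `end` (seconds;
#'   non-overlapping, ordered).
#' @param width Segment width in seconds.
#' @param min_gap Minimum response gap for pruning (s).
#' @param seed Integer seed for the NBI sampling (a dedicated generator, so
#'   behavioural and EEG stages reproduce independently).
#' @return A tibble of class `interval_set`: `kind` ("BI"/"NBI"), `clip_id`,
#'   `pair_id`, `bin`, `segment_start` (realigned window start), `marker_time`.
#' @export
build_interval_pairs <- function(responses, clips, width = 2, min_gap = 4, seed = 1L) {
  stopifnot(all(c("clip_id", "start", "end") %in% names(clips)))
  check_number(seed, "seed", integerish = TRUE)
  if (nrow(clips) > 1L) {
    ord <- order(clips$start)
    clips <- clips[ord, ]
    if (any(clips$end[-nrow(clips)] > clips$start[-1] + 1e-9)) {
      abort("Clips must be non-overlapping.")
    }
  }
  pruned <- prune_responses(sort(responses), min_gap = min_gap)

  set.seed(seed)
  out <- vector("list", nrow(clips))
  next_pair <- 0L
  for (i in seq_len(nrow(clips))) {
    clip <- clips[i, ]
    clip_len <- clip$end - clip$start
    n_bins <- floor((clip_len + 1e-9) / width)
    bin_start <- clip$start + (seq_len(n_bins) - 1L) * width
    bin_end <- bin_start + width

    in_clip <- pruned[pruned >= clip$start & pruned < clip$start + n_bins * width]
    bi_bin <- findInterval(in_clip, bin_start)
    # realigned window must stay inside the clip
    marker <- in_clip
    ok_edge <- marker - 1 >= clip$start & marker + 1 <= clip$end
    if (any(!ok_edge)) {
      warn(sprintf(
        "Clip %s: dropped %d boundary interval(s) whose realigned window crosses a clip edge.",
        as.character(clip$clip_id), sum(!ok_edge)
      ))
      marker <- marker[ok_edge]
      bi_bin <- bi_bin[ok_edge]
    }
    n_bi <- length(marker)
    if (n_bi == 0L) {
      warn(sprintf("Clip %s: no boundary intervals; contributes nothing.",
                   as.character(clip$clip_id)))
      next
    }

    has_resp_bin <- rep(FALSE, n_bins)
    has_resp_bin[unique(findInterval(in_clip, bin_start))] <- TRUE
    # NBI eligibility: no response (pruned or not) within (bin_start-1, bin_end+1)
    # and the widest realigned window fits inside the clip
    all_in_clip <- responses[responses >= clip$start & responses < clip$end]
    clean <- vapply(seq_len(n_bins), function(b) {
      !any(all_in_clip > bin_start[b] - 1 & all_in_clip < bin_end[b] + 1)
    }, logical(1))
    fits <- bin_start - 1 >= clip$start - 1e-9 & bin_end + 1 <= clip$end + 1e-9
    candidates <- which(clean & fits & !has_resp_bin)
    if (length(candidates) < n_bi) {
      abort(sprintf(
        "Clip %s: %d boundary intervals but only %d eligible no-boundary bins.",
        as.character(clip$clip_id), n_bi, length(candidates)
      ))
    }
    nbi_bin <- sort(sample(candidates, n_bi))
    bi_ord <- order(marker)
    marker <- marker[bi_ord]
    bi_bin <- bi_bin[bi_ord]

    offset <- marker - bin_start[bi_bin]          # within-bin marker offset
    nbi_marker <- bin_start[nbi_bin] + offset     # virtual marker, same offset

    pair_id <- next_pair + seq_len(n_bi)
    next_pair <- next_pair + n_bi
    out[[i]] <- tibble::tibble(
      kind = rep(c("BI", "NBI"), each = n_bi),
      clip_id = clip$clip_id,
      pair_id = rep(pair_id, 2L),
      bin = c(bi_bin, nbi_bin) - 1L,
      segment_start = c(marker, nbi_marker) - 1,
      marker_time = c(marker, nbi_marker)
    )
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      kind = character(), clip_id = clips$clip_id[0], pair_id = integer(),
      bin = integer(), segment_start = numeric(), marker_time = numeric()
    )
  }
  out <- dplyr::arrange(out, .data$pair_id, .data$kind)
  class(out) <- c("interval_set", class(out))
  out
}

#' Write / read an interval set as TSV
#'
#' Columns: `kind`, `clip_id`, `pair_id`, `bin`, `segment_start`,
#' `marker_time`.
#'
#' @param intervals An `interval_set` tibble.
#' @param path File path.
#' @export
write_intervals_tsv <- function(intervals, path) {
  readr::write_tsv(intervals, path)
  invisible(path)
}

#' @rdname write_intervals_tsv
#' @export
read_intervals_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  class(out) <- c("interval_set", class(out))
  out
}

#' Write / read response streams as TSV
#'
#' Columns: `subject_id`, `group`, `time` (seconds).
#'
#' @param streams Tibble from [response_streams()].
#' @param path File path.
#' @export
write_responses_tsv <- function(streams, path) {
  readr::write_tsv(streams, path)
  invisible(path)
}

#' @rdname write_responses_tsv
#' @export
read_responses_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
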