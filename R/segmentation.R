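#' Detect nonsilent segments in an audio energy envelope
#'
#' Energy-based voice activity detection: frames whose envelope value is at
#' least `threshold_frac` times the envelope maximum are active; maximal runs
#' of active frames separated by silent gaps shorter than `min_gap_s`
#' seconds are merged. Segments are 0-based half-open frame intervals on the
#' envelope timeline, returned in temporal order.
#'
#' @param envelope Non-negative numeric vector, one energy value per frame.
#' @param frame_rate Envelope frame rate in frames per second.
#' @param threshold_frac Activity threshold as a fraction of the envelope
#'   maximum, in (0, 1). Default 0.1.
#' @param min_gap_s Silent gaps shorter than this (seconds) are merged into
#'   the surrounding activity. Default 0.3.
#' @return List of segments, each a list with `start_frame`, `end_frame`
#'   and `frame_rate`. Empty list for an all-zero envelope.
#' @export
detect_nonsilent_segments <- function(envelope, frame_rate, threshold_frac = 0.1,
                                      min_gap_s = 0.3) {
  if (length(envelope) < 1) stop("envelope must contain at least one frame")
  if (any(envelope < 0)) stop("envelope values must be non-negative")
  if (threshold_frac <= 0 || threshold_frac >= 1) stop("threshold_frac must be in (0, 1)")
  peak <- max(envelope)
  if (peak == 0) return(list())
  active <- envelope >= threshold_frac * peak
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  segs <- cbind(starts[r$values], ends[r$values])
  if (nrow(segs) == 0) return(list())
  # merge runs separated by a silent gap shorter than min_gap_s
  min_gap <- min_gap_s * frame_rate
  merged <- segs[1, , drop = FALSE]
  if (nrow(segs) > 1) {
    for (i in 2:nrow(segs)) {
      gap <- segs[i, 1] - merged[nrow(merged), 2]
      if (gap < min_gap) {
        merged[nrow(merged), 2] <- segs[i, 2]
      } else {
        merged <- rbind(merged, segs[i, ])
      }
    }
  }
  lapply(seq_len(nrow(merged)), function(i) {
    list(start_frame = as.integer(merged[i, 1]),
         end_frame = as.integer(merged[i, 2]),
         frame_rate = frame_rate)
  })
}

#' Locate the emotional phase of a recording
#'
#' The emotional phase is taken to be the longest continuous nonsilent
#' segment of the recording's audio envelope, extended by `pad_after_s`
#' seconds to capture emotional expressions that outlast the utterance, and
#' clipped to the recording length. Ties on segment length are broken in
#' favour of the earliest segment.
#'
#' @inheritParams detect_nonsilent_segments
#' @param pad_after_s Seconds appended after the detected segment
#'   (default 1).
#' @return A segment (list with `start_frame`, `end_frame`, `frame_rate`)
#'   on the envelope timeline.
#' @export
extract_emotional_phase <- function(envelope, frame_rate, threshold_frac = 0.1,
                                    min_gap_s = 0.3, pad_after_s = 1.0) {
  segs <- detect_nonsilent_segments(envelope, frame_rate, threshold_frac, min_gap_s)
  if (length(segs) == 0) stop("no nonsilent segment found in envelope")
  lens <- vapply(segs, function(s) s$end_frame - s$start_frame, numeric(1))
  best <- segs[[which.max(lens)]]  # which.max returns the earliest maximum
  pad <- round(frame_rate * pad_after_s)
  best$end_frame <- as.integer(min(best$end_frame + pad, length(envelope)))
  best
}

#' Map a segment between two frame rates
#'
#' Converts a 0-based half-open interval from one timeline to another:
#' start index via `floor`, end index via `ceiling`, so the mapped window
#' covers the full span of the source window.
#'
#' @param seg Segment on the source timeline.
#' @param to_fps Target frame rate.
#' @return Segment on the target timeline.
#' @export
map_segment <- function(seg, to_fps) {
  scale <- to_fps / seg$frame_rate
  list(start_frame = as.integer(floor(seg$start_frame * scale)),
       end_frame = as.integer(ceiling(seg$end_frame * scale)),
       frame_rate = to_fps)
}

#' Trim a video record to a detected segment
#'
#' Restricts the record's feature sequence to the frames covered by `seg`
#' (mapped from the envelope timeline to the feature timeline when the two
#' rates differ) and records the resulting phase on the output.
#'
#' @param rec A `video_record`.
#' @param seg A segment, typically from [extract_emotional_phase()] on
#'   `rec$envelope`.
#' @return A `video_record` whose features cover only the segment.
#' @export
trim_to_phase <- function(rec, seg) {
  stopifnot(inherits(rec, "video_record"))
  feat_fps <- rec$features$fps
  m <- if (seg$frame_rate == feat_fps) seg else map_segment(seg, feat_fps)
  t_total <- nrow(rec$features$values)
  start <- max(0L, m$start_frame)
  end <- min(t_total, m$end_frame)
  if (end - start < 1) stop("segment maps to fewer than one feature frame")
  values <- rec$features$values[(start + 1):end, , drop = FALSE]
  feats <- feature_sequence(values, kind = rec$features$kind, fps = feat_fps,
                            detected = rec$features$detected[(start + 1):end])
  out <- video_record(rec$subject_id, rec$label, feats, envelope = rec$envelope,
                      phase = NULL)
  out$phase_in_source <- c(start, end)  # location of the kept window in the input
  out
}

#' Detect and trim the emotional phase of a record
#'
#' Convenience wrapper: runs [extract_emotional_phase()] on the record's
#' audio envelope and trims the features to it.
#'
#' @inheritParams extract_emotional_phase
#' @param rec A `video_record` with an audio envelope.
#' @return The trimmed `video_record` (see [trim_to_phase()]).
#' @export
segment_record <- function(rec, threshold_frac = 0.1, min_gap_s = 0.3,
                           pad_after_s = 1.0) {
  if (is.null(rec$envelope)) stop("record has no audio envelope to segment")
  seg <- extract_emotional_phase(rec$envelope$values, rec$envelope$fps,
                                 threshold_frac, min_gap_s, pad_after_s)
  trim_to_phase(rec, seg)
}

#' Jaccard overlap of two half-open frame intervals
#'
#' @param a,b Length-2 numeric vectors `c(start, end)`.
#' @return Intersection over union of the two intervals, in `[0, 1]`.
#' @export
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  union <- (a[2] - a[1]) + (b[2] - b[1]) - inter
  if (union <= 0) return(0)
  inter / union
}
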