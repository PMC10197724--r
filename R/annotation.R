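#' Define a repeating annotation cycle
#'
#' A cycle is an ordered list of labeled durations (in frames) that repeats
#' for as long as the recording lasts. Typical use: a stimulus alternation
#' such as 8 frames of a circle followed by 8 frames of a square. Repetitions
#' of the cycle are tracked as 0-based iterations, which matters in behavioral
#' experiments where the subject habituates to, or learns from, a repeated
#' stimulus.
#'
#' Segments are given as a named integer vector; names may repeat (e.g.
#' `c(on = 5, off = 5, on = 3)`). The cycle is anchored at frame 1 — a phase
#' offset can be emulated with a leading segment.
#'
#' @param group Name of the annotation group (condition dimension), e.g.
#'   `"shape"`.
#' @param segments Named integer vector of durations in frames; all >= 1.
#' @param descriptions Optional named character vector of free-text label
#'   descriptions.
#' @return An object of class `cycle`.
#' @examples
#' shape <- cycle("shape", c(circle = 8, square = 8))
#' tr <- expand_cycle(shape, n_frames = 42)
#' iteration_of(tr, 30)  # 1, i.e. the second iteration
#' @export
cycle <- function(group, segments, descriptions = NULL) {
  new_segmented("cycle", group, segments, descriptions)
}

#' Define an exact annotation timeline
#'
#' A timeline is an ordered list of labeled durations that must cover the
#' recording exactly once: at expansion its durations must sum to the total
#' number of frames. Unlike a [cycle()], a timeline is never repeated or
#' truncated, and carries no iteration index.
#'
#' @inheritParams cycle
#' @return An object of class `timeline`.
#' @examples
#' light <- timeline("light", c(off = 25, on = 17))
#' tr <- expand_timeline(light, n_frames = 42)
#' frames_with_label(tr, "on")  # frames 26..42
#' @export
timeline <- function(group, segments, descriptions = NULL) {
  new_segmented("timeline", group, segments, descriptions)
}

new_segmented <- function(kind, group, segments, descriptions) {
  if (!is.character(group) || length(group) != 1L || !nzchar(group)) {
    stop("`group` must be a single non-empty string.", call. = FALSE)
  }
  if (length(segments) == 0L) {
    stop(sprintf("a %s needs at least one segment.", kind), call. = FALSE)
  }
  labs <- names(segments)
  if (is.null(labs) || any(!nzchar(labs))) {
    stop("`segments` must be a named vector (label = duration).",
         call. = FALSE)
  }
  durs <- as.integer(segments)
  if (anyNA(durs) || any(durs < 1L)) {
    stop("every segment duration must be an integer >= 1.", call. = FALSE)
  }
  if (!is.null(descriptions)) {
    extra <- setdiff(names(descriptions), labs)
    if (length(extra) > 0L) {
      stop(sprintf("descriptions given for unknown label(s): %s.",
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
  }
  structure(
    list(
      group = group,
      segments = data.frame(label = labs, duration = durs,
                            stringsAsFactors = FALSE),
      descriptions = descriptions
    ),
    class = kind
  )
}

#' @export
print.cycle <- function(x, ...) {
  cat(sprintf("<cycle> group '%s', length %d frames: %s\n",
              x$group, sum(x$segments$duration),
              paste(sprintf("%s x%d", x$segments$label, x$segments$duration),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.timeline <- function(x, ...) {
  cat(sprintf("<timeline> group '%s', %d frames: %s\n",
              x$group, sum(x$segments$duration),
              paste(sprintf("%s x%d", x$segments$label, x$segments$duration),
                    collapse = ", ")))
  invisible(x)
}

new_annotation_track <- function(group, per_frame_label, per_frame_iteration,
                                 source_kind, segments, cycle_length,
                                 descriptions = NULL) {
  structure(
    list(
      group = group,
      per_frame_label = per_frame_label,
      per_frame_iteration = per_frame_iteration,
      source_kind = source_kind,
      segments = segments,
      cycle_length = cycle_length,
      descriptions = descriptions
    ),
    class = "annotation_track"
  )
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> group '%s' (%s), %d frames, labels: %s\n",
              x$group, x$source_kind, length(x$per_frame_label),
              paste(unique(x$segments$label), collapse = ", ")))
  invisible(x)
}

#' Expand a cycle over a recording
#'
#' Frame `f` (1-based) receives the label at within-cycle position
#' `(f - 1) %% cycle_length` and iteration `(f - 1) %/% cycle_length`
#' (0-based). The final repetition is truncated if the cycle length does not
#' divide `n_frames`; a cycle longer than the recording yields a single
#' truncated iteration.
#'
#' @param cycle A [cycle()].
#' @param n_frames Total number of frames in the recording.
#' @return An object of class `annotation_track` holding `per_frame_label`
#'   and `per_frame_iteration`, both of length `n_frames`.
#' @export
expand_cycle <- function(cycle, n_frames) {
  stopifnot(inherits(cycle, "cycle"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1.", call. = FALSE)
  one <- rep(cycle$segments$label, times = cycle$segments$duration)
  len <- length(one)
  pos0 <- (seq_len(n_frames) - 1L) %% len
  new_annotation_track(
    group = cycle$group,
    per_frame_label = one[pos0 + 1L],
    per_frame_iteration = (seq_len(n_frames) - 1L) %/% len,
    source_kind = "cycle",
    segments = cycle$segments,
    cycle_length = len,
    descriptions = cycle$descriptions
  )
}

#' Expand a timeline over a recording
#'
#' The per-frame labels are the literal concatenation of the segments. The
#' segment durations must sum to `n_frames` exactly; a timeline is never
#' silently repeated or truncated.
#'
#' @param timeline A [timeline()].
#' @param n_frames Total number of frames in the recording.
#' @return An `annotation_track` without an iteration vector.
#' @export
expand_timeline <- function(timeline, n_frames) {
  stopifnot(inherits(timeline, "timeline"))
  n_frames <- as.integer(n_frames)
  total <- sum(timeline$segments$duration)
  if (total != n_frames) {
    stop(sprintf(
      "timeline '%s' covers %d frame(s) but the recording has %d; a timeline must cover the recording exactly.",
      timeline$group, total, n_frames), call. = FALSE)
  }
  new_annotation_track(
    group = timeline$group,
    per_frame_label = rep(timeline$segments$label,
                          times = timeline$segments$duration),
    per_frame_iteration = NULL,
    source_kind = "timeline",
    segments = timeline$segments,
    cycle_length = NA_integer_,
    descriptions = timeline$descriptions
  )
}

#' Frames carrying a given label
#'
#' @param track An `annotation_track`.
#' @param label_name Label to look up. An unknown label returns an empty
#'   vector with a warning, so compound queries degrade gracefully.
#' @return Sorted integer vector of 1-based frame ids.
#' @export
frames_with_label <- function(track, label_name) {
  stopifnot(inherits(track, "annotation_track"))
  if (!label_name %in% track$segments$label) {
    warning(sprintf("label '%s' is not defined in group '%s' (labels: %s); returning no frames.",
                    label_name, track$group,
                    paste(unique(track$segments$label), collapse = ", ")),
            call. = FALSE)
    return(integer(0))
  }
  which(track$per_frame_label == label_name)
}

#' Cycle iteration of a frame
#'
#' Iterations are 0-based internally; reports render them ordinally (frame 30
#' of a 16-frame cycle lies in iteration 1, "the second iteration").
#'
#' @param track An `annotation_track` built from a [cycle()].
#' @param frame_id 1-based frame number.
#' @return 0-based iteration index.
#' @export
iteration_of <- function(track, frame_id) {
  stopifnot(inherits(track, "annotation_track"))
  if (track$source_kind != "cycle") {
    stop(sprintf("group '%s' was annotated with a timeline; timelines have no cycle iterations.",
                 track$group), call. = FALSE)
  }
  frame_id <- as.integer(frame_id)
  n <- length(track$per_frame_label)
  if (length(frame_id) != 1L || is.na(frame_id) ||
      frame_id < 1L || frame_id > n) {
    stop(sprintf("frame_id must lie in [1, %d].", n), call. = FALSE)
  }
  track$per_frame_iteration[frame_id]
}

# Ordinal rendering of a 0-based iteration (0 -> "1st", 1 -> "2nd", ...).
ordinal <- function(i) {
  n <- as.integer(i) + 1L
  d <- n %% 10L
  suffix <- ifelse(n %% 100L %in% 11:13, "th",
                   ifelse(d == 1L, "st",
                          ifelse(d == 2L, "nd",
                                 ifelse(d == 3L, "rd", "th"))))
  paste0(n, suffix)
}
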