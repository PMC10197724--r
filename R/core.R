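#' Build a file map for a multi-file recording
#'
#' A recording is acquired as one continuous stream of 2D frames split across
#' several image files. The file map records, for each file, its position in
#' the recording and its frame count, plus the cumulative frame offsets needed
#' to translate a global frame number into a (file, page) location.
#'
#' @param paths Character vector of file paths, already in acquisition order.
#' @param frame_counts Integer vector, one count per file; every count must be
#'   at least 1.
#'
#' @return An object of class `file_map` with components:
#'   \describe{
#'     \item{files}{data.frame with `order_index` (0-based), `path`,
#'       `n_frames`.}
#'     \item{cumulative_offsets}{integer vector; `cumulative_offsets[i]` is the
#'       number of frames stored in files preceding file `i`.}
#'     \item{total_frames}{total number of frames in the recording.}
#'   }
#' @examples
#' fm <- file_map(c("a.tif", "b.tif", "c.tif"), c(13, 13, 16))
#' fm$total_frames        # 42
#' locate_frame(fm, 30)   # 4th page of the 3rd file
#' @seealso [locate_frame()], [volume_map()]
#' @export
file_map <- function(paths, frame_counts) {
  if (length(paths) == 0L) {
    stop("`paths` must contain at least one file.", call. = FALSE)
  }
  if (length(paths) != length(frame_counts)) {
    stop(sprintf("%d paths but %d frame counts.", length(paths),
                 length(frame_counts)), call. = FALSE)
  }
  frame_counts <- as.integer(frame_counts)
  if (anyNA(frame_counts) || any(frame_counts < 1L)) {
    stop("every frame count must be an integer >= 1.", call. = FALSE)
  }
  offsets <- cumsum(c(0L, frame_counts[-length(frame_counts)]))
  structure(
    list(
      files = data.frame(
        order_index = seq_along(paths) - 1L,
        path = as.character(paths),
        n_frames = frame_counts,
        stringsAsFactors = FALSE
      ),
      cumulative_offsets = as.integer(offsets),
      total_frames = sum(frame_counts)
    ),
    class = "file_map"
  )
}

#' @export
print.file_map <- function(x, ...) {
  cat(sprintf("<file_map> %d file(s), %d frames\n",
              nrow(x$files), x$total_frames))
  for (i in seq_len(nrow(x$files))) {
    cat(sprintf("  [%d] %s  (%d frames, offset %d)\n",
                x$files$order_index[i], x$files$path[i],
                x$files$n_frames[i], x$cumulative_offsets[i]))
  }
  invisible(x)
}

#' Locate a global frame inside its file
#'
#' Frames are numbered 1-based across the whole recording ("frame number 30"
#' is the 30th acquired frame); pages within a file are 0-based.
#'
#' @param map A [file_map()].
#' @param frame_id 1-based global frame number.
#' @return A list with `frame_id`, `file_order` (0-based file position),
#'   `page_index` (0-based page within that file), and `path`.
#' @export
locate_frame <- function(map, frame_id) {
  stopifnot(inherits(map, "file_map"))
  frame_id <- as.integer(frame_id)
  if (length(frame_id) != 1L || is.na(frame_id) ||
      frame_id < 1L || frame_id > map$total_frames) {
    stop(sprintf("frame_id must lie in [1, %d]; got %s.",
                 map$total_frames, format(frame_id)), call. = FALSE)
  }
  file_order <- findInterval(frame_id - 1L, map$cumulative_offsets,
                             rightmost.closed = FALSE) - 1L
  page_index <- frame_id - map$cumulative_offsets[file_order + 1L] - 1L
  list(
    frame_id = frame_id,
    file_order = file_order,
    page_index = page_index,
    path = map$files$path[file_order + 1L]
  )
}

# Volume codes: 0..(n_full-1) are full volumes, -1 marks head frames acquired
# before the first complete volume, -2 marks tail frames after the last one.
VOL_HEAD <- -1L
VOL_TAIL <- -2L

#' Map every frame of a recording to its volume and slice
#'
#' A volume is a stack of `frames_per_volume` consecutive frames, one per
#' imaging depth. Recordings rarely divide evenly: `head_offset` frames at the
#' start may belong to a volume whose beginning was not recorded, and frames
#' after the last complete volume form a partial tail. Full volumes are coded
#' `0 .. n_full_volumes-1`; head frames are coded `-1`, tail frames `-2`.
#'
#' Slice indices are 0-based depth positions. Tail frames restart at slice 0
#' (they are the first slices of the unfinished next volume); head frames get
#' the trailing slice indices `frames_per_volume - head_offset`, ... (they are
#' the last slices of the truncated first volume).
#'
#' @param n_frames Total number of frames in the recording.
#' @param frames_per_volume Number of frames (depth slices) per volume.
#' @param head_offset Number of frames preceding the first full volume
#'   (default 0).
#' @return An object of class `volume_map` with `n_frames`,
#'   `frames_per_volume`, `head_offset`, `n_full_volumes`, and per-frame
#'   vectors `per_frame_volume` and `per_frame_slice`.
#' @examples
#' vm <- volume_map(42, 10)
#' vm$n_full_volumes                 # 4 full volumes
#' sum(vm$per_frame_volume == -2)    # 2 tail frames
#' volume_and_slice_of(vm, 30)       # slice 9 of volume 2 (the 3rd volume)
#' @export
volume_map <- function(n_frames, frames_per_volume, head_offset = 0L) {
  n_frames <- as.integer(n_frames)
  frames_per_volume <- as.integer(frames_per_volume)
  head_offset <- as.integer(head_offset)
  if (n_frames < 1L) stop("n_frames must be >= 1.", call. = FALSE)
  if (frames_per_volume < 1L) {
    stop("frames_per_volume must be >= 1.", call. = FALSE)
  }
  if (head_offset < 0L || head_offset >= n_frames) {
    stop(sprintf("head_offset must lie in [0, %d); got %d.",
                 n_frames, head_offset), call. = FALSE)
  }
  n_full <- (n_frames - head_offset) %/% frames_per_volume

  ids <- seq_len(n_frames)
  rel <- ids - head_offset                       # 1-based position past head
  vol <- (rel - 1L) %/% frames_per_volume
  slice <- (rel - 1L) %% frames_per_volume
  vol[vol >= n_full] <- VOL_TAIL
  is_head <- ids <= head_offset
  vol[is_head] <- VOL_HEAD
  slice[is_head] <- frames_per_volume - head_offset + ids[is_head] - 1L

  structure(
    list(
      n_frames = n_frames,
      frames_per_volume = frames_per_volume,
      head_offset = head_offset,
      n_full_volumes = as.integer(n_full),
      per_frame_volume = as.integer(vol),
      per_frame_slice = as.integer(slice)
    ),
    class = "volume_map"
  )
}

#' @export
print.volume_map <- function(x, ...) {
  cat(sprintf(
    "<volume_map> %d frames, %d per volume: %d full volume(s), %d head, %d tail\n",
    x$n_frames, x$frames_per_volume, x$n_full_volumes,
    sum(x$per_frame_volume == VOL_HEAD), sum(x$per_frame_volume == VOL_TAIL)))
  invisible(x)
}

#' Volume code and slice index of one frame
#'
#' @param map A [volume_map()].
#' @param frame_id 1-based global frame number.
#' @return A list with `volume_code` (full volumes 0-based; `-1` head, `-2`
#'   tail) and `slice_index` (0-based).
#' @export
volume_and_slice_of <- function(map, frame_id) {
  stopifnot(inherits(map, "volume_map"))
  frame_id <- as.integer(frame_id)
  if (length(frame_id) != 1L || is.na(frame_id) ||
      frame_id < 1L || frame_id > map$n_frames) {
    stop(sprintf("frame_id must lie in [1, %d]; got %s.",
                 map$n_frames, format(frame_id)), call. = FALSE)
  }
  list(
    volume_code = map$per_frame_volume[frame_id],
    slice_index = map$per_frame_slice[frame_id]
  )
}

#' Frames making up the requested volumes
#'
#' Inverse of [volume_and_slice_of()]: returns the sorted 1-based frame
#' numbers whose volume code is among `volume_codes`. Requesting all codes
#' present in the map partitions `1..n_frames` exactly.
#'
#' @param map A [volume_map()].
#' @param volume_codes Integer vector of volume codes (`-1` head, `-2` tail,
#'   `0..n_full_volumes-1` full).
#' @return Sorted integer vector of frame ids.
#' @export
frames_of_volumes <- function(map, volume_codes) {
  stopifnot(inherits(map, "volume_map"))
  volume_codes <- as.integer(volume_codes)
  known <- unique(map$per_frame_volume)
  bad <- setdiff(volume_codes, known)
  if (length(bad) > 0L) {
    stop(sprintf("unknown volume code(s): %s (codes present: %s).",
                 paste(bad, collapse = ", "),
                 paste(sort(known), collapse = ", ")), call. = FALSE)
  }
  sort(which(map$per_frame_volume %in% volume_codes))
}

#' Full-volume codes of a volume map
#'
#' @param map A [volume_map()].
#' @return Integer vector `0 .. n_full_volumes-1` (empty when no frame span
#'   completes a volume).
#' @export
full_volume_codes <- function(map) {
  stopifnot(inherits(map, "volume_map"))
  if (map$n_full_volumes == 0L) integer(0) else seq_len(map$n_full_volumes) - 1L
}
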