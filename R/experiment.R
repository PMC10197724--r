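#' Create an experiment: map files, volumes, and annotations
#'
#' The mapping step of the pipeline: probes every image file for its frame
#' count, builds the global frame-to-(file, page) and frame-to-(volume,
#' slice) maps, and expands the supplied annotations ([cycle()]s and
#' [timeline()]s) into per-frame label assignments. The result answers
#' condition queries in memory; [save_experiment()] persists it to a SQLite
#' file.
#'
#' @param data_dir Directory holding the recording's image files; all files
#'   with a registered extension are used, ordered lexicographically by name.
#'   Ignored when `files` is given.
#' @param frames_per_volume Number of frames (depth slices) per volume.
#' @param head_offset Frames preceding the first full volume (default 0).
#' @param annotations List of [cycle()] / [timeline()] objects, one per
#'   annotation group.
#' @param files Explicit character vector of file paths in acquisition
#'   order; overrides `data_dir` discovery.
#' @param verbose Emit a one-line mapping summary via [message()]
#'   (default TRUE).
#' @return An object of class `experiment`.
#' @examples
#' \dontrun{
#' ex <- experiment(data_dir = "toy", frames_per_volume = 10,
#'                  annotations = list(
#'                    timeline("light", c(off = 25, on = 17)),
#'                    cycle("shape", c(circle = 8, square = 8))))
#' choose_volumes(ex, list(c("light", "on")))
#' }
#' @export
experiment <- function(data_dir = NULL, frames_per_volume, head_offset = 0L,
                       annotations = list(), files = NULL, verbose = TRUE) {
  if (is.null(files)) {
    if (is.null(data_dir)) {
      stop("either `data_dir` or `files` must be given.", call. = FALSE)
    }
    all_files <- list.files(data_dir, full.names = TRUE)
    ext <- vapply(all_files, function(p) normalize_ext(tools::file_ext(p)),
                  character(1))
    files <- all_files[ext %in% registered_formats()]
    files <- files[order(basename(files))]
    if (length(files) == 0L) {
      stop(sprintf("no image files with a registered extension (%s) found in '%s'.",
                   paste(registered_formats(), collapse = ", "), data_dir),
           call. = FALSE)
    }
  }
  sources <- lapply(files, probe)
  shapes <- vapply(sources, function(s) paste(s$page_shape, collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L) {
    stop(sprintf("page shapes differ across files (%s); one recording must have a single frame shape.",
                 paste(unique(shapes), collapse = ", ")), call. = FALSE)
  }
  fm <- file_map(files, vapply(sources, `[[`, integer(1), "n_pages"))
  vm <- volume_map(fm$total_frames, frames_per_volume, head_offset)

  tracks <- list()
  for (ann in annotations) {
    tr <- if (inherits(ann, "cycle")) {
      expand_cycle(ann, fm$total_frames)
    } else if (inherits(ann, "timeline")) {
      expand_timeline(ann, fm$total_frames)
    } else if (inherits(ann, "annotation_track")) {
      if (length(ann$per_frame_label) != fm$total_frames) {
        stop(sprintf("annotation group '%s' covers %d frame(s) but the recording has %d.",
                     ann$group, length(ann$per_frame_label),
                     fm$total_frames), call. = FALSE)
      }
      ann
    } else {
      stop("each annotation must be a cycle(), timeline(), or annotation_track.",
           call. = FALSE)
    }
    if (tr$group %in% names(tracks)) {
      stop(sprintf("duplicate annotation group '%s'.", tr$group),
           call. = FALSE)
    }
    tracks[[tr$group]] <- tr
  }

  ex <- structure(
    list(file_map = fm, volume_map = vm, tracks = tracks,
         sources = sources, db = NULL),
    class = "experiment"
  )
  if (verbose) {
    message(sprintf(
      "mapped %d file(s), %d frames: %d full volume(s) of %d frame(s), %d head + %d tail frame(s), %d annotation group(s)",
      nrow(fm$files), fm$total_frames, vm$n_full_volumes, frames_per_volume,
      sum(vm$per_frame_volume == VOL_HEAD),
      sum(vm$per_frame_volume == VOL_TAIL), length(tracks)))
  }
  ex
}

#' @export
print.experiment <- function(x, ...) {
  cat(sprintf(
    "<experiment> %d file(s), %d frames, %d full volume(s) (%d/volume), groups: %s%s\n",
    nrow(x$file_map$files), x$file_map$total_frames,
    x$volume_map$n_full_volumes, x$volume_map$frames_per_volume,
    if (length(x$tracks)) paste(names(x$tracks), collapse = ", ") else "<none>",
    if (is.null(x$db)) "" else sprintf(" [db: %s]", x$db$db_path)))
  invisible(x)
}

#' Save an experiment to a SQLite database file
#'
#' @param ex An [experiment()].
#' @param db_path Path of the database file to write.
#' @return The experiment, invisibly, with the database handle attached (so
#'   subsequent queries run against the file).
#' @export
save_experiment <- function(ex, db_path) {
  stopifnot(inherits(ex, "experiment"))
  ex$db <- persist_experiment(ex$file_map, ex$volume_map, ex$tracks, db_path)
  invisible(ex)
}

#' Reopen an experiment from its database file
#'
#' The restored experiment answers all frame/volume queries from the
#' database alone. Pixel loading additionally needs the image files: their
#' paths are taken from the database, or rebased into `data_dir` by file
#' name when the recording has moved.
#'
#' @param db_path Path to a database written by [save_experiment()] /
#'   [persist_experiment()].
#' @param data_dir Optional directory now holding the image files.
#' @return An `experiment`.
#' @export
load_experiment <- function(db_path, data_dir = NULL) {
  st <- restore_experiment(db_path)
  paths <- st$file_map$files$path
  if (!is.null(data_dir)) {
    paths <- file.path(data_dir, basename(paths))
    st$file_map <- file_map(paths, st$file_map$files$n_frames)
  }
  sources <- NULL
  if (all(file.exists(paths))) {
    sources <- lapply(paths, probe)
    counts <- vapply(sources, `[[`, integer(1), "n_pages")
    if (!identical(counts, st$file_map$files$n_frames)) {
      stop("frame counts on disk no longer match the database; was the recording modified?",
           call. = FALSE)
    }
  }
  structure(
    list(file_map = st$file_map, volume_map = st$volume_map,
         tracks = st$tracks, sources = sources, db = st$db),
    class = "experiment"
  )
}

# In-memory evaluation of a condition set against expanded tracks.
memory_frame_query <- function(ex, cond, logic) {
  sets <- vector("list", nrow(cond))
  for (i in seq_len(nrow(cond))) {
    g <- cond$group[i]
    if (!g %in% names(ex$tracks)) {
      stop(sprintf("unknown annotation group(s): %s (available: %s).", g,
                   if (length(ex$tracks))
                     paste(sort(names(ex$tracks)), collapse = ", ")
                   else "<none>"),
           call. = FALSE)
    }
    sets[[i]] <- frames_with_label(ex$tracks[[g]], cond$label[i])
  }
  sort(Reduce(if (logic == "and") intersect else union, sets))
}

#' Frames matching experimental conditions
#'
#' Returns the sorted 1-based indices of all frames recorded under the given
#' combination of conditions. When the experiment has a database attached
#' the query runs in SQL; otherwise it is evaluated against the in-memory
#' tracks. Both paths give identical answers.
#'
#' @param ex An [experiment()].
#' @inheritParams query_frames
#' @return Sorted integer vector of frame ids.
#' @export
choose_frames <- function(ex, conditions, logic = NULL) {
  stopifnot(inherits(ex, "experiment"))
  cond <- normalize_conditions(conditions)
  logic <- check_logic(logic, nrow(cond))
  res <- if (!is.null(ex$db)) {
    query_frames(ex$db, cond, logic)
  } else {
    memory_frame_query(ex, cond, logic)
  }
  log_query("frames", cond, logic, length(res))
  res
}

#' Full volumes matching experimental conditions
#'
#' A volume is selected only when all of its frames match; partial head/tail
#' frames never form a returned volume. Conditions that switch mid-volume
#' (e.g. a stimulus cycle shorter than a volume) can therefore select frames
#' but no volumes — use [choose_frames()] there.
#'
#' @inheritParams choose_frames
#' @return Sorted integer vector of full-volume codes (0-based).
#' @export
choose_volumes <- function(ex, conditions, logic = NULL) {
  stopifnot(inherits(ex, "experiment"))
  cond <- normalize_conditions(conditions)
  logic <- check_logic(logic, nrow(cond))
  res <- if (!is.null(ex$db)) {
    query_volumes(ex$db, cond, logic)
  } else {
    frames <- memory_frame_query(ex, cond, logic)
    full <- full_volume_codes(ex$volume_map)
    keep <- vapply(full, function(v) {
      all(frames_of_volumes(ex$volume_map, v) %in% frames)
    }, logical(1))
    full[keep]
  }
  log_query("volumes", cond, logic, length(res))
  res
}

log_query <- function(what, cond, logic, n_hits) {
  message(sprintf("query %s: %s [%s] -> %d hit(s)", what,
                  paste(sprintf("%s=%s", cond$group, cond$label),
                        collapse = ", "),
                  logic, n_hits))
}

experiment_sources <- function(ex) {
  if (is.null(ex$sources)) {
    stop("image files are not available for this experiment (database-only session); pixel loading needs them.",
         call. = FALSE)
  }
  ex$sources
}

#' Load individual frames as a 3D array
#'
#' Frames are fetched lazily: only the pages backing the requested frames
#' are decoded, grouped by file. The output keeps the caller's order, and
#' duplicate ids are honored.
#'
#' @param ex An [experiment()].
#' @param frame_ids 1-based global frame numbers.
#' @return Array of shape `(length(frame_ids), height, width)`.
#' @export
load_frames <- function(ex, frame_ids) {
  stopifnot(inherits(ex, "experiment"))
  sources <- experiment_sources(ex)
  frame_ids <- as.integer(frame_ids)
  shape <- sources[[1]]$page_shape
  if (length(frame_ids) == 0L) return(array(0, dim = c(0L, shape)))

  locs <- lapply(frame_ids, function(f) locate_frame(ex$file_map, f))
  file_order <- vapply(locs, `[[`, integer(1), "file_order")
  page_index <- vapply(locs, `[[`, integer(1), "page_index")
  out <- array(0L, dim = c(length(frame_ids), shape))
  for (fo in unique(file_order)) {
    sel <- which(file_order == fo)
    stack <- read_pages(sources[[fo + 1L]], page_index[sel])
    out[sel, , ] <- stack
  }
  out
}

#' Load volumes as a 4D array
#'
#' @param ex An [experiment()].
#' @param volume_codes Full-volume codes (0-based), in the stacking order the
#'   caller wants.
#' @param allow_partial Also accept the partial head (`-1`) / tail (`-2`)
#'   codes. Because partial volumes have fewer slices, the result is then a
#'   list with one `(slices, height, width)` array per requested code.
#' @return Array of shape `(length(volume_codes), frames_per_volume, height,
#'   width)`, or a list of 3D arrays when `allow_partial = TRUE`.
#' @export
load_volumes <- function(ex, volume_codes, allow_partial = FALSE) {
  stopifnot(inherits(ex, "experiment"))
  sources <- experiment_sources(ex)
  volume_codes <- as.integer(volume_codes)
  shape <- sources[[1]]$page_shape
  fpv <- ex$volume_map$frames_per_volume

  if (any(volume_codes < 0L) && !allow_partial) {
    stop("partial head/tail volumes requested; pass allow_partial = TRUE to load them (their slice depth differs).",
         call. = FALSE)
  }
  if (allow_partial) {
    return(lapply(volume_codes, function(v) {
      load_frames(ex, frames_of_volumes(ex$volume_map, v))
    }))
  }
  if (length(volume_codes) == 0L) {
    return(array(0, dim = c(0L, fpv, shape)))
  }
  frames <- lapply(volume_codes, function(v) {
    frames_of_volumes(ex$volume_map, v)
  })
  flat <- load_frames(ex, unlist(frames))
  out <- array(0L, dim = c(length(volume_codes), fpv, shape))
  for (i in seq_along(volume_codes)) {
    out[i, , , ] <- flat[(i - 1L) * fpv + seq_len(fpv), , , drop = FALSE]
  }
  out
}

#' Summarize an experiment
#'
#' @param ex An [experiment()].
#' @param ... Unused.
#' @return An object of class `experiment_summary`: files, frame/volume
#'   totals, and per-group label frame counts and cycle lengths.
#' @export
describe <- function(ex, ...) UseMethod("describe")

#' @rdname describe
#' @export
describe.experiment <- function(ex, ...) {
  vm <- ex$volume_map
  groups <- lapply(ex$tracks, function(tr) {
    counts <- table(factor(tr$per_frame_label,
                           levels = unique(tr$segments$label)))
    list(kind = tr$source_kind,
         cycle_length = tr$cycle_length,
         label_counts = stats::setNames(as.integer(counts), names(counts)))
  })
  structure(
    list(
      files = ex$file_map$files,
      n_frames = ex$file_map$total_frames,
      frames_per_volume = vm$frames_per_volume,
      head_offset = vm$head_offset,
      n_full_volumes = vm$n_full_volumes,
      n_head_frames = sum(vm$per_frame_volume == VOL_HEAD),
      n_tail_frames = sum(vm$per_frame_volume == VOL_TAIL),
      groups = groups
    ),
    class = "experiment_summary"
  )
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("%d file(s), %d frames, %d per volume: %d full volume(s), %d head, %d tail\n",
              nrow(x$files), x$n_frames, x$frames_per_volume,
              x$n_full_volumes, x$n_head_frames, x$n_tail_frames))
  for (g in names(x$groups)) {
    gi <- x$groups[[g]]
    cat(sprintf("  %s (%s%s): %s\n", g, gi$kind,
                if (!is.na(gi$cycle_length))
                  sprintf(", cycle length %d", gi$cycle_length) else "",
                paste(sprintf("%s=%d", names(gi$label_counts),
                              gi$label_counts), collapse = ", ")))
  }
  invisible(x)
}

#' Per-frame report of everything known about one frame
#'
#' Collects the storage location, volumetric position, and every group's
#' label (with the cycle iteration rendered ordinally) for one frame.
#'
#' @param ex An [experiment()].
#' @param frame_id 1-based frame number.
#' @return A list with `frame_id`, `file_order`, `page_index`, `path`,
#'   `volume_code`, `slice_index`, and a named list `labels` of
#'   `list(label, iteration, iteration_ordinal)` per group.
#' @export
frame_report <- function(ex, frame_id) {
  stopifnot(inherits(ex, "experiment"))
  loc <- locate_frame(ex$file_map, frame_id)
  vs <- volume_and_slice_of(ex$volume_map, frame_id)
  labels <- lapply(ex$tracks, function(tr) {
    it <- if (tr$source_kind == "cycle") iteration_of(tr, frame_id) else NA_integer_
    list(label = tr$per_frame_label[frame_id],
         iteration = it,
         iteration_ordinal = if (is.na(it)) NA_character_ else ordinal(it))
  })
  c(loc, vs, list(labels = labels))
}

#' Build an experiment from a YAML configuration
#'
#' The configuration mirrors the [experiment()] arguments:
#'
#' ```yaml
#' data_dir: toy
#' frames_per_volume: 10
#' head_offset: 0
#' file_order: [mov0.tif, mov1.tif, mov2.tif]   # optional, overrides sorting
#' annotations:
#'   light:
#'     kind: timeline
#'     segments: [{off: 25}, {on: 17}]
#'   shape:
#'     kind: cycle
#'     segments: [{circle: 8}, {square: 8}]
#' ```
#'
#' Segments are a YAML list of single-entry `label: duration` maps so that
#' order is preserved and labels may repeat.
#'
#' @param config_path Path to the YAML file.
#' @param verbose Passed to [experiment()].
#' @return An `experiment`.
#' @export
experiment_from_yaml <- function(config_path, verbose = TRUE) {
  # keep 'on', 'off', 'yes', 'no' as literal label names rather than YAML 1.1
  # booleans; the config schema has no boolean-valued field
  cfg <- yaml::read_yaml(config_path, handlers = list(
    "bool#yes" = function(x) x, "bool#no" = function(x) x))
  for (req in c("data_dir", "frames_per_volume")) {
    if (is.null(cfg[[req]])) {
      stop(sprintf("config is missing required field '%s'.", req),
           call. = FALSE)
    }
  }
  files <- NULL
  if (!is.null(cfg$file_order)) {
    files <- file.path(cfg$data_dir, cfg$file_order)
  }
  annotations <- list()
  for (g in names(cfg$annotations)) {
    spec <- cfg$annotations[[g]]
    if (is.null(spec$kind) || !spec$kind %in% c("cycle", "timeline")) {
      stop(sprintf("annotation group '%s' must declare kind: cycle or timeline.",
                   g), call. = FALSE)
    }
    segs <- parse_yaml_segments(spec$segments, g)
    ctor <- if (spec$kind == "cycle") cycle else timeline
    annotations[[g]] <- ctor(g, segs,
                             descriptions = unlist(spec$descriptions))
  }
  experiment(
    data_dir = cfg$data_dir,
    frames_per_volume = cfg$frames_per_volume,
    head_offset = if (is.null(cfg$head_offset)) 0L else cfg$head_offset,
    annotations = annotations,
    files = files,
    verbose = verbose
  )
}

parse_yaml_segments <- function(segments, group) {
  if (is.null(segments) || length(segments) == 0L) {
    stop(sprintf("annotation group '%s' has no segments.", group),
         call. = FALSE)
  }
  labs <- character(0)
  durs <- integer(0)
  for (s in segments) {
    if (!is.list(s) && length(s) == 1L && !is.null(names(s))) {
      s <- as.list(s)
    }
    if (length(s) != 1L || is.null(names(s))) {
      stop(sprintf("each segment of group '%s' must be a single 'label: duration' entry.",
                   group), call. = FALSE)
    }
    labs <- c(labs, names(s))
    durs <- c(durs, as.integer(s[[1]]))
  }
  stats::setNames(durs, labs)
}
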