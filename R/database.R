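# SQLite schema. The database file is self-contained: a restored experiment
# answers every frame/volume query without the original image files (only
# pixel loading touches them).
DB_SCHEMA_VERSION <- "1.0"

DB_TABLES <- c("options", "files", "frames", "volumes", "annotation_groups",
               "labels", "frame_labels", "frame_iterations", "cycles")

db_connect <- function(db_path) {
  DBI::dbConnect(RSQLite::SQLite(), db_path, bigint = "integer")
}

#' Persist an experiment description to a SQLite database file
#'
#' Writes the full mapping state — file map, volume map, and all expanded
#' annotation tracks (labels, cycle iterations, segment definitions) — into a
#' single self-contained SQLite file that can be shared or reopened later.
#'
#' @param file_map A [file_map()].
#' @param volume_map A [volume_map()] over the same number of frames.
#' @param tracks List of `annotation_track` objects (possibly empty); every
#'   track must cover exactly `file_map$total_frames` frames.
#' @param db_path Path of the database file to create (overwritten if
#'   present).
#' @return An object of class `experiment_db` (fields `db_path`,
#'   `schema_version`).
#' @seealso [restore_experiment()], [query_frames()], [query_volumes()]
#' @export
persist_experiment <- function(file_map, volume_map, tracks, db_path) {
  stopifnot(inherits(file_map, "file_map"), inherits(volume_map, "volume_map"))
  n <- file_map$total_frames
  if (volume_map$n_frames != n) {
    stop(sprintf("volume map covers %d frames but the file map holds %d.",
                 volume_map$n_frames, n), call. = FALSE)
  }
  for (tr in tracks) {
    stopifnot(inherits(tr, "annotation_track"))
    if (length(tr$per_frame_label) != n) {
      stop(sprintf("annotation group '%s' covers %d frame(s) but the recording has %d.",
                   tr$group, length(tr$per_frame_label), n), call. = FALSE)
    }
  }
  groups <- vapply(tracks, function(tr) tr$group, character(1))
  if (anyDuplicated(groups)) {
    stop(sprintf("duplicate annotation group(s): %s.",
                 paste(unique(groups[duplicated(groups)]), collapse = ", ")),
         call. = FALSE)
  }

  if (file.exists(db_path)) file.remove(db_path)
  con <- db_connect(db_path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  DBI::dbExecute(con, "PRAGMA journal_mode = MEMORY")
  DBI::dbBegin(con)

  DBI::dbExecute(con, "CREATE TABLE options (key TEXT PRIMARY KEY, value TEXT NOT NULL)")
  DBI::dbExecute(con, "CREATE TABLE files (order_index INTEGER PRIMARY KEY, path TEXT NOT NULL, n_frames INTEGER NOT NULL)")
  DBI::dbExecute(con, "CREATE TABLE frames (frame_id INTEGER PRIMARY KEY, file_order INTEGER NOT NULL, page_index INTEGER NOT NULL)")
  DBI::dbExecute(con, "CREATE TABLE volumes (frame_id INTEGER PRIMARY KEY, volume_code INTEGER NOT NULL, slice_index INTEGER NOT NULL)")
  DBI::dbExecute(con, "CREATE TABLE annotation_groups (group_name TEXT PRIMARY KEY, source_kind TEXT NOT NULL, cycle_length INTEGER)")
  DBI::dbExecute(con, "CREATE TABLE labels (group_name TEXT NOT NULL, label_name TEXT NOT NULL, description TEXT, PRIMARY KEY (group_name, label_name))")
  DBI::dbExecute(con, "CREATE TABLE frame_labels (frame_id INTEGER NOT NULL, group_name TEXT NOT NULL, label_name TEXT NOT NULL, PRIMARY KEY (frame_id, group_name))")
  DBI::dbExecute(con, "CREATE TABLE frame_iterations (frame_id INTEGER NOT NULL, group_name TEXT NOT NULL, iteration INTEGER NOT NULL, PRIMARY KEY (frame_id, group_name))")
  DBI::dbExecute(con, "CREATE TABLE cycles (group_name TEXT PRIMARY KEY, segments_json TEXT NOT NULL)")
  DBI::dbExecute(con, "CREATE INDEX idx_frame_labels_cond ON frame_labels (group_name, label_name)")
  DBI::dbExecute(con, "CREATE INDEX idx_volumes_code ON volumes (volume_code)")

  opts <- data.frame(
    key = c("schema_version", "n_frames", "frames_per_volume", "head_offset"),
    value = as.character(c(DB_SCHEMA_VERSION, n,
                           volume_map$frames_per_volume,
                           volume_map$head_offset)),
    stringsAsFactors = FALSE
  )
  DBI::dbAppendTable(con, "options", opts)
  DBI::dbAppendTable(con, "files", file_map$files[, c("order_index", "path", "n_frames")])

  locs <- lapply(seq_len(n), function(f) locate_frame(file_map, f))
  DBI::dbAppendTable(con, "frames", data.frame(
    frame_id = seq_len(n),
    file_order = vapply(locs, `[[`, integer(1), "file_order"),
    page_index = vapply(locs, `[[`, integer(1), "page_index")
  ))
  DBI::dbAppendTable(con, "volumes", data.frame(
    frame_id = seq_len(n),
    volume_code = volume_map$per_frame_volume,
    slice_index = volume_map$per_frame_slice
  ))

  for (tr in tracks) {
    DBI::dbAppendTable(con, "annotation_groups", data.frame(
      group_name = tr$group, source_kind = tr$source_kind,
      cycle_length = if (is.na(tr$cycle_length)) NA_integer_ else tr$cycle_length
    ))
    labs <- unique(tr$segments$label)
    descr <- vapply(labs, function(l) {
      d <- tr$descriptions[[l]]
      if (is.null(d)) NA_character_ else as.character(d)
    }, character(1))
    DBI::dbAppendTable(con, "labels", data.frame(
      group_name = tr$group, label_name = labs, description = unname(descr)
    ))
    DBI::dbAppendTable(con, "frame_labels", data.frame(
      frame_id = seq_len(n), group_name = tr$group,
      label_name = tr$per_frame_label
    ))
    if (!is.null(tr$per_frame_iteration)) {
      DBI::dbAppendTable(con, "frame_iterations", data.frame(
        frame_id = seq_len(n), group_name = tr$group,
        iteration = tr$per_frame_iteration
      ))
    }
    DBI::dbAppendTable(con, "cycles", data.frame(
      group_name = tr$group,
      segments_json = jsonlite::toJSON(tr$segments, dataframe = "columns")
    ))
  }

  DBI::dbCommit(con)
  structure(list(db_path = db_path, schema_version = DB_SCHEMA_VERSION),
            class = "experiment_db")
}

#' @export
print.experiment_db <- function(x, ...) {
  cat(sprintf("<experiment_db> %s (schema %s)\n", x$db_path,
              x$schema_version))
  invisible(x)
}

#' Open an existing experiment database
#'
#' Validates the file's schema (tables present, recognized schema version)
#' and returns a handle usable with [query_frames()], [query_volumes()] and
#' [restore_experiment()].
#'
#' @param db_path Path to a database written by [persist_experiment()].
#' @return An `experiment_db` handle.
#' @export
open_experiment_db <- function(db_path) {
  if (!file.exists(db_path)) {
    stop(sprintf("database file not found: '%s'.", db_path), call. = FALSE)
  }
  con <- db_connect(db_path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  have <- DBI::dbListTables(con)
  missing <- setdiff(DB_TABLES, have)
  if (length(missing) > 0L) {
    stop(sprintf("'%s' is not a valid experiment database: missing table(s) %s.",
                 db_path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  ver <- DBI::dbGetQuery(
    con, "SELECT value FROM options WHERE key = 'schema_version'")$value
  if (length(ver) != 1L || !identical(ver, DB_SCHEMA_VERSION)) {
    stop(sprintf("unknown schema version '%s' in '%s' (this build reads version %s).",
                 if (length(ver) == 1L) ver else "<absent>", db_path,
                 DB_SCHEMA_VERSION), call. = FALSE)
  }
  structure(list(db_path = db_path, schema_version = ver),
            class = "experiment_db")
}

#' Restore an experiment description from its database file
#'
#' Reconstructs the file map, volume map, and every annotation track
#' (including cycle iterations and original segment definitions) from a
#' database written by [persist_experiment()].
#'
#' @param db_path Path to the database file, or an `experiment_db` handle.
#' @return A list with components `file_map`, `volume_map`, `tracks` (named
#'   list of `annotation_track`), and `db` (the `experiment_db` handle).
#' @export
restore_experiment <- function(db_path) {
  db <- if (inherits(db_path, "experiment_db")) db_path else
    open_experiment_db(db_path)
  con <- db_connect(db$db_path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)

  opt <- DBI::dbGetQuery(con, "SELECT key, value FROM options")
  getopt <- function(k) opt$value[opt$key == k]
  n <- as.integer(getopt("n_frames"))
  fpv <- as.integer(getopt("frames_per_volume"))
  head_offset <- as.integer(getopt("head_offset"))

  files <- DBI::dbGetQuery(
    con, "SELECT order_index, path, n_frames FROM files ORDER BY order_index")
  fm <- file_map(files$path, files$n_frames)
  vm <- volume_map(n, fpv, head_offset)

  groups <- DBI::dbGetQuery(
    con, "SELECT group_name, source_kind, cycle_length FROM annotation_groups ORDER BY rowid")
  tracks <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups$group_name[i]
    fl <- DBI::dbGetQuery(con,
      "SELECT frame_id, label_name FROM frame_labels WHERE group_name = ? ORDER BY frame_id",
      params = list(g))
    iter <- NULL
    if (groups$source_kind[i] == "cycle") {
      it <- DBI::dbGetQuery(con,
        "SELECT frame_id, iteration FROM frame_iterations WHERE group_name = ? ORDER BY frame_id",
        params = list(g))
      iter <- as.integer(it$iteration)
    }
    seg_json <- DBI::dbGetQuery(con,
      "SELECT segments_json FROM cycles WHERE group_name = ?",
      params = list(g))$segments_json
    segs <- as.data.frame(jsonlite::fromJSON(seg_json))
    segs$duration <- as.integer(segs$duration)
    labs <- DBI::dbGetQuery(con,
      "SELECT label_name, description FROM labels WHERE group_name = ?",
      params = list(g))
    descr <- NULL
    if (any(!is.na(labs$description))) {
      keep <- !is.na(labs$description)
      descr <- stats::setNames(labs$description[keep], labs$label_name[keep])
    }
    tracks[[g]] <- new_annotation_track(
      group = g,
      per_frame_label = fl$label_name,
      per_frame_iteration = iter,
      source_kind = groups$source_kind[i],
      segments = segs,
      cycle_length = if (is.na(groups$cycle_length[i])) NA_integer_ else
        as.integer(groups$cycle_length[i]),
      descriptions = descr
    )
  }
  list(file_map = fm, volume_map = vm, tracks = tracks, db = db)
}

# Normalize query conditions to a two-column data.frame (group, label),
# deduplicated, preserving first-appearance order. Accepts list of length-2
# vectors, a named character vector (group = label), or a data.frame.
normalize_conditions <- function(conditions) {
  if (is.data.frame(conditions)) {
    stopifnot(ncol(conditions) >= 2L)
    df <- data.frame(group = as.character(conditions[[1]]),
                     label = as.character(conditions[[2]]),
                     stringsAsFactors = FALSE)
  } else if (is.character(conditions) && !is.null(names(conditions))) {
    df <- data.frame(group = names(conditions),
                     label = unname(conditions), stringsAsFactors = FALSE)
  } else if (is.list(conditions)) {
    if (length(conditions) == 0L) {
      stop("at least one (group, label) condition is required; an empty condition list is ambiguous.",
           call. = FALSE)
    }
    ok <- vapply(conditions, function(x) length(x) == 2L, logical(1))
    if (!all(ok)) {
      stop("each condition must be a (group, label) pair.", call. = FALSE)
    }
    df <- data.frame(
      group = vapply(conditions, function(x) as.character(x[[1]]), character(1)),
      label = vapply(conditions, function(x) as.character(x[[2]]), character(1)),
      stringsAsFactors = FALSE
    )
  } else {
    stop("`conditions` must be a list of (group, label) pairs, a named character vector, or a data.frame.",
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("at least one (group, label) condition is required; an empty condition list is ambiguous.",
         call. = FALSE)
  }
  unique(df)
}

check_logic <- function(logic, n_conditions) {
  if (n_conditions >= 2L && (is.null(logic) || length(logic) != 1L)) {
    stop("`logic` ('and' or 'or') is required when combining two or more conditions.",
         call. = FALSE)
  }
  if (is.null(logic)) logic <- "or"
  match.arg(logic, c("and", "or"))
}

check_groups <- function(con, groups) {
  have <- DBI::dbGetQuery(
    con, "SELECT group_name FROM annotation_groups")$group_name
  bad <- setdiff(groups, have)
  if (length(bad) > 0L) {
    stop(sprintf("unknown annotation group(s): %s (available: %s).",
                 paste(bad, collapse = ", "),
                 if (length(have)) paste(sort(have), collapse = ", ") else "<none>"),
         call. = FALSE)
  }
  for (g in unique(groups)) {
    labs <- DBI::dbGetQuery(
      con, "SELECT label_name FROM labels WHERE group_name = ?",
      params = list(g))$label_name
    # unknown labels are a warning, not an error: the condition simply
    # matches no frames, and compound queries degrade gracefully
    invisible(labs)
  }
}

warn_unknown_labels <- function(con, cond) {
  for (i in seq_len(nrow(cond))) {
    labs <- DBI::dbGetQuery(
      con, "SELECT label_name FROM labels WHERE group_name = ?",
      params = list(cond$group[i]))$label_name
    if (!cond$label[i] %in% labs) {
      warning(sprintf("label '%s' is not defined in group '%s' (labels: %s); it matches no frames.",
                      cond$label[i], cond$group[i],
                      paste(sort(labs), collapse = ", ")), call. = FALSE)
    }
  }
}

#' Query the database for frames matching conditions
#'
#' Conditions are (annotation group, label) pairs combined with `"and"`
#' (intersection of the per-condition frame sets) or `"or"` (union). The
#' query is evaluated in SQL against the database file, so it works on a
#' restored experiment even when the image files are absent.
#'
#' Two conditions from the same group under `"and"` intersect like any
#' others; since a frame carries exactly one label per group, the result is
#' empty unless the labels are identical.
#'
#' @param db An `experiment_db` handle (or path to a database file).
#' @param conditions List of `c(group, label)` pairs, a named character
#'   vector (`c(light = "on")`), or a two-column data.frame.
#' @param logic `"and"` or `"or"`; required when two or more conditions are
#'   given.
#' @return Sorted integer vector of 1-based frame ids.
#' @export
query_frames <- function(db, conditions, logic = NULL) {
  if (!inherits(db, "experiment_db")) db <- open_experiment_db(db)
  cond <- normalize_conditions(conditions)
  logic <- check_logic(logic, nrow(cond))
  con <- db_connect(db$db_path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  check_groups(con, cond$group)
  warn_unknown_labels(con, cond)

  clauses <- paste(rep("(group_name = ? AND label_name = ?)", nrow(cond)),
                   collapse = " OR ")
  params <- as.list(as.vector(t(as.matrix(cond))))
  sql <- sprintf(
    "SELECT frame_id FROM frame_labels WHERE %s GROUP BY frame_id%s ORDER BY frame_id",
    clauses,
    if (logic == "and") sprintf(" HAVING COUNT(*) = %d", nrow(cond)) else "")
  as.integer(DBI::dbGetQuery(con, sql, params = params)$frame_id)
}

#' Query the database for full volumes matching conditions
#'
#' A full volume is returned only when *every* one of its frames satisfies
#' the combined condition; partial head/tail volumes are never returned.
#'
#' @inheritParams query_frames
#' @return Sorted integer vector of full-volume codes (0-based).
#' @export
query_volumes <- function(db, conditions, logic = NULL) {
  if (!inherits(db, "experiment_db")) db <- open_experiment_db(db)
  cond <- normalize_conditions(conditions)
  logic <- check_logic(logic, nrow(cond))
  con <- db_connect(db$db_path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  check_groups(con, cond$group)
  warn_unknown_labels(con, cond)

  fpv <- as.integer(DBI::dbGetQuery(
    con, "SELECT value FROM options WHERE key = 'frames_per_volume'")$value)
  clauses <- paste(rep("(group_name = ? AND label_name = ?)", nrow(cond)),
                   collapse = " OR ")
  params <- as.list(as.vector(t(as.matrix(cond))))
  sql <- sprintf(
    "SELECT v.volume_code AS volume_code
       FROM volumes v
       JOIN (SELECT frame_id FROM frame_labels WHERE %s
             GROUP BY frame_id%s) m
         ON v.frame_id = m.frame_id
      WHERE v.volume_code >= 0
      GROUP BY v.volume_code
     HAVING COUNT(*) = %d
      ORDER BY v.volume_code",
    clauses,
    if (logic == "and") sprintf(" HAVING COUNT(*) = %d", nrow(cond)) else "",
    fpv)
  as.integer(DBI::dbGetQuery(con, sql, params = params)$volume_code)
}
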