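# Registry of file-format readers, keyed by lower-case file extension.
# Each entry: list(probe = function(path) -> frame_source fields,
#                  read  = function(source, pages_0based) -> list of matrices)
.format_registry <- new.env(parent = emptyenv())

#' Register a file-format reader
#'
#' The loader layer dispatches on file extension. A format implementation is
#' a pair of functions: `probe_fun(path)` returning a list with `n_pages`,
#' `page_shape` (height, width) and `sample_kind` without decoding pixel
#' data, and `read_fun(source, page_indices)` returning one matrix per
#' requested 0-based page, in the requested order. TIFF support is registered
#' automatically when the package loads; this function is the extension point
#' for additional formats.
#'
#' @param extension File extension including or excluding the leading dot
#'   (case-insensitive), e.g. `".tif"`.
#' @param probe_fun,read_fun The implementation (see Details).
#' @param overwrite Allow replacing an existing registration (default FALSE;
#'   duplicate registration without it is an error).
#' @return Invisibly, the normalized extension.
#' @seealso [probe()], [read_pages()], [registered_formats()]
#' @export
register_format <- function(extension, probe_fun, read_fun,
                            overwrite = FALSE) {
  ext <- normalize_ext(extension)
  if (!is.function(probe_fun) || !is.function(read_fun)) {
    stop("`probe_fun` and `read_fun` must be functions.", call. = FALSE)
  }
  if (!overwrite && !is.null(.format_registry[[ext]])) {
    stop(sprintf("format '%s' is already registered; pass overwrite = TRUE to replace it.",
                 ext), call. = FALSE)
  }
  assign(ext, list(probe = probe_fun, read = read_fun),
         envir = .format_registry)
  invisible(ext)
}

#' Currently registered file extensions
#' @return Character vector of extensions (with leading dot).
#' @export
registered_formats <- function() {
  sort(ls(.format_registry, all.names = TRUE))
}

normalize_ext <- function(extension) {
  ext <- tolower(extension)
  if (!startsWith(ext, ".")) ext <- paste0(".", ext)
  ext
}

lookup_format <- function(path) {
  ext <- normalize_ext(tools::file_ext(path))
  impl <- .format_registry[[ext]]
  if (is.null(impl)) {
    stop(sprintf("unsupported file format '%s' for '%s' (registered: %s).",
                 ext, path, paste(registered_formats(), collapse = ", ")),
         call. = FALSE)
  }
  impl
}

#' Probe an image file without reading pixel data
#'
#' Reads only per-page metadata to report how many 2D pages (frames) a file
#' holds and their shape. This is what lets a recording of many gigabytes be
#' mapped without loading it.
#'
#' @param path Path to an image file with a registered extension.
#' @return An object of class `frame_source` with `path`, `n_pages`,
#'   `page_shape` (height, width) and `sample_kind` (e.g. `"uint16"`).
#' @export
probe <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'.", path), call. = FALSE)
  }
  impl <- lookup_format(path)
  meta <- impl$probe(path)
  structure(
    list(
      path = path,
      n_pages = as.integer(meta$n_pages),
      page_shape = as.integer(meta$page_shape),
      sample_kind = meta$sample_kind
    ),
    class = "frame_source"
  )
}

#' @export
print.frame_source <- function(x, ...) {
  cat(sprintf("<frame_source> %s: %d page(s) of %dx%d %s\n",
              x$path, x$n_pages, x$page_shape[1], x$page_shape[2],
              x$sample_kind))
  invisible(x)
}

#' Read selected pages from an image file
#'
#' Decodes only the requested pages; the rest of the file is untouched, so
#' reading k pages from an n-page file costs O(k) decoding work.
#'
#' @param source A `frame_source` from [probe()].
#' @param page_indices Integer vector of 0-based page indices; order is
#'   preserved in the output and duplicates are allowed.
#' @return A numeric/integer array of shape `(length(page_indices), height,
#'   width)`; pixel values keep the file's scalar type (no rescaling).
#' @export
read_pages <- function(source, page_indices) {
  stopifnot(inherits(source, "frame_source"))
  page_indices <- as.integer(page_indices)
  if (length(page_indices) == 0L) {
    return(array(0, dim = c(0L, source$page_shape)))
  }
  if (anyNA(page_indices) || any(page_indices < 0L) ||
      any(page_indices >= source$n_pages)) {
    stop(sprintf("page indices must lie in [0, %d].", source$n_pages - 1L),
         call. = FALSE)
  }
  impl <- lookup_format(source$path)
  pages <- impl$read(source, page_indices)
  out <- array(pages[[1]][1] * 0L,
               dim = c(length(pages), source$page_shape))
  for (i in seq_along(pages)) out[i, , ] <- pages[[i]]
  out
}

# --- built-in TIFF support (multi-page, grayscale) --------------------------

tiff_probe <- function(path) {
  info <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  if (any(info$samples.per.pixel != 1L)) {
    stop(sprintf("'%s' has multi-sample (e.g. RGB) pages; only single-channel grayscale frames are supported.",
                 path), call. = FALSE)
  }
  if (length(unique(info$width)) != 1L || length(unique(info$length)) != 1L ||
      length(unique(info$bits.per.sample)) != 1L) {
    stop(sprintf("'%s' mixes page shapes or bit depths; all pages in one file must match.",
                 path), call. = FALSE)
  }
  bits <- info$bits.per.sample[1]
  kind <- if (!is.null(info$sample.format) &&
              any(info$sample.format == "float")) {
    sprintf("float%d", bits)
  } else {
    sprintf("uint%d", bits)
  }
  list(
    n_pages = nrow(info),
    page_shape = c(info$length[1], info$width[1]),  # (height, width)
    sample_kind = kind
  )
}

tiff_read <- function(source, page_indices) {
  # readTIFF decodes only the directories named in `all`; read each wanted
  # page once and fan duplicates out afterwards.
  wanted <- sort(unique(page_indices)) + 1L            # 1-based for readTIFF
  pages <- tiff::readTIFF(source$path, all = wanted, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  pages[match(page_indices + 1L, wanted)]
}

register_builtin_formats <- function() {
  for (ext in c(".tif", ".tiff")) {
    register_format(ext, tiff_probe, tiff_read, overwrite = TRUE)
  }
}

.onLoad <- function(libname, pkgname) {
  register_builtin_formats()
}
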