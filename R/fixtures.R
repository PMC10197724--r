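#' Specification of the built-in toy recording
#'
#' A small, fully synthetic recording used throughout the documentation and
#' test-suite: 42 frames split over three multi-page TIFF files, acquired as
#' volumes of 10 frames (4 full volumes plus 2 trailing frames), with three
#' annotation groups — a `light` timeline (off for 25 frames, then on for
#' 17), a `label` cycle (c1 x10, c2 x10, c3 x20, repeating) and a `shape`
#' cycle (circle x8, square x8, repeating; note that the shape switches in
#' the middle of a volume).
#'
#' Every value is configuration: change a field and [generate_toy_dataset()]
#' and [canonical_experiment()] follow.
#'
#' @return A list with `n_frames`, `file_split`, `frames_per_volume`,
#'   `page_shape`, and `annotations` (list of [cycle()] / [timeline()]).
#' @export
toy_spec <- function() {
  list(
    n_frames = 42L,
    file_split = c(13L, 13L, 16L),
    frames_per_volume = 10L,
    page_shape = c(16L, 16L),
    annotations = list(
      timeline("light", c(off = 25L, on = 17L)),
      cycle("label", c(c1 = 10L, c2 = 10L, c3 = 20L)),
      cycle("shape", c(circle = 8L, square = 8L))
    )
  )
}

#' Generate the toy recording on disk
#'
#' Writes the recording described by `spec` as multi-page grayscale 16-bit
#' TIFF files named `movie_00.tif`, `movie_01.tif`, ... The page for global
#' frame `f` has every pixel equal to `f` (frame-number encoding), so loaded
#' pixel content is machine-checkable: slice 3 of a loaded stack must be a
#' constant image whose value names its source frame.
#'
#' Generation is deterministic: the same `spec` and `seed` always produce
#' byte-identical files.
#'
#' @param out_dir Directory to write into (created if needed).
#' @param spec A [toy_spec()]-shaped list.
#' @param seed Integer seed; the default frame-number encoding is itself
#'   deterministic, but the seed is fixed anyway so variants of the
#'   generator that add noise stay reproducible.
#' @return Character vector of written file paths, invisibly.
#' @export
generate_toy_dataset <- function(out_dir, spec = toy_spec(), seed = 1L) {
  if (sum(spec$file_split) != spec$n_frames) {
    stop(sprintf("file_split sums to %d but n_frames is %d.",
                 sum(spec$file_split), spec$n_frames), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory '%s'.", out_dir),
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  paths <- file.path(out_dir, sprintf("movie_%02d.tif",
                                      seq_along(spec$file_split) - 1L))
  frame <- 0L
  for (i in seq_along(spec$file_split)) {
    pages <- lapply(seq_len(spec$file_split[i]), function(j) {
      # writeTIFF takes values in [0, 1]; 16-bit quantization maps
      # f/65535 back to the integer f exactly
      matrix((frame + j) / 65535, spec$page_shape[1], spec$page_shape[2])
    })
    tiff::writeTIFF(pages, paths[i], bits.per.sample = 16L,
                    compression = "none")
    frame <- frame + spec$file_split[i]
  }
  invisible(paths)
}

#' The toy experiment, mapped and annotated
#'
#' Generates the toy recording in `out_dir` (unless its files are already
#' there) and returns the fully mapped [experiment()] with the three
#' canonical annotation groups attached.
#'
#' @param out_dir Directory for the TIFF files.
#' @param spec A [toy_spec()]-shaped list.
#' @param verbose Passed to [experiment()].
#' @return An `experiment`.
#' @examples
#' ex <- canonical_experiment(file.path(tempdir(), "toy"), verbose = FALSE)
#' suppressMessages(choose_volumes(ex, list(c("label", "c3"),
#'                                          c("light", "on")), "and"))  # 3
#' @export
canonical_experiment <- function(out_dir, spec = toy_spec(), verbose = TRUE) {
  expected <- file.path(out_dir, sprintf("movie_%02d.tif",
                                         seq_along(spec$file_split) - 1L))
  if (!all(file.exists(expected))) {
    generate_toy_dataset(out_dir, spec)
  }
  experiment(
    files = expected,
    frames_per_volume = spec$frames_per_volume,
    annotations = spec$annotations,
    verbose = verbose
  )
}
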