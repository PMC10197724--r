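# Independent brute-force oracles. These deliberately use sequential walks
# and literal tiling rather than the arithmetic the package uses, so the two
# routes can disagree if either is wrong.

# Walk the recording frame by frame, filling volumes of `fpv` slices after
# skipping `head` frames; whatever completes is a full volume, the rest is
# head (-1) / tail (-2). Head frames are the trailing slices of the
# truncated first volume; tail slices restart at 0.
oracle_volume_map <- function(n, fpv, head = 0L) {
  code <- integer(n)
  slice <- integer(n)
  for (f in seq_len(min(head, n))) {
    code[f] <- -1L
    slice[f] <- fpv - head + f - 1L
  }
  f <- head + 1L
  v <- 0L
  while (f + fpv - 1L <= n) {
    for (s in 0:(fpv - 1L)) {
      code[f] <- v
      slice[f] <- s
      f <- f + 1L
    }
    v <- v + 1L
  }
  s <- 0L
  while (f <= n) {
    code[f] <- -2L
    slice[f] <- s
    s <- s + 1L
    f <- f + 1L
  }
  list(code = code, slice = slice, n_full = v)
}

# Literal tiling: repeat the expanded segment list until it covers n frames,
# then truncate.
oracle_tile_cycle <- function(segments, n) {
  one <- rep(names(segments), times = segments)
  reps <- ceiling(n / length(one))
  list(
    labels = rep(one, reps)[seq_len(n)],
    iterations = rep(seq_len(reps) - 1L, each = length(one))[seq_len(n)]
  )
}

# Frame-by-frame condition evaluation over per-frame label vectors.
# `tracks` is a named list of character vectors; `conditions` a list of
# c(group, label) pairs.
oracle_query_frames <- function(tracks, conditions, logic) {
  n <- length(tracks[[1]])
  hits <- integer(0)
  for (f in seq_len(n)) {
    m <- vapply(conditions, function(cnd) {
      tracks[[cnd[[1]]]][f] == cnd[[2]]
    }, logical(1))
    ok <- if (logic == "and") all(m) else any(m)
    if (ok) hits <- c(hits, f)
  }
  hits
}

# A full volume is selected iff every one of its frames was selected.
oracle_query_volumes <- function(frame_hits, vol_codes) {
  out <- integer(0)
  for (v in sort(unique(vol_codes[vol_codes >= 0L]))) {
    members <- which(vol_codes == v)
    if (all(members %in% frame_hits)) out <- c(out, v)
  }
  out
}

# Shared toy fixture on disk, generated once per test run.
toy_dir <- function() {
  d <- file.path(tempdir(), "voltime-toy-fixture")
  if (!dir.exists(d)) generate_toy_dataset(d)
  d
}

toy_experiment <- function() {
  canonical_experiment(toy_dir(), verbose = FALSE)
}

# Per-frame label vectors of the toy annotations, built by the oracles (not
# by expand_cycle/expand_timeline).
toy_oracle_tracks <- function(n = 42L) {
  list(
    light = rep(c("off", "on"), times = c(25L, 17L))[seq_len(n)],
    label = oracle_tile_cycle(c(c1 = 10L, c2 = 10L, c3 = 20L), n)$labels,
    shape = oracle_tile_cycle(c(circle = 8L, square = 8L), n)$labels
  )
}
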