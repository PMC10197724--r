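test_that("experiment maps the toy directory: files, volumes, tail frames", {
  ex <- toy_experiment()
  expect_identical(nrow(ex$file_map$files), 3L)
  expect_identical(ex$file_map$total_frames, 42L)
  expect_identical(ex$volume_map$n_full_volumes, 4L)
  expect_identical(sum(ex$volume_map$per_frame_volume == -2L), 2L)
  expect_identical(names(ex$tracks), c("light", "label", "shape"))
})

test_that("a single exactly-divided file maps to one full volume", {
  d <- tempfile()
  spec <- toy_spec()
  spec$n_frames <- 10L
  spec$file_split <- 10L
  spec$annotations <- list()
  generate_toy_dataset(d, spec)
  ex <- experiment(data_dir = d, frames_per_volume = 10, verbose = FALSE)
  expect_identical(ex$volume_map$n_full_volumes, 1L)
  expect_identical(sum(ex$volume_map$per_frame_volume < 0L), 0L)
})

test_that("creation aborts when an annotation does not cover the recording", {
  expect_error(
    experiment(data_dir = toy_dir(), frames_per_volume = 10, verbose = FALSE,
               annotations = list(timeline("light", c(off = 25L, on = 16L)))),
    "light.*41.*42")
})

test_that("choose_frames matches the per-condition oracle on the toy data", {
  ex <- toy_experiment()
  ora <- toy_oracle_tracks()
  sq <- suppressMessages(choose_frames(ex, list(c("shape", "square"))))
  expect_identical(sq, c(9:16, 25:32, 41:42))
  expect_identical(sq, which(ora$shape == "square"))
  expect_identical(
    suppressMessages(choose_frames(ex, list(c("light", "on"),
                                            c("light", "off")), "or")),
    1:42)
  expect_error(suppressMessages(choose_frames(ex, list())), "ambiguous")
})

test_that("choose_volumes reproduces the canonical and/or query answers", {
  ex <- toy_experiment()
  conds <- list(c("label", "c3"), c("light", "on"))
  expect_identical(suppressMessages(choose_volumes(ex, conds, "and")), 3L)
  expect_identical(suppressMessages(choose_volumes(ex, conds, "or")),
                   c(2L, 3L))
  # the shape cycle switches mid-volume: no full volume is all-square
  expect_identical(
    suppressMessages(choose_volumes(ex, list(c("shape", "square")), "and")),
    integer(0))
})

test_that("in-memory and database query paths agree exhaustively on the toy data", {
  ex_mem <- toy_experiment()
  ex_db <- save_experiment(ex_mem, tempfile(fileext = ".db"))
  labels <- list(light = c("off", "on"), label = c("c1", "c2", "c3"),
                 shape = c("circle", "square"))
  pairs <- list()
  for (g in names(labels)) for (l in labels[[g]]) {
    pairs[[length(pairs) + 1L]] <- c(g, l)
  }
  for (i in seq_along(pairs)) {
    for (j in seq_along(pairs)) {
      for (logic in c("and", "or")) {
        conds <- list(pairs[[i]], pairs[[j]])
        expect_identical(
          suppressMessages(choose_frames(ex_mem, conds, logic)),
          suppressMessages(choose_frames(ex_db, conds, logic)),
          info = sprintf("frames %s-%s %s", i, j, logic))
        expect_identical(
          suppressMessages(choose_volumes(ex_mem, conds, logic)),
          suppressMessages(choose_volumes(ex_db, conds, logic)),
          info = sprintf("volumes %s-%s %s", i, j, logic))
      }
    }
  }
})

test_that("choose_volumes under 'and' is monotone in its conditions", {
  ex <- toy_experiment()
  conds <- list(c("label", "c3"), c("light", "on"))
  both <- suppressMessages(choose_volumes(ex, conds, "and"))
  for (cnd in conds) {
    single <- suppressMessages(choose_volumes(ex, list(cnd), "or"))
    expect_true(all(both %in% single))
  }
})

test_that("load_frames keeps caller order across file boundaries", {
  ex <- toy_experiment()
  x <- load_frames(ex, c(13L, 14L))  # spans files 1 -> 2
  expect_identical(dim(x), c(2L, 16L, 16L))
  expect_identical(as.vector(x[, 1, 1]), c(13L, 14L))
  one <- load_frames(ex, 1L)
  expect_identical(unique(as.vector(one)), 1L)
  on_frames <- suppressMessages(choose_frames(ex, list(c("light", "on"))))
  expect_identical(dim(load_frames(ex, on_frames))[1], 17L)
})

test_that("load_volumes stacks 4D volumes whose content is the encoded frame numbers", {
  ex <- toy_experiment()
  v3 <- load_volumes(ex, 3L)
  expect_identical(dim(v3), c(1L, 10L, 16L, 16L))
  expect_identical(as.vector(v3[1, , 1, 1]), 31:40)
  v23 <- load_volumes(ex, c(2L, 3L))
  expect_identical(dim(v23), c(2L, 10L, 16L, 16L))
  expect_identical(as.vector(v23[1, , 1, 1]), 21:30)
  expect_identical(as.vector(v23[2, , 1, 1]), 31:40)
  empty <- load_volumes(ex, integer(0))
  expect_identical(dim(empty), c(0L, 10L, 16L, 16L))
})

test_that("partial volumes load only behind the explicit flag, as a per-code list", {
  ex <- toy_experiment()
  expect_error(load_volumes(ex, c(3L, -2L)), "allow_partial")
  parts <- load_volumes(ex, c(3L, -2L), allow_partial = TRUE)
  expect_identical(length(parts), 2L)
  expect_identical(dim(parts[[1]]), c(10L, 16L, 16L))
  expect_identical(dim(parts[[2]]), c(2L, 16L, 16L))
  expect_identical(as.vector(parts[[2]][, 1, 1]), 41:42)
})

test_that("every full volume loads identically via volumes and via its frames", {
  ex <- toy_experiment()
  for (v in full_volume_codes(ex$volume_map)) {
    via_vol <- load_volumes(ex, v)
    via_frames <- load_frames(ex, frames_of_volumes(ex$volume_map, v))
    expect_identical(via_vol[1, , , ], via_frames, info = sprintf("volume %d", v))
  }
})

test_that("describe summarizes groups with conserved frame counts", {
  ex <- toy_experiment()
  s <- describe(ex)
  expect_identical(s$n_full_volumes, 4L)
  expect_identical(s$n_tail_frames, 2L)
  expect_identical(length(s$groups), 3L)
  expect_identical(s$groups$light$label_counts, c(off = 25L, on = 17L))
  for (g in s$groups) expect_identical(sum(g$label_counts), 42L)

  bare <- experiment(data_dir = toy_dir(), frames_per_volume = 10,
                     verbose = FALSE)
  expect_identical(length(describe(bare)$groups), 0L)
})

test_that("frame_report assembles the complete frame-30 story", {
  rep30 <- frame_report(toy_experiment(), 30)
  expect_identical(rep30$file_order, 2L)     # 3rd file
  expect_identical(rep30$page_index, 3L)     # 4th page
  expect_identical(rep30$volume_code, 2L)    # 3rd volume
  expect_identical(rep30$slice_index, 9L)    # last slice, 0-based
  expect_identical(rep30$labels$shape$label, "square")
  expect_identical(rep30$labels$shape$iteration_ordinal, "2nd")
  expect_identical(rep30$labels$label$label, "c3")
  expect_identical(rep30$labels$label$iteration_ordinal, "1st")
  expect_identical(rep30$labels$light$label, "on")
})

test_that("a YAML config reproduces the programmatic experiment", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(sprintf("
data_dir: %s
frames_per_volume: 10
head_offset: 0
annotations:
  light:
    kind: timeline
    segments: [{off: 25}, {on: 17}]
  label:
    kind: cycle
    segments: [{c1: 10}, {c2: 10}, {c3: 20}]
  shape:
    kind: cycle
    segments: [{circle: 8}, {square: 8}]
", toy_dir()), cfg)
  ex <- experiment_from_yaml(cfg, verbose = FALSE)
  ref <- toy_experiment()
  for (g in names(ref$tracks)) {
    expect_identical(ex$tracks[[g]]$per_frame_label,
                     ref$tracks[[g]]$per_frame_label, info = g)
  }
  expect_identical(
    suppressMessages(choose_volumes(ex, list(c("label", "c3"),
                                             c("light", "on")), "and")), 3L)
})

test_that("a saved experiment reopens fully functional from the database alone", {
  dbp <- tempfile(fileext = ".db")
  save_experiment(toy_experiment(), dbp)
  back <- load_experiment(dbp)
  conds <- list(c("label", "c3"), c("light", "on"))
  expect_identical(suppressMessages(choose_volumes(back, conds, "and")), 3L)
  expect_identical(suppressMessages(choose_volumes(back, conds, "or")),
                   c(2L, 3L))
  # pixel data still reachable because the files are where the db says
  expect_identical(unique(as.vector(load_frames(back, 30L))), 30L)
})
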