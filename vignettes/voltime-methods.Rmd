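---
title: "Mapping and querying volumetric imaging recordings with voltime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and querying volumetric imaging recordings with voltime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Volumetric functional imaging (light-sheet or two-photon calcium imaging of
a whole brain, for instance) acquires one continuous stream of 2D frames:
the microscope sweeps through depth, so every `frames_per_volume`
consecutive frames assemble into one 3D volume, and the stream is written
out as a series of multi-page TIFF files whose boundaries have nothing to do
with volume boundaries. Analysing such a recording requires three mappings
that are tedious and error-prone to maintain by hand:

1. **storage** — which file and which page within it holds global frame *f*;
2. **geometry** — which volume and which depth slice frame *f* belongs to;
3. **conditions** — which stimulus / behavioral / experimental labels were
   active while frame *f* was acquired, and, for repeating stimuli, which
   repetition ("iteration") the recording was in.

voltime builds all three once, stores them in a single SQLite file, and then
answers condition queries and loads the matching pixel data lazily. The
deliberate split into *map once, query many times* means the expensive and
failure-prone bookkeeping is done (and persisted, and shareable) exactly
once per recording.

## Index conventions

These conventions are the only set consistent with all the bookkeeping facts
the toy recording asserts (see below), and they are applied everywhere:

* **Global frames are 1-based**: "frame number 30" is the 30th acquired
  frame.
* **Pages within a file and slices within a volume are 0-based**: frame 30
  of the toy recording is page 3 of its file and slice 9 of its volume.
* **Full volumes are 0-based codes `0, 1, 2, ...`**; the ordinal "3rd
  volume" is code 2. Two sentinel codes mark frames outside any full
  volume: `-1` for *head* frames acquired before the first complete volume
  and `-2` for *tail* frames after the last one.
* **Cycle iterations are 0-based** internally and rendered ordinally in
  reports (`iteration 1` prints as "2nd").

### Partial volumes

`head_offset` exists because real acquisitions often start mid-volume; the
toy recording uses 0. Head frames are interpreted as the trailing slices of
a truncated first volume, so with `frames_per_volume = 10` and
`head_offset = 3` the first three frames get slice indices 7, 8, 9. Tail
frames are the opening slices of an unfinished volume and restart at slice
0. Only full volumes are ever returned by volume queries or stacked by
`load_volumes()` (partial codes load behind an explicit `allow_partial`
flag, as a list, because their slice depth differs).

## Annotations: cycles vs timelines

An annotation *group* is one condition dimension (light, stimulus identity,
shape, ...) whose labels partition the frames. Two declaration forms exist,
and they deliberately have different validation rules:

* A **timeline** lists labeled durations that must sum to the total frame
  count *exactly*; it is never repeated or truncated. Use it when you know
  the whole recording's course (e.g. `light: off x25, on x17`).
* A **cycle** lists one period of a repeating pattern; it is tiled from
  frame 1 to the end of the recording, truncating the final repetition
  mid-segment if necessary, and every frame additionally records its
  0-based iteration number. Iteration tracking matters when the subject
  habituates to or learns from a repeated stimulus. A cycle longer than
  the recording is accepted and yields a single truncated iteration.

Cycles are anchored at frame 1 (no phase parameter): a phase offset is
expressible as a leading segment, and an explicit leading segment is
self-documenting where a numeric phase is not.

Frame `f` of a cycle of length `L` gets the label at within-cycle position
`(f-1) mod L` and iteration `(f-1) div L`.

## Querying

Conditions are `(group, label)` pairs combined with `and` (intersection of
the per-condition frame sets) or `or` (union). Frame queries return every
matching frame. Volume queries return a full volume only when **all** of
its frames match — a stimulus that switches mid-volume therefore selects
frames but possibly no volume, which is intended behavior, not a defect
(work at frame level there). Edge cases are resolved as follows:

* An **empty condition list is an error**, not "all frames": a silent
  select-all is a foot-gun in analysis code.
* `logic` is **required** once two or more conditions are combined; for a
  single condition both logics coincide and it may be omitted.
* An **unknown group is an error** (listing the available groups); an
  **unknown label in a known group is a warning** and matches no frames, so
  a compound `or` query degrades gracefully while a typo stays visible.
* Two conditions from the same group under `and` intersect like any
  others; since each frame carries exactly one label per group, the result
  is empty unless the labels are identical. This is documented rather than
  special-cased.

When the experiment has a database attached the query is evaluated in SQL
(`GROUP BY frame_id HAVING COUNT(*) = n` for intersections, a join against
the volume table with `HAVING COUNT(*) = frames_per_volume` for
full-volume coverage); without one, an equivalent in-memory evaluation over
the expanded tracks is used. The test-suite checks the two paths agree
exhaustively on the toy fixture, and checks both against an independent
frame-by-frame brute-force evaluator.

## Persistence

`save_experiment()` writes everything — file map, volume map, per-frame
labels and iterations, segment definitions, and scalar options including a
schema version — into one SQLite file. Design choices:

* Queries run **against the file**, not against in-memory state, so a
  restored experiment is fully functional without the image files; only
  pixel loading touches TIFFs.
* The schema version is stored from day one and an unrecognized version
  fails loudly; a best-effort parse of an unknown schema risks silently
  wrong science. Interoperability with databases written by other tools is
  not claimed.
* Logical content is the contract, not byte layout: the round-trip test
  compares row sets, and restoring preserves annotation-group insertion
  order.

## Lazy loading

`probe()` reads only per-page TIFF metadata (page count, shape, bit depth),
so mapping a recording never decodes pixels. `read_pages()` decodes exactly
the requested pages; the loader test registers a spy format to assert that
pages outside a request never reach a decoder. Only single-channel
grayscale pages are supported — functional imaging frames are
single-channel, and rejecting RGB outright avoids silent channel-mixing —
and the pixel scalar type is preserved end-to-end (`as.is` reads, no
rescaling). Formats are dispatched by file extension through a registry
(`register_format()`), which is the extension point for OME-TIFF or HDF5
readers later; duplicate registration without an explicit overwrite flag is
an error.

When several files are discovered in a directory their order defaults to a
lexicographic sort of file names — reproducible, and correct for the
zero-padded numbering acquisition software emits — and an explicit
user-supplied file list always overrides it.

## The toy recording

`toy_spec()` describes a 42-frame recording in three TIFF files (13, 13,
16 pages) at 10 frames per volume — 4 full volumes plus 2 tail frames —
with three annotation groups: a `light` timeline (`off x25, on x17`), a
`label` cycle (`c1 x10, c2 x10, c3 x20`) and a `shape` cycle
(`circle x8, square x8`), the latter switching mid-volume on purpose. Under
these parameters the recording satisfies, all at once: frame 30 is the 4th
page of the 3rd file, slice 9 (0-based) of the 3rd volume, labeled square /
c3 / light-on, in the 2nd shape iteration and 1st label iteration; the
query `label=c3 AND light=on` selects exactly volume 3, and
`label=c3 OR light=on` exactly volumes 2 and 3. The file split and segment
durations are configuration, not hard-coded truths — they were chosen as
the minimal-complexity values satisfying those facts, and a dedicated
consistency test re-derives every fact from the generated data.

Pages encode their own 1-based global frame number as a constant pixel
value (16-bit, so the quantization `f/65535` round-trips exactly). A
constant-valued page is machine-checkable — every pixel-loading test can
assert content, not just shape — which is worth more in a fixture than
visual fidelity; the generator makes no attempt to emulate optics, noise,
or actual neural signal, so passing tests demonstrate correct bookkeeping
and retrieval, not robustness to real imaging artifacts.

## Problem sizes and determinism

All tests run at desk scale: the toy recording (42 frames of 16x16
pixels), randomized property checks up to 500 frames and 50
frames-per-volume with 20–30 replicates under fixed seeds, and the
exhaustive query-path comparison over all 7x7 label pairs and both logics.
These sizes already exercise every boundary (file splits, truncated
cycles, head/tail frames) while keeping the whole suite fast. The
toy generator is fully deterministic: identical spec and seed produce
byte-identical files.

## Known limitations

* Only plain multi-page grayscale TIFF is read natively; BigTIFF/tiled
  dialects work only insofar as the underlying TIFF reader parses them.
* One experiment per database file; no concurrent writers.
* Annotations must be supplied as segment lists; deriving them from rig
  logs or behavioral tracking output is out of scope.
* No pixel processing (registration, motion correction, dF/F): voltime
  ends where analysis begins, handing over plain arrays.
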