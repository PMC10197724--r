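# voltime

Time annotation and retrieval for volumetric functional-imaging recordings.

Volumetric functional imaging (light-sheet / two-photon calcium imaging)
acquires one continuous stream of 2D frames; every `frames_per_volume`
consecutive frames form a 3D volume, and the stream is split across
multi-page TIFF files whose boundaries ignore volume boundaries. Correct
analysis needs, for every frame *f*, three pieces of bookkeeping:

* **storage** — the file and 0-based page holding frame *f*
  (`page = f − 1 − offset(file)`);
* **geometry** — its volume and depth slice
  (`volume = ⌊(f−1)/fpv⌋`, `slice = (f−1) mod fpv`, with partial
  head/tail frames coded `−1`/`−2`);
* **conditions** — the label each annotation group assigned while *f* was
  acquired, and for repeating stimulus cycles of length *L* the iteration
  `⌊(f−1)/L⌋`.

voltime builds these maps once, persists them to a single SQLite file, and
then returns the frames or full volumes matching arbitrary `and`/`or`
combinations of conditions — decoding only the TIFF pages it needs. A full
volume is returned only when *all* of its frames match. Audience: anyone
wrangling long functional-imaging recordings who wants the
stimulus-to-frame bookkeeping out of notebooks and into one queryable,
shareable file.

## Worked example

The package ships a deterministic toy recording: 42 frames in three TIFF
files (13/13/16 pages), 10 frames per volume (4 full volumes + 2 tail
frames), three annotation groups, and pages whose constant pixel value is
their own global frame number.

```r
library(voltime)

ex <- canonical_experiment("toy_dir")   # generates the TIFFs, then maps them
#> mapped 3 file(s), 42 frames: 4 full volume(s) of 10 frame(s),
#> 0 head + 2 tail frame(s), 3 annotation group(s)

describe(ex)
#> 3 file(s), 42 frames, 10 per volume: 4 full volume(s), 0 head, 2 tail
#>   light (timeline): off=25, on=17
#>   label (cycle, cycle length 40): c1=12, c2=10, c3=20
#>   shape (cycle, cycle length 16): circle=24, square=18

str(frame_report(ex, 30)[c("file_order", "page_index",
                           "volume_code", "slice_index")])
#> List of 4
#>  $ file_order : int 2     # 3rd file ...
#>  $ page_index : int 3     # ... 4th page in it
#>  $ volume_code: int 2     # 3rd volume ...
#>  $ slice_index: int 9     # ... last slice (0-based)

ex <- save_experiment(ex, "toy.db")     # queries now run in SQL

conds <- list(c("label", "c3"), c("light", "on"))
choose_volumes(ex, conds, "and")
#> query volumes: label=c3, light=on [and] -> 1 hit(s)
#> [1] 3
choose_volumes(ex, conds, "or")
#> query volumes: label=c3, light=on [or] -> 2 hit(s)
#> [1] 2 3

v <- load_volumes(ex, 3)                # shape (1, 10, 16, 16)
unique(as.vector(v[1, 1, , ]))
#> [1] 31                                # slice 0 of volume 3 is frame 31
```

Volume 3 (frames 31–40) is the only full volume entirely inside both
`c3` (frames 21–40) and `light on` (frames 26–42); the union additionally
covers volume 2 (frames 21–30). The `shape` cycle switches mid-volume, so
`choose_volumes(ex, list(c("shape", "square")))` is empty while
`choose_frames()` returns its 18 frames — by design.

The same pipeline is scriptable from a shell via
`system.file("cli", "voltime.R", package = "voltime")`
(subcommands `make-toy`, `init`, `describe`, `query`, `export`).

## Documentation

`vignettes/voltime-methods.Rmd` documents the index conventions
(1-based frames, 0-based pages/slices/volumes/iterations), the
cycle/timeline semantics, partial-volume handling, the SQLite schema
contract, and the toy recording's construction.
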