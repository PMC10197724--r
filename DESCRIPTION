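Package: voltime
Title: Time Annotation and Retrieval for Volumetric Functional Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Synchronizes time annotations (stimuli, behaviors, experimental
    conditions, repeating stimulus cycles) with volumetric functional-imaging
    time series stored as multi-page TIFF files. Maps every acquired 2D frame
    to its storage location (file, page) and its volumetric position (volume,
    slice), expands repeating cycles and exact timelines into per-frame label
    and iteration assignments, persists the complete experiment description to
    a single SQLite database file, and retrieves frames or full volumes
    matching arbitrary and/or combinations of conditions without loading the
    whole dataset into memory. Includes a deterministic toy-dataset generator
    so the full pipeline can be exercised without external data, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    jsonlite,
    tiff,
    tools,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
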