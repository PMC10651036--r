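Package: grayscape
Title: Gray-Level Landscape Pattern Metrics on Raster Maps
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes 51 first- and second-order landscape pattern metrics
    from gray-level frequency and gray-level adjacency (co-occurrence)
    tabulations on categorical or quantized-numeric raster maps with integer
    values in [0, 100]. Supports moving-window analysis producing a
    continuous metric map at the input resolution, global whole-extent
    analysis producing a single value, and a multi-scale scalogram driver.
    Includes ternary landscape-mosaic classifiers, a synthetic raster
    generator, an independent brute-force oracle for verification, 8-bit and
    32-bit float TIFF input/output, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    optparse,
    tiff,
    grDevices,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
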