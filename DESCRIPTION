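Package: cmapscreen
Title: Target-Gene Drug-Repurposing Screens on L1000 Level-5 Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for in-silico drug-repurposing screens that rank
    small-molecule perturbagens by their ability to shift a single target
    gene's expression in Connectivity-Map-style L1000 level-5 signature
    data. Reads and writes the GCTX (HDF5) and GCT text matrix formats and
    the tab-separated signature/gene metadata dialects, filters signatures
    by perturbagen type, pools replicate signatures per compound, tests
    each compound's mean differential expression against the plate-control
    baseline, and emits a ranked, curated candidate table. A synthetic
    signature generator with planted effects supports calibration and
    power analysis of the screen without the multi-gigabyte reference
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
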