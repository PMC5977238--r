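Package: SaltoMap
Title: Mapping and Analysis of Transposable Phage Integration Sites from
    Virion Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating and characterising the replicative
    transposition sites of Mu-like transposable phages (saltoviruses) from
    virion DNA sequencing. Virion chromosomes carry host DNA at both ends of
    the packaged phage genome, so sequencing reads that span a phage-host
    junction pinpoint individual integration events at base-pair resolution.
    The package extracts and filters junction reads, places the trimmed host
    fragments on a reference genome, tallies per-position integration counts,
    compares observed coincidence spectra with a closed-form random-placement
    model, calls insertion hotspots and derives the adjacent degenerate
    consensus motif, detects low-GC coldspots, and analyses the rare
    self-insertion events that reveal the domain and loop organisation of the
    phage chromosome. A synthetic virion-read generator with ground-truth
    event tables makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
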