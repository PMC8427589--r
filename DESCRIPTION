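Package: alongshore
Title: Along-Shore Spatial Structure of Intertidal Abundance Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the along-shore spatial organisation of
    abundance in coastal survey data, built around timed-search
    catch-per-unit-effort (CPUE) estimates of intertidal invertebrates such
    as sea urchins. Provides bias filters for search duration and tidal
    height, observer-concordance checks, along-shore coastline projection,
    global Moran's I and empirical variograms, Morlet continuous-wavelet
    detection of dominant spatial scales with surrogate-based significance,
    a sliding-window scan correlating abundance with upstream and downstream
    rocky-habitat amount under Benjamini-Hochberg false-discovery control,
    and pairwise species co-occurrence correlations within sympatric ranges.
    A synthetic coastal-survey generator with configurable periodic
    abundance structure, habitat coupling and observer effects makes every
    stage testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
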