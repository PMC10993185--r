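Package: gazenet
Title: Gaze-Based Attention Networks from Head-Mounted Eye Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses gaze-based attention networks from
    head-mounted (VR) eye-tracking logs. Provides an analytic gaze-ray
    caster that turns local eye-tracker gaze directions into world-frame
    rays and resolves the first object of interest (OOI) hit, preprocessing
    that aggregates per-frame gaze targets into gaze-transition tables,
    construction of weighted directed attention networks, and the
    structural variables used to describe them: node strength, Candeloro
    weighted degree centrality, a chi-square gaze-uniformity index, cut
    sizes over node partitions, and maximal-clique summaries. A synthetic
    session generator with a Markov attention process provides
    ground-truthed data for validation without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
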