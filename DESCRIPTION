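Package: FluorNet
Title: Simulated Neural Calcium Fluorescence and Bibliometric Activity Movies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates networks of excitatory leaky integrate-and-fire
    neurons with short-term synaptic depression, converts their spike
    rasters into calcium-fluorescence imaging movies with indicator
    saturation, Gaussian noise and light scattering, and builds analogous
    activity movies from publication and patent keyword dynamics
    (yearly keyword counts, co-occurrence-gated Pearson correlation,
    ranking and spatial layout). The two kinds of movies are compared
    with the Earth Mover's Distance, computed by an exact
    transportation-simplex solver, and directed functional connectivity
    is estimated with plug-in transfer entropy on differenced
    fluorescence series. A synthetic-corpus generator with planted
    correlated keyword pairs makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    igraph,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
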