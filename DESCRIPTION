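Package: alderfix
Title: Symbiotic Nitrogen Fixation Fluxes and Landscape Nitrogen Cycling in
    Alder Shrub Tundra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating landscape nitrogen inputs from symbiotic
    fixation by alder (Alnus viridis) in tundra ecosystems. Converts 15N2
    nodule incubations into per-nodule fixation rates, estimates nodule
    biomass density from gridded and bullseye soil-core plot designs, scales
    peak-season area fluxes to annual fluxes through a seasonal step
    function, classifies shrubland cover from multi-band raster stacks by
    unsupervised k-means clustering, fits seasonal negative-exponential
    distance-decay models of resin-captured soil inorganic nitrogen with
    likelihood-ratio/AIC model selection and bootstrap confidence intervals,
    derives area-basis leaf chemistry and nutrient resorption efficiencies
    with bootstrap principal-component ordination, and provides synthetic
    generators for every input stream so the full pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
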