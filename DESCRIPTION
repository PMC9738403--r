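Package: medaccess
Title: Multimodal Transport Accessibility of Medical Facilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the spatial accessibility of medical facilities
    (tertiary hospitals down to pharmacies) through a multimodal travel-time
    network that combines walking, bus and rail, with stations as transfer
    points and a fixed dwell impedance per stop. Computes isochrone service
    areas at configurable time thresholds, district-level service-area and
    service-population ratios, and the classical point-pattern statistics
    used to characterise facility layouts: the Clark-Evans nearest-neighbour
    ratio, quartic kernel density surfaces, the mean centre and the standard
    deviational ellipse. Includes a synthetic-city generator (clustered
    facility point processes, grid walk network, transit corridors,
    multi-centre population raster, Voronoi districts) so the whole pipeline
    is reproducible without proprietary map data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
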