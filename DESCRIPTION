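Package: olfactomap
Title: Current Source Density Mapping of Insect Antennal Olfactory Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Localizes odor-evoked activity along the insect antennal
    funiculus from electroantennogram (EAG) recordings made at multiple
    proximo-distal positions. Builds a forward model of surface potentials
    generated by rectangular current sources on the virtually unfolded
    funiculus surface, inverts it to estimate compartmental current source
    densities (CSD), and summarizes responses as per-compartment areas and
    spatial barycenters. Companion tools turn scanning-electron-microscopy
    sensilla annotations into kernel density maps, dominance-index profiles
    and count summaries, and compare species through a bootstrap
    between/within distance-ratio test plus discriminant and
    principal-component projections. A synthetic-data generator produces
    ground-truth-known EAG cohorts and sensilla point patterns so the whole
    pipeline can be exercised and validated without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
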