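Package: toothmap
Title: Quantitative Mapping of Immunofluorescence Expression Domains in
    Developing Tooth Germ Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.invalid",
           role = c("aut", "cre"))
Description: A tested re-implementation of an immunofluorescence
    image-quantification workflow for epithelial/mesenchymal organ
    sections: iterative dark-point background equalization verified at
    negative marker points, counter-channel bleed-through subtraction with
    median filtering, seven-level intensity threshold banding with
    composite hotmaps, expression-domain size quantification over regions
    of interest, five-pixel-increment sample-unit band images, pixel-to-
    optical-density calibration from step-tablet readings with cm-scaled
    plot profiles, intensity-correlation co-localization analysis with
    serial-threshold overlap series, and Kruskal-Wallis/Dunn rank-based
    group comparison. Ships a seeded synthetic tooth-germ phantom
    generator with complete ground truth so the entire pipeline is
    testable without archival tissue.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
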