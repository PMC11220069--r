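Package: coccotraits
Title: Morphometric Cell Size and Cellular Calcite Estimation for Coccolithophores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes coccolithophore cellular morphological traits from
    per-coccosphere scanning electron microscopy measurements: coccosphere
    volume by geometric shape class, equivalent spherical diameter, inner
    cell size from a taxon-specific cell-to-coccosphere volume fraction,
    and cellular calcite (particulate inorganic carbon) from the shape-factor
    coccolith mass model, including taxon-specific correction rules
    (multilayer coccospheres, dimorphic spinose coccoliths, exothecal and
    appendage coccoliths, fixed fallback counts and lengths, holococcolith
    count back-calculation). Ships a versioned taxon-parameter registry, a
    one-at-a-time sensitivity analysis of calcite estimates to shape factor,
    coccolith length and coccolith count, and a seeded synthetic-data
    generator for pipeline validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
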