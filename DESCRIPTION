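Package: phytoalloc
Title: Macromolecular Resource Allocation and Emergent C:N:P:Fe Stoichiometry in Phytoplankton
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A coarse-grained macromolecular allocation model of phytoplankton
    physiology (protein, RNA, DNA, chlorophyll, lipid and storage pools) that
    links cellular growth rate, light and nutrient quotas to elemental
    stoichiometry (C:N:P:Fe).  Includes Droop-style quota dynamics with Liebig
    limitation and luxury storage, a two-size-class ecosystem driver with
    dissolved and detrital nutrient pools, seeded generators for culture-style
    and idealized meridional ocean forcing, and the stoichiometric diagnostics
    (size-class N:P decomposition, coefficient of variation of zonal profiles,
    phosphorus-storage estimation from paired cultures, biomass-weighted
    trait histograms).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
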