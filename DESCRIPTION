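Package: xylemcomp
Title: Comparative Analysis of Conifer Xylem Hydraulics and Pit Anatomy
Version: 0.1.0
Authors@R: person("Schovenhorst", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits xylem vulnerability curves (P50, slope, specific hydraulic
    conductivity) from centrifuge conductance series, derives bordered-pit
    sealing traits (torus overlap, margo flexibility, valve effect, pit
    aperture resistance) and tracheid traits (hydraulic diameter,
    thickness-to-span ratio, tracheid density) from anatomical measurements,
    and runs a phylogenetic comparative battery: Pearson and phylogenetically
    independent contrast correlations, Blomberg's K with permutation tests,
    one-way ANOVA with Tukey HSD letters, PCA, VIF screening, exhaustive
    AICc multimodel selection with averaging, and recursive path analysis
    with chi-square fit. A synthetic-data generator produces trees, trait
    tables and centrifuge datasets with the covariance structure the
    analysis assumes, so the whole pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
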