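Package: archasym
Title: Bilateral Shape Asymmetry and Dental-Formula Variation in
    Pharyngeal Arches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Geometric-morphometric analysis of paired (left/right)
    three-dimensional landmark configurations, built around the matching
    symmetry design for bilateral structures such as the pharyngeal
    arches of cyprinid fishes. Provides generalised Procrustes
    superimposition, thin-plate-spline bending energy and sliding
    semi-landmarks, tangent-space projection, Procrustes ANOVA
    decomposition of shape variation into individual, directional
    asymmetry, fluctuating asymmetry and digitising-error components with
    permutation inference, redundancy analysis and two-factor variance
    partitioning with Ezekiel-adjusted R-squared, phenotypic trajectory
    comparisons, dental-formula parsing with Simpson diversity and
    contingency statistics, and a seeded synthetic generator of bilateral
    landmark datasets with known variance components for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
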