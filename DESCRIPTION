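Package: primface
Title: Quantitative Analysis of Primate Face Stimuli and Their Rated Attractiveness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how humans rate the attractiveness of primate
    faces. Quantifies colour composition, lightness, saturation and fur pattern
    of face stimuli from HSL hue bins; derives traditional morphometric traits
    from 19 facial landmarks and summarises them with maximum-likelihood factor
    analysis, canonical variate analysis and PCA; measures rater agreement on
    Likert scores with two-way consistency intraclass correlations, the
    Spearman-Brown relation, Mann-Whitney gender screens and nested variance
    components; and models species-level attractiveness with AIC-reduced linear
    models, redundancy analysis with sequential permutation tests, Tukey group
    contrasts and LOWESS human-likeness curves. A synthetic-data module
    generates face images, landmark sets and complete Likert rating matrices
    with controlled statistical structure so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    vegan,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
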