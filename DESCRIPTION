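Package: skewnet
Title: Social Control and Reproductive Skew in Animal Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying group-level social control in wild animal
    societies and relating it to female reproductive skew. Builds directed,
    weighted agonistic networks for annually resolved social groups, computes
    global reaching centrality (a network measure of despotism that accounts
    for direct and indirect relationships), Landau's linearity index and de
    Vries's randomised correction h', detects social groups from simple-ratio
    association indices with a two-level map-equation community detection
    algorithm, computes the multinomial M index of reproductive skew with its
    exact null correction, and fits the group-level mixed models (marginal,
    conditional and semi-partial R-squared, AICc, VIF) that link despotism to
    skew. Includes a synthetic colony generator with tunable despotism-skew
    coupling so the full pipeline can be exercised and validated without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmerTest,
    car,
    optparse
Config/testthat/edition: 3
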