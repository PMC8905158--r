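Package: viscokin
Title: Kin Selection and Altruism Under Density-Dependent Dispersal in
    Viscous Populations
Version: 0.1.0
Authors@R:
    person("Robin", "Whitfield", email = "robin.whitfield@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the evolution of indiscriminate altruism in
    Wright's infinite island model when dispersal is conditioned on local
    patch density.  Provides exact closed-form evaluation of whole-group
    relatedness, the scale of competition, the dispersal-mortality load,
    the Hamilton's-rule margin, the potential for altruism (the threshold
    cost-to-benefit ratio below which altruism is favoured), and the
    evolutionarily stable density-dependent dispersal schedule (the
    constant non-disperser strategy).  A compiled individual-based
    simulator co-evolves heritable altruism and a linear dispersal
    reaction norm on a finite set of patches, and experiment drivers
    reproduce the negative association between the evolved dispersal rate
    and the potential for altruism across a grid of patch sizes and
    dispersal costs, assessed with a Monte Carlo randomization test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
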