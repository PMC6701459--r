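Package: bdswap
Title: Symmetries and Parameter Transformations for Birth-Death Phylodynamic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the constant-rate linear birth-death model with
    incomplete sampling of extant individuals. Provides classical transition
    probabilities and a generator-exponential oracle, the probabilities of the
    number of sampled extant descendants of a lineage, the canonical
    two-parameter (lambda', mu') reparameterization with its feasibility
    intervals and equivalence classes of parameter triplets, reconstructed-tree
    probability densities under seven conditionings with Newick input and
    output, a Gillespie simulator with rho-sampling at the present, and
    maximum-likelihood inference carried out in the identifiable canonical
    coordinates, including likelihood-ridge diagnostics and an effective-prior
    pushforward for Bayesian analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Matrix,
    stats
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
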