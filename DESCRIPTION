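Package: subcloner
Title: Subclone Deconvolution of Bulk Tumor Sequencing Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolutes tumor heterogeneity from a single bulk-sequencing
    sample. Somatic variant allele frequencies are inverted to candidate
    cellular prevalences under every possible mutation/copy-number timing
    scenario, subclones and tumor purity are estimated from the peaks of a
    Gaussian kernel density over the pooled prevalences (Scott's rule
    bandwidth, grid search with Nelder-Mead refinement), every variant is
    assigned to a subclone by binomial maximum likelihood with
    expectation-maximization mixture weights, and candidate phylogenies are
    enumerated exhaustively under the prevalence ordering and sum
    constraints. Ships a forward tumor simulator with known ground truth and
    SMC-Het-style scoring metrics (purity, clone number, proportions,
    co-clustering, ancestry) so the whole stack is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
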