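Package: clonearch
Title: Clonal Architecture and Phylogeny Reconstruction from Multiregion
    Tumour Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing tumour clonal architecture from
    multiregion and longitudinal sequencing of solid tumours. Computes
    cancer cell fractions (CCFs) from per-sample read counts corrected for
    purity, ploidy, local copy number and mutation multiplicity; applies a
    battery of mutation quality filters including strand-bias, detection
    power, loss-of-heterozygosity conflict and binomial private/shared
    testing with Benjamini-Hochberg control; clusters mutations in
    two-dimensional CCF space with tensor-product smoothing splines and
    peak detection; infers clone trees under the infinite-sites assumption
    and the CCF sum rule with maximum-parsimony tie-breaking; classifies
    phylogenies into six topology classes; refits single-base-substitution
    mutational-signature exposures by non-negative least squares with
    backward selection; and calls high ploidy and whole-genome doubling
    from allele-specific copy number. A synthetic multiregion tumour
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
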