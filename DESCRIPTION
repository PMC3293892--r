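Package: grnbench
Title: Synthetic Regulatory-Network Benchmarks for Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates case/control gene-expression benchmarks with known
    biomarkers by simulating the evolution of a population of gene regulatory
    networks (pairing, mutation, phenotype-preserving selection), perturbing
    hub genes by in-silico knock-out and knock-down, and adding gene-wise
    measurement noise. Provides the matching evaluation stack: linear and
    Gaussian-kernel SVM, spectral-regression discriminant analysis and
    I-Relief feature weighting under entropy-based recursive feature
    elimination, Monte Carlo bootstrap resampling, a permutation-based
    moderated t-test with FDR selection, and ranked-list quality measures
    including Canberra-distance stability indicators for full and partial
    lists, the Matthews correlation coefficient, precision/recall and the
    area under the precision-recall curve.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    e1071,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
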