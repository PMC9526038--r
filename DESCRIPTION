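Package: impMKT
Title: Imputed McDonald-Kreitman Test and Related Estimators of Adaptive
    Evolution
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimators of the rate of adaptive protein evolution from
    polymorphism and divergence counts. Implements the imputed
    McDonald-Kreitman test (impMKT), which infers the number of slightly
    deleterious nonsynonymous variants segregating below a frequency
    cutoff and removes only those from the 2x2 contingency table, together
    with the classical McDonald-Kreitman test, the frequency-cutoff (FWW)
    and extended (eMKT) corrections, and the asymptotic extrapolation of
    alpha(x). Includes S4 containers for site frequency spectra and
    per-gene variation records, readers and writers for tabular gene
    data, gene pooling with bootstrap resampling, and a Poisson Random
    Field generator of synthetic datasets with known true alpha for
    estimator benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, minpack.lm
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
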