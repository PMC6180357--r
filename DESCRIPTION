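Package: sfhe
Title: Simplified Fixed Hessian Logistic Regression on Homomorphically Encrypted Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a binary logistic regression model directly on data encrypted
    under the Fan-Vercauteren (FV) somewhat-homomorphic encryption scheme. The
    trainer is a simplified fixed Hessian (SFH) Newton method: the Hessian is
    replaced once and for all by a diagonal negative-definite lower bound obtained
    from Gerschgorin's circle theorem, the sigmoid is linearised by its first-order
    Taylor expansion, and reciprocals are computed by a single division-free
    Newton step. Real inputs are mapped to sparse signed-digit plaintext
    polynomials with the w-NIBNAF non-integral-base encoding, the plaintext
    modulus is split by the Chinese remainder theorem, and one training
    iteration is evaluated as an arithmetic circuit of exactly five
    ciphertext-ciphertext multiplication stages. Includes plaintext reference
    implementations (exact Newton-Raphson and IRLS maximum likelihood), synthetic
    generators emulating binary genomic and min-max-normalised financial
    datasets, and confusion-matrix, ROC and AUC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
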