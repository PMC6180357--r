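# shared fixtures and independent oracles

# synthetic dataset guaranteed to be trainable (no all-zero covariate column,
# both classes present); deterministic: scans seeds upward from `seed`
gen_trainable <- function(N, d, kind = "binary", beta_true = NULL, seed = 1L) {
  for (s in seq(seed, seed + 100L)) {
    data <- gen_synthetic(N, d, kind, beta_true, seed = s)
    if (all(colSums(data$X[, -1, drop = FALSE] != 0) > 0) &&
        length(unique(data$y)) == 2L) {
      return(data)
    }
  }
  stop("no trainable draw found")
}

# O(D^2) schoolbook negacyclic convolution, centered mod t: the independent
# oracle for every ring-multiplication path
schoolbook_negacyclic <- function(a, b, t) {
  D <- length(a)
  out <- numeric(D)
  for (i in 0:(D - 1)) {
    for (j in 0:(D - 1)) {
      e <- i + j
      s <- 1
      if (e >= D) { e <- e - D; s <- -1 }
      out[e + 1] <- out[e + 1] + s * a[i + 1] * b[j + 1]
    }
  }
  r <- out %% t
  ifelse(r > t / 2, r - t, r)
}

# small FV parameter set for fast scheme-level tests
fv_params_small <- function() fv_params(D = 64, qbits = 60, t = 257, sigma = 20,
                                        relin_base_bits = 16)
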