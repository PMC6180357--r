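# Shared toy fixture: one keygen/encryption reused across blocks (everything
# downstream is deterministic, so reuse is safe).
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      data <- gen_trainable(10, 3, "binary", beta_true = c(0, 2, -1, 1), seed = 1)
      cfg <- encoding_preset("toy")
      par <- fv_params_preset("toy")
      keys <- fv_keygen_crt(par, cfg$t_factors, seed = 5)
      enc <- encrypt_dataset(data, cfg, keys, seed = 9)
      cache <<- list(data = data, cfg = cfg, par = par, keys = keys, enc = enc)
    }
    cache
  }
})

test_that("dataset encoding is exact for binary covariates and labels", {
  fx <- toy_fixture()
  enc <- encode_dataset(fx$data, fx$cfg)
  expect_true(enc$binary)
  expect_equal(enc$emin, 0L)   # single digits at exponent 0 only
  expect_equal(enc$emax, 0L)
  for (i in 1:3) {
    for (j in 1:3)
      expect_equal(nibnaf_decode(enc$x[[i]][[j]], fx$cfg, 0L),
                   unname(fx$data$X[i, j + 1]))
    expect_equal(nibnaf_decode(enc$y[[i]], fx$cfg, 0L), fx$data$y[i])
  }
})

test_that("encrypted dataset layout matches the T*(d+1)*N size accounting", {
  fx <- toy_fixture()
  m <- fx$enc$manifest
  expect_equal(m$n_ct, 1 * (3 + 1) * 10)
  expect_equal(m$size_bits, m$n_ct * 2 * m$D * m$qbits)
  # the closed-form size at full-scale parameters
  expect_equal(encrypted_size_bits(T = 3, d = 20, N = 10, D = 4096, qbits = 186),
               3 * 21 * 10 * 2 * 4096 * 186)
  # every stored covariate decrypts back to its original value
  for (i in c(1, 7)) {
    for (j in 1:3) {
      dec <- fv_decrypt(fx$keys[[1]], fx$enc$cts[[1]]$x[[i]][[j]])
      expect_equal(nibnaf_decode(dec, fx$cfg, 0L), unname(fx$data$X[i, j + 1]))
    }
  }
  # parameter mismatches are rejected
  bad_keys <- fv_keygen_crt(fv_params_preset("toy"), 101, seed = 1)
  expect_error(encrypt_dataset(fx$data, fx$cfg, bad_keys, seed = 1),
               "plaintext modulus")
})

test_that("one encrypted iteration equals the plaintext Newton-mode trainer", {
  fx <- toy_fixture()
  mod <- encrypted_sfh_iteration(fx$enc, fx$keys, iters = 1)
  beta_enc <- decrypt_model(fx$keys, mod)
  beta_pl <- sfh_train(fx$data, iters = 1, inversion = "newton", x0 = mod$x0)
  # binary data and a single-digit x0 make the circuit exact
  expect_equal(as.numeric(beta_enc), as.numeric(beta_pl), tolerance = 1e-12)
  # ... and therefore scores and AUC coincide exactly
  p_enc <- predict_proba(beta_enc, fx$data)
  p_pl <- predict_proba(beta_pl, fx$data)
  expect_equal(roc_auc(p_enc, fx$data$y)$auc, roc_auc(p_pl, fx$data$y)$auc)
  # re-running the (deterministic) circuit reproduces the result bit-exactly
  mod2 <- encrypted_sfh_iteration(fx$enc, fx$keys, iters = 1)
  expect_identical(lapply(mod$beta[[1]], `[[`, "data"),
                   lapply(mod2$beta[[1]], `[[`, "data"))
})

test_that("the circuit instrumentation reports five multiplication stages", {
  fx <- toy_fixture()
  mod <- encrypted_sfh_iteration(fx$enc, fx$keys, iters = 1)
  rep <- mod$report
  expect_equal(rep$ct_mults, 5L)
  # elementwise op counts: h and G cost N*d each, the Newton step and the
  # update cost d+1 each
  expect_equal(rep$ct_mult_ops, 2 * 10 * 3 + 3 * (3 + 1))
  expect_equal(rep$pt_mults, 0L)
  expect_equal(rep$max_level, 4L)
  expect_gt(rep$ct_adds, 0L)
  # operation counts scale linearly in N and d
  d2 <- gen_trainable(20, 3, "binary", beta_true = c(0, 2, -1, 1), seed = 31)
  r2 <- rt_sfh_iteration(d2, fx$cfg, iters = 1)$report
  expect_equal(r2$ct_mult_ops, 2 * 20 * 3 + 3 * 4)
  d3 <- gen_trainable(10, 6, "binary", beta_true = c(0, 2, -1, 1, 1, -1, 2), seed = 32)
  r3 <- rt_sfh_iteration(d3, fx$cfg, iters = 1)$report
  expect_equal(r3$ct_mult_ops, 2 * 10 * 6 + 3 * 7)
})

test_that("zero iterations decrypt to the zero model", {
  fx <- toy_fixture()
  m0 <- encrypted_sfh_iteration(fx$enc, fx$keys, iters = 0)
  expect_equal(as.numeric(decrypt_model(fx$keys, m0)), rep(0, 4))
  expect_equal(m0$report$ct_mults, 0L)
})

test_that("decrypted circuit equals the R_t circuit coefficient for coefficient", {
  fx <- toy_fixture()
  mod <- encrypted_sfh_iteration(fx$enc, fx$keys, iters = 1)
  rt <- rt_sfh_iteration(fx$data, fx$cfg, iters = 1)
  for (f in seq_along(fx$keys)) {
    for (k in seq_along(mod$beta[[f]])) {
      expect_identical(fv_decrypt(fx$keys[[f]], mod$beta[[f]][[k]]),
                       rt$polys[[f]][[k]])
    }
  }
  expect_equal(as.numeric(decrypt_model(fx$keys, mod)), as.numeric(rt$beta))
  expect_identical(mod$spans, rt$spans)
})

test_that("noise budget survives the full one-iteration circuit", {
  fx <- toy_fixture()
  mod <- encrypted_sfh_iteration(fx$enc, fx$keys, iters = 1)
  budgets <- vapply(mod$beta[[1]], function(ct) fv_noise_budget(fx$keys[[1]], ct),
                    numeric(1))
  expect_true(all(budgets > 0))
})

test_that("multi-iteration circuit tracks the plaintext Newton trainer", {
  # run in the plaintext ring (identical topology to the encrypted circuit);
  # the wide genomic modulus absorbs the coefficient growth of 3 iterations
  data <- gen_trainable(10, 3, "binary", beta_true = c(0, 2, -1, 1), seed = 1)
  cfg <- encoding_preset("genomic")
  for (iters in c(2, 3)) {
    rt <- rt_sfh_iteration(data, cfg, iters = iters)
    pl <- sfh_train(data, iters = iters, inversion = "newton", x0 = rt$x0)
    expect_equal(as.numeric(rt$beta), as.numeric(pl), tolerance = 1e-9)
    expect_equal(rt$report$ct_mults, 5L + 3L * (iters - 1L))
  }
})

test_that("continuous covariates pass through the encrypted pipeline", {
  # financial-style: min-max-normalised values, two CRT factors, full ring
  data <- gen_trainable(8, 2, "continuous", beta_true = c(0, 3, -3), seed = 3)
  cfg <- encoding_preset("financial")
  par <- fv_params_preset("fullscale")
  keys <- fv_keygen_crt(par, cfg$t_factors, seed = 21)
  enc <- encrypt_dataset(data, cfg, keys, seed = 22)
  expect_equal(enc$manifest$n_ct, 2 * 3 * 8)
  expect_false(enc$manifest$binary)
  mod <- encrypted_sfh_iteration(enc, keys, iters = 1)
  beta_enc <- decrypt_model(keys, mod)
  beta_pl <- sfh_train(data, iters = 1, inversion = "newton", x0 = mod$x0)
  # truncation of the continuous encodings bounds the gap
  expect_equal(as.numeric(beta_enc), as.numeric(beta_pl), tolerance = 1e-5)
  expect_equal(mod$report$ct_mults, 5L)
  budgets <- vapply(seq_along(keys), function(f)
    min(vapply(mod$beta[[f]], function(ct) fv_noise_budget(keys[[f]], ct),
               numeric(1))), numeric(1))
  expect_true(all(budgets > 0))
})
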