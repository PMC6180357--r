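test_that("negacyclic ring product agrees with the schoolbook oracle", {
  set.seed(61)
  for (D in c(16, 32, 64)) {
    for (t in c(257, 4099)) {
      a <- sample(-floor(t / 2):floor(t / 2), D, replace = TRUE)
      b <- sample(-floor(t / 2):floor(t / 2), D, replace = TRUE)
      expect_equal(as.numeric(ring_mul(a, b, t)),
                   schoolbook_negacyclic(a, b, t))
    }
  }
})

test_that("key generation is seeded and produces a well-formed public key", {
  p <- fv_params_small()
  k1 <- fv_keygen(p, seed = 7)
  k2 <- fv_keygen(p, seed = 7)
  k3 <- fv_keygen(p, seed = 8)
  s1 <- .fv_keys_serialize_cpp(k1$ptr, TRUE)
  expect_identical(s1, .fv_keys_serialize_cpp(k2$ptr, TRUE))
  expect_false(identical(s1, .fv_keys_serialize_cpp(k3$ptr, TRUE)))
  # [b + a s]_q is the keygen error: bounded by the 6-sigma truncation
  expect_lte(.fv_pk_noise_cpp(k1$ptr), 6 * p$sigma)
  # the full-scale parameter set generates without error
  expect_s3_class(fv_keygen(fv_params_preset("fullscale"), seed = 1), "sfhe_fv_keys")
})

test_that("encryption round-trips, masks zero, and is seed-deterministic", {
  p <- fv_params_small()
  k <- fv_keygen(p, seed = 9)
  set.seed(62)
  for (rep in 1:10) {
    m <- sample(-128:128, p$D, replace = TRUE)
    ct <- fv_encrypt(k, m, seed = rep)
    expect_identical(fv_decrypt(k, ct), as.integer(m))
  }
  c0 <- fv_encrypt(k, 0, seed = 3)
  expect_true(any(c0$data != as.raw(0)))        # semantic masking
  expect_gt(fv_noise_budget(k, c0), 0)
  expect_identical(fv_encrypt(k, 5, seed = 4)$data, fv_encrypt(k, 5, seed = 4)$data)
  expect_false(identical(fv_encrypt(k, 5, seed = 4)$data,
                         fv_encrypt(k, 5, seed = 5)$data))
  expect_error(fv_encrypt(k, rep(1000, p$D), seed = 1), "range")
})

test_that("homomorphic addition matches ring addition", {
  p <- fv_params_small()
  k <- fv_keygen(p, seed = 10)
  set.seed(63)
  a <- sample(-100:100, p$D, replace = TRUE)
  b <- sample(-100:100, p$D, replace = TRUE)
  ca <- fv_encrypt(k, a, seed = 1); cb <- fv_encrypt(k, b, seed = 2)
  expect_identical(fv_decrypt(k, fv_add(ca, cb)),
                   as.integer(centered_mod(a + b, p$t)))
  expect_identical(fv_decrypt(k, fv_add(ca, cb)), fv_decrypt(k, fv_add(cb, ca)))
  expect_identical(fv_decrypt(k, fv_add(ca, fv_encrypt(k, 0, seed = 3))),
                   as.integer(a))
  expect_identical(fv_decrypt(k, fv_sub(ca, cb)),
                   as.integer(centered_mod(a - b, p$t)))
  # n-fold sum of Enc(1) decrypts to n mod t
  one <- fv_encrypt(k, 1, seed = 4)
  acc <- one
  for (i in 2:300) acc <- fv_add(acc, one)
  expect_equal(fv_decrypt(k, acc)[1], as.integer(centered_mod(300, p$t)))
})

test_that("homomorphic multiplication matches ring arithmetic in R_t", {
  p <- fv_params(D = 16, qbits = 60, t = 257, sigma = 20, relin_base_bits = 16)
  k <- fv_keygen(p, seed = 11)
  expect_equal(fv_decrypt(k, fv_mul(fv_encrypt(k, 2, seed = 1),
                                    fv_encrypt(k, 3, seed = 2), k))[1], 6L)
  set.seed(64)
  for (rep in 1:10) {
    a <- sample(-128:128, 16, replace = TRUE)
    b <- sample(-128:128, 16, replace = TRUE)
    ca <- fv_encrypt(k, a, seed = 2 * rep); cb <- fv_encrypt(k, b, seed = 2 * rep + 1)
    expect_identical(fv_decrypt(k, fv_mul(ca, cb, k)), ring_mul(a, b, 257))
    expect_identical(fv_decrypt(k, fv_pt_mul(ca, b)), ring_mul(a, b, 257))
    expect_identical(fv_decrypt(k, fv_mul(ca, fv_lift(p, b), k)),
                     ring_mul(a, b, 257))
  }
  expect_identical(fv_decrypt(k, fv_pt_mul(fv_encrypt(k, 9, seed = 99), 1))[1], 9L)
})

test_that("fixed-point squares survive encrypt-multiply-decode", {
  cfg <- encoding_preset("toy")
  par <- fv_params_preset("toy")
  k <- fv_keygen(par, seed = 12)
  p5 <- laurent_fold(nibnaf_encode(0.5, cfg), cfg$D)
  ct <- fv_mul(fv_encrypt(k, centered_mod(p5, par$t), seed = 1),
               fv_encrypt(k, centered_mod(p5, par$t), seed = 2), k)
  dec <- nibnaf_decode(fv_decrypt(k, ct), cfg, 2L * (cfg$precision + 5L))
  expect_equal(dec, 0.25, tolerance = 1e-5)
})

test_that("noise budget is positive while correct and decreasing under mult", {
  par <- fv_params_preset("toy")
  k <- fv_keygen(par, seed = 13)
  ct <- fv_encrypt(k, 2, seed = 1)
  budgets <- fv_noise_budget(k, ct)
  vals <- fv_decrypt(k, ct)[1]
  x <- ct
  truth <- 2
  truths <- truth
  for (i in 1:6) {
    x <- fv_mul(x, x, k)
    budgets <- c(budgets, fv_noise_budget(k, x))
    vals <- c(vals, fv_decrypt(k, x)[1])
    truth <- (truth * truth) %% par$t
    truths <- c(truths, truth)
  }
  expect_true(all(diff(budgets) < 0))            # strictly decreasing
  expect_equal(x$level, 6)
  ok <- vals == as.integer(centered_mod(truths, par$t))
  # exact while the budget is clearly positive; once the measured budget
  # collapses (noise at Delta/2) decryption goes wrong
  expect_true(all(ok[budgets > 1]))
  expect_true(any(budgets < 1))
  expect_false(all(ok[budgets < 1]))
})

test_that("ciphertexts pack at exactly 2*D*log2(q) bits and round-trip", {
  p <- fv_params_small()
  k <- fv_keygen(p, seed = 14)
  ct <- fv_encrypt(k, 17, seed = 1)
  payload <- fv_pack(ct)
  expect_equal(length(payload), 2 * p$D * p$qbits / 8)
  back <- fv_unpack(payload, p)
  expect_identical(back$data, ct$data)
  # file round trip is bit-exact; truncation is reported
  path <- withr::local_tempfile(fileext = ".ct")
  write_ciphertext(ct, path)
  rt <- read_ciphertext(path)
  expect_identical(rt$data, ct$data)
  expect_identical(fv_pack(rt), payload)
  writeBin(readBin(path, "raw", 50), path)
  expect_error(read_ciphertext(path), "truncated")
  writeBin(as.raw(1:100), path)
  expect_error(read_ciphertext(path), "not an sfhe ciphertext")
})

test_that("key files round-trip and evaluation keys cannot decrypt", {
  p <- fv_params_small()
  k <- fv_keygen(p, seed = 15)
  path <- withr::local_tempfile(fileext = ".key")
  write_keys(k, path)
  k2 <- read_keys(path)
  ct <- fv_encrypt(k, 23, seed = 1)
  expect_identical(fv_decrypt(k2, ct), fv_decrypt(k, ct))
  m <- fv_mul(ct, ct, k2)
  m23 <- c(23, integer(p$D - 1))
  expect_identical(fv_decrypt(k, m), ring_mul(m23, m23, p$t))
  ke <- fv_evaluation_keys(k)
  expect_error(fv_decrypt(ke, ct), "secret")
  expect_error(fv_noise_budget(ke, ct), "secret")
  expect_identical(fv_decrypt(k, fv_mul(ct, ct, ke)), fv_decrypt(k, m))
  # public (sk-less) key file
  write_keys(k, path, with_sk = FALSE)
  kp <- read_keys(path)
  expect_false(kp$has_sk)
  expect_identical(fv_decrypt(k, fv_encrypt(kp, 5, seed = 9))[1], 5L)
})
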