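test_that("calibrated bases lie in (1,2) and shrink towards 1 as w grows", {
  bs <- vapply(c(2, 10, 150, 715), nibnaf_base, numeric(1))
  expect_true(all(bs > 1 & bs < 2))
  expect_true(all(diff(bs) < 0))
  # preset configurations (including the full-scale w values) build cleanly
  expect_s3_class(encoding_preset("genomic"), "sfhe_encoding")
  expect_s3_class(encoding_preset("financial"), "sfhe_encoding")
})

test_that("greedy expansion honours digit-set and spacing and encodes anchors", {
  cfg <- encoding_preset("toy")
  expect_length(nibnaf_encode(0, cfg)$exp, 0)
  e1 <- nibnaf_encode(1, cfg)
  expect_equal(e1$exp, 0L)
  expect_equal(e1$sign, 1L)
  eb <- nibnaf_encode(cfg$b, cfg)   # the base itself maps to X
  expect_equal(eb$exp, 1L)
  em <- nibnaf_encode(-1, cfg)
  expect_equal(em$sign, -1L)
})

test_that("round-trip error stays within the truncation tail bound", {
  set.seed(51)
  for (w in c(2, 10, 150)) {
    cfg <- encoding_config(w = w, D = 4096, t_factors = 97)
    tail_bound <- cfg$b^(-cfg$precision) / (1 - cfg$b^(-w))
    for (theta in runif(200, -1, 1)) {
      dg <- nibnaf_encode(theta, cfg)
      expect_true(nibnaf_digits_valid(dg, w))
      expect_lte(abs(digits_value(dg) - theta), tail_bound * (1 + 1e-9))
    }
  }
})

test_that("digit count obeys the sparsity bound span/w + 1", {
  set.seed(52)
  for (w in c(10, 150)) {
    cfg <- encoding_config(w = w, D = 4096, t_factors = 97)
    for (theta in runif(100, -1, 1)) {
      dg <- nibnaf_encode(theta, cfg)
      if (!length(dg$exp)) next
      span <- max(dg$exp) - min(dg$exp) + 1
      expect_lte(length(dg$exp), ceiling(span / w) + 1)
    }
  }
})

test_that("folding wraps negative exponents with a sign flip (X^D = -1)", {
  expect_equal(laurent_fold(list(exp = 0L, sign = 1L), 8), c(1, rep(0, 7)))
  expect_equal(laurent_fold(list(exp = -1L, sign = 1L), 4), c(0, 0, 0, -1))
  expect_equal(laurent_fold(list(exp = c(2L, -2L), sign = c(1L, -1L)), 8),
               c(0, 0, 1, 0, 0, 0, 1, 0))
  # fold then unfold is the identity on valid digit maps
  set.seed(53)
  cfg <- encoding_config(w = 6, D = 64, t_factors = 97, precision = 40)
  for (theta in runif(50, -1, 1)) {
    dg <- nibnaf_encode(theta, cfg)
    if (!length(dg$exp)) next
    u <- laurent_unfold(laurent_fold(dg, 64), frac_span = 45)
    o <- order(u$exp, decreasing = TRUE)
    expect_equal(u$exp[o], dg$exp)
    expect_equal(u$coef[o], as.numeric(dg$sign))
  }
  expect_error(laurent_fold(list(exp = c(0L, -4L), sign = c(1L, 1L)), 4), "span")
  expect_error(laurent_fold(list(exp = c(3L, 3L), sign = c(1L, 1L)), 8),
               "collision")
})

test_that("decode inverts encode through the ring and respects homomorphisms", {
  cfg <- encoding_preset("toy")
  fs <- cfg$precision + 10L
  expect_equal(nibnaf_decode(integer(cfg$D), cfg, fs), 0)
  set.seed(54)
  th <- runif(60, -1, 1)
  for (theta in th[1:20]) {
    p <- laurent_fold(nibnaf_encode(theta, cfg), cfg$D)
    expect_lt(abs(nibnaf_decode(p, cfg, fs) - theta), 1e-6)
  }
  # additive homomorphism
  for (k in 1:10) {
    t1 <- th[2 * k]; t2 <- th[2 * k + 1]
    p1 <- laurent_fold(nibnaf_encode(t1, cfg), cfg$D)
    p2 <- laurent_fold(nibnaf_encode(t2, cfg), cfg$D)
    expect_lt(abs(nibnaf_decode(p1 + p2, cfg, fs) - (t1 + t2)), 2e-6)
  }
  # boundary coefficients are refused rather than mis-decoded
  bad <- integer(cfg$D); bad[3] <- floor(cfg$t / 2)
  expect_error(nibnaf_decode(bad, cfg, fs), "t too small")
})

test_that("multiplicative homomorphism holds through the ring product", {
  # single-factor toy modulus
  cfg <- encoding_preset("toy")
  fs2 <- 2L * (cfg$precision + 10L)
  set.seed(55)
  for (k in 1:10) {
    t1 <- runif(1, -1, 1); t2 <- runif(1, -1, 1)
    p1 <- laurent_fold(nibnaf_encode(t1, cfg), cfg$D)
    p2 <- laurent_fold(nibnaf_encode(t2, cfg), cfg$D)
    pr <- ring_mul(p1, p2, cfg$t)
    expect_lt(abs(nibnaf_decode(pr, cfg, fs2) - t1 * t2), 1e-5)
  }
  # full-scale moduli via the CRT route (per-factor products, then join)
  cfg <- encoding_preset("financial")
  fs2 <- 2L * (cfg$precision + 10L)
  for (k in 1:3) {
    t1 <- runif(1, -1, 1); t2 <- runif(1, -1, 1)
    p1 <- laurent_fold(nibnaf_encode(t1, cfg), cfg$D)
    p2 <- laurent_fold(nibnaf_encode(t2, cfg), cfg$D)
    pr <- crt_join(lapply(cfg$t_factors, function(ti)
      ring_mul(centered_mod(p1, ti), centered_mod(p2, ti), ti)), cfg$t_factors)
    expect_lt(abs(nibnaf_decode(pr, cfg, fs2) - t1 * t2), 1e-5)
  }
})

test_that("CRT split/join uses centered representatives and is a bijection", {
  expect_equal(crt_split(7, c(3, 5)), list(1, 2))
  expect_equal(as.numeric(crt_join(list(1, 2), c(3, 5))), 7)
  expect_equal(crt_split(-1, 3)[[1]], -1)      # centered lift of 2 mod 3
  set.seed(56)
  for (fs in list(c(3, 5), c(5179, 5189, 5197), c(2237, 2239))) {
    t <- prod(fs)
    p <- sample(-floor((t - 1) / 2):floor((t - 1) / 2), 40, replace = TRUE)
    expect_equal(as.numeric(crt_join(crt_split(p, fs), fs)), p)
  }
  expect_error(encoding_config(w = 6, D = 64, t_factors = c(6, 9)), "coprime")
  expect_error(crt_join(list(1, 1), c(4, 6)), "not invertible|coprime")
})

test_that("centered_mod lands in (-m/2, m/2]", {
  expect_equal(centered_mod(-1, 3), -1)
  expect_equal(centered_mod(2, 3), -1)
  expect_equal(centered_mod(c(0, 1, 2, 3, 4), 5), c(0, 1, 2, -2, -1))
})
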