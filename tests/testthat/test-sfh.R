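test_that("Taylor sigmoid is the unclamped affine surrogate of the sigmoid", {
  expect_equal(sigmoid_taylor(0), 0.5)
  expect_equal(sigmoid_taylor(2), 1.0)           # not clamped
  expect_equal(sigmoid_taylor(6), 2.0)
  # surrogate error at z = 2 against the numeric sigmoid
  expect_lt(abs(abs(sigmoid_taylor(2) - 1 / (1 + exp(-2))) - 0.119), 1e-3)
})

test_that("log likelihood matches closed forms and is non-positive", {
  d4 <- dataset(matrix(c(1, 0, 1, 0), 4), c(1, -1, 1, -1))
  expect_equal(log_likelihood(rep(0, 2), d4), -4 * log(2))
  d1 <- dataset(matrix(1, 1), 1)
  expect_equal(log_likelihood(c(0, 1), d1), -log(1 + exp(-1)))
  # correctly classified record: likelihood tends to 0 as beta scales up
  lls <- sapply(c(1, 10, 100), function(s) log_likelihood(c(0, s), d1))
  expect_true(all(diff(lls) > 0) && lls[3] > -1e-40)
  set.seed(4)
  dd <- gen_trainable(25, 3, seed = 2)
  expect_lte(log_likelihood(rnorm(4), dd), 0)
  expect_error(log_likelihood(rep(0, 7), dd), "length")
})

test_that("gradient agrees with closed forms and finite differences", {
  d2 <- dataset(matrix(c(1, 0), 2), c(1, -1))
  expect_equal(gradient(c(0, 0), d2, "exact"), c(0, 0.5),
               ignore_attr = TRUE)
  expect_equal(gradient(c(0, 0), d2, "taylor"), c(0, 0.5),
               ignore_attr = TRUE)
  set.seed(11)
  dd <- gen_trainable(20, 4, "continuous", seed = 3)
  beta <- rnorm(5) / 2
  # taylor mode collapses to X'y/2 - X'X beta / 4
  expect_equal(gradient(beta, dd, "taylor"),
               drop(crossprod(dd$X, dd$y)) / 2 - drop(crossprod(dd$X) %*% beta) / 4,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(gradient(rep(0, 5), dd, "taylor"),
               drop(crossprod(dd$X, dd$y)) / 2, ignore_attr = TRUE)
  # central finite differences of the log likelihood
  h <- 1e-6
  fd <- vapply(seq_along(beta), function(k) {
    e <- numeric(length(beta)); e[k] <- h
    (log_likelihood(beta + e, dd) - log_likelihood(beta - e, dd)) / (2 * h)
  }, numeric(1))
  expect_equal(gradient(beta, dd, "exact"), fd, ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("fixed Hessian is -X'X/4", {
  d2 <- dataset(matrix(c(1, 0), 2), c(1, -1))
  expect_equal(unname(fixed_hessian(d2)),
               matrix(c(-0.5, -0.25, -0.25, -0.25), 2))
  set.seed(8)
  dd <- gen_trainable(15, 4, "continuous", seed = 5)
  H <- fixed_hessian(dd)
  expect_true(isSymmetric(H))
  # intercept-only-style data: all-zero covariates give diag(-N/4, 0)
  d0 <- suppressWarnings(dataset(matrix(0, 8, 1), rep(c(1, -1), 4)))
  expect_equal(unname(fixed_hessian(d0)), matrix(c(-2, 0, 0, 0), 2))
})

test_that("simplified Hessian diagonal: row sums, O(Nd) multiplication count", {
  d2 <- dataset(matrix(c(1, 0), 2), c(1, -1))
  expect_equal(as.numeric(simplified_hessian_diag(d2)), c(-0.75, -0.5))
  for (s in 1:5) {
    dd <- gen_trainable(20, 3 + s, "continuous", seed = s)
    expect_equal(as.numeric(simplified_hessian_diag(dd)),
                 unname(rowSums(fixed_hessian(dd))), tolerance = 1e-12)
  }
  # multiplication count linear in d (and within the N*(d+2) contract)
  n1 <- attr(simplified_hessian_diag(gen_trainable(40, 5, seed = 2)), "n_mults")
  n2 <- attr(simplified_hessian_diag(gen_trainable(40, 10, seed = 2)), "n_mults")
  expect_lte(n1, 40 * 7)
  expect_lte(n2, 40 * 12)
  expect_equal(n2 - n1, 40 * 5)  # linear growth, not quadratic
  # intercept-only: d=0 is not constructible, but all-zero covariate shows -N/4
  d0 <- suppressWarnings(dataset(matrix(0, 8, 1), rep(c(1, -1), 4)))
  expect_equal(as.numeric(simplified_hessian_diag(d0))[1], -2)
})

test_that("Loewner ordering checks via eigenvalues", {
  expect_true(loewner_nonneg(matrix(c(1, -1, -1, 1), 2)))
  expect_false(loewner_nonneg(matrix(c(-1, 0, 0, 1), 2)))
  expect_error(loewner_nonneg(matrix(c(1, 2, 3, 4), 2)), "symmetric")
  # Gerschgorin argument: A - diag(rowsums A) is psd for non-positive symmetric A
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(2:10, 1)
    A <- -abs(matrix(rnorm(n * n), n))
    A <- (A + t(A)) / 2
    expect_true(loewner_nonneg(A - diag(rowSums(A))))
  }
})

test_that("Loewner chain H(beta) >= -X'X/4 >= Htilde on random designs", {
  set.seed(31)
  for (kind in c("binary", "continuous")) {
    for (rep in 1:10) {
      dd <- gen_trainable(20, 4, kind, seed = rep)
      beta <- rnorm(5)
      z <- dd$y * drop(dd$X %*% beta)
      s <- sigmoid(z)
      H <- -crossprod(dd$X * sqrt(s * (1 - s)))
      Hbar <- fixed_hessian(dd)
      Ht <- diag(as.numeric(simplified_hessian_diag(dd)))
      expect_true(loewner_nonneg(H - Hbar, tol = 1e-8))
      expect_true(loewner_nonneg(Hbar - Ht, tol = 1e-8))
    }
  }
})

test_that("division-free Newton reciprocal follows its recurrence", {
  expect_equal(invert_scalar_newton(2, 0.5, 1), 0.5)      # exact fixed point
  expect_equal(invert_scalar_newton(4, 0.2, 1), 0.24)     # 0.2*(2-0.8)
  expect_equal(invert_scalar_newton(5, 0.1, 10), 0.2, tolerance = 1e-12)
  expect_equal(invert_scalar_newton(5, 0.1, 0), 0.1)
  expect_error(invert_scalar_newton(0, 1, 1), "zero")
  # one-step relative error is exactly (1 - a*x0)^2
  a <- 7; x0 <- 1.2 / a
  expect_equal(abs(invert_scalar_newton(a, x0, 1) - 1 / a) * a, (1 - a * x0)^2)
})

test_that("SFH trainer reproduces the worked example and its contract", {
  d2 <- dataset(matrix(c(1, 0), 2), c(1, -1))
  expect_equal(as.numeric(sfh_train(d2, iters = 1)), c(0, 1))
  expect_equal(as.numeric(sfh_train(d2, iters = 0)), c(0, 0))
  # long-run fixed point: Taylor gradient vanishes
  dd <- gen_trainable(60, 3, "continuous", seed = 9)
  beta <- sfh_train(dd, iters = 4000)
  expect_lt(max(abs(gradient(beta, dd, "taylor"))), 1e-8)
  expect_equal(as.numeric(beta),
               as.numeric(2 * solve(crossprod(dd$X), crossprod(dd$X, dd$y))),
               tolerance = 1e-6)
  # degenerate all-zero covariate column is reported
  dz <- suppressWarnings(dataset(matrix(0, 6, 1), rep(c(1, -1), 3)))
  expect_error(sfh_train(dz), "degenerate")
})

test_that("Newton-inverse trainer matches exact inversion as inv_iters grows", {
  dd <- gen_trainable(40, 4, seed = 13)
  b_exact <- sfh_train(dd, iters = 1, inversion = "exact")
  x0 <- newton_x0(dd$N, dd$d, mu = 1)
  b_n1 <- sfh_train(dd, iters = 1, inversion = "newton", x0 = x0, inv_iters = 1)
  b_n6 <- sfh_train(dd, iters = 1, inversion = "newton", x0 = x0, inv_iters = 6)
  b_n12 <- sfh_train(dd, iters = 1, inversion = "newton", x0 = x0, inv_iters = 12)
  # one shared start serves every diagonal entry, so convergence rates differ
  # per coordinate; more reciprocal steps monotonically recover the exact fit
  expect_equal(as.numeric(b_n12), as.numeric(b_exact), tolerance = 1e-6)
  e1 <- max(abs(b_n1 - b_exact)); e6 <- max(abs(b_n6 - b_exact))
  expect_gt(e1, 0)
  expect_lt(e6, e1)
  expect_lt(e1 / max(abs(b_exact)), 1)
})

test_that("IRLS reference is the maximum-likelihood oracle", {
  # effectively intercept-only fit: the covariate has identical class-
  # conditional distributions, so the MLE is beta1 = 0, beta0 = log(n+/n-)
  d0 <- dataset(matrix(c(0, 0, 0, 1, 1, 1, 0, 1), 8),
                c(1, 1, 1, 1, 1, 1, -1, -1))
  b <- irls_reference(d0)
  expect_equal(unname(b[1]), log(3), tolerance = 1e-4)
  expect_equal(unname(b[2]), 0, tolerance = 1e-4)
  dd <- gen_trainable(80, 3, "continuous", seed = 17)
  bi <- irls_reference(dd)
  expect_lt(max(abs(gradient(bi, dd, "exact"))), 1e-5)
  expect_gte(log_likelihood(bi, dd), log_likelihood(sfh_train(dd, 1), dd))
  expect_gte(log_likelihood(bi, dd), log_likelihood(sfh_train(dd, 50), dd))
  # separable data: capped with a warning, not an error
  ds <- dataset(matrix(c(0, 0, 1, 1), 4), c(-1, -1, 1, 1))
  expect_warning(bs <- irls_reference(ds), "separable|converge")
  expect_true(all(abs(bs) <= 30))
})

test_that("prediction uses the true sigmoid and inclusive thresholding", {
  expect_equal(predict_proba(c(0, 0), matrix(0.3, 1)), 0.5)
  expect_equal(classify(0.5, 0.5), 1)            # boundary inclusive
  expect_equal(classify(0.49, 0.5), -1)
  expect_error(classify(0.5, 1), "tau")
  expect_equal(predict_proba(c(log(3), 0), matrix(0, 1)), 0.75)
  # monotone in the linear predictor
  p <- predict_proba(c(0, 1), matrix(seq(-5, 5, 1), ncol = 1))
  expect_true(all(diff(p) > 0))
})

test_that("models round-trip through key=value files", {
  beta <- c(`(Intercept)` = -0.25, x1 = 1.5, x2 = -1 / 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(beta, path)
  expect_equal(read_model(path), beta)
})
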