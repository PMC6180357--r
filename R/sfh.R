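#' Logistic sigmoid and its first-order Taylor surrogate
#'
#' `sigmoid()` is the exact logistic function `1 / (1 + exp(-z))`.
#' `sigmoid_taylor()` is the affine surrogate `1/2 + z/4` used inside the
#' encrypted training circuit, where the true sigmoid is unavailable. The
#' surrogate is deliberately *not* clamped to `[0, 1]`: the circuit consumes
#' the raw affine value.
#'
#' @param z numeric vector.
#' @return numeric vector of the same length.
#' @examples
#' sigmoid_taylor(0)        # 0.5, agrees with sigmoid(0)
#' sigmoid_taylor(2)        # 1.0 (unclamped)
#' @export
sigmoid <- function(z) 1 / (1 + exp(-z))

#' @rdname sigmoid
#' @export
sigmoid_taylor <- function(z) 0.5 + z / 4

#' Log likelihood of a logistic model
#'
#' Computes `l(beta) = -sum_i log(1 + exp(-y_i * beta' x_i))`, the quantity
#' maximised during training. Always non-positive. Evaluated with `log1p` in a
#' numerically stable split so that strongly classified records do not
#' overflow.
#'
#' @param beta numeric coefficient vector of length `d + 1` (intercept first).
#' @param data an [dataset()].
#' @return scalar log likelihood.
#' @export
log_likelihood <- function(beta, data) {
  stopifnot(inherits(data, "sfhe_dataset"))
  if (length(beta) != data$d + 1L) stop("beta has wrong length")
  z <- data$y * drop(data$X %*% beta)
  # -log(1 + exp(-z)), stable for both signs of z
  -sum(ifelse(z > 0, log1p(exp(-z)), -z + log1p(exp(z))))
}

#' Gradient of the log likelihood
#'
#' `grad l(beta) = sum_i (1 - sigma(y_i beta' x_i)) y_i x_i`. With
#' `mode = "taylor"` the sigmoid is replaced by its affine surrogate, which
#' collapses the gradient to `X'y / 2 - (X'X) beta / 4` (using `y_i^2 = 1`);
#' this is the gradient the encrypted circuit evaluates. Both modes coincide
#' at `beta = 0`.
#'
#' @inheritParams log_likelihood
#' @param mode `"exact"` (true sigmoid) or `"taylor"`.
#' @return numeric vector of length `d + 1`.
#' @export
gradient <- function(beta, data, mode = c("exact", "taylor")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "sfhe_dataset"))
  if (length(beta) != data$d + 1L) stop("beta has wrong length")
  z <- data$y * drop(data$X %*% beta)
  s <- if (mode == "exact") sigmoid(z) else sigmoid_taylor(z)
  drop(crossprod(data$X, (1 - s) * data$y))
}

#' Fixed Hessian lower bound -X'X / 4
#'
#' The logistic Hessian satisfies `H(beta) >= -X'X/4` in the Loewner ordering
#' for every `beta`, because `sigma(1-sigma) <= 1/4`. The bound is independent
#' of `beta`, so a Newton method using it inverts a single constant matrix.
#'
#' @param data an [dataset()].
#' @return symmetric `(d+1) x (d+1)` matrix `-X'X / 4`.
#' @export
fixed_hessian <- function(data) {
  stopifnot(inherits(data, "sfhe_dataset"))
  -crossprod(data$X) / 4
}

#' Diagonal simplified Hessian, computed in O(Nd)
#'
#' Replaces the fixed Hessian by the diagonal matrix whose entries are its row
#' sums: `Htilde_kk = -1/4 * sum_i x_{i,k} * r_i` with `r_i = sum_j x_{i,j}`
#' the per-record row sum. By Gerschgorin's circle theorem (see
#' [loewner_nonneg()]) this diagonal matrix is still a Loewner lower bound of
#' the Hessian whenever all entries of `X` are non-negative, and being diagonal
#' it is invertible entrywise -- the property the encrypted circuit relies on.
#'
#' The row-sum-first evaluation order costs `N*(d+1)` scalar multiplications
#' (linear in `d`), not the `O(N d^2)` of forming `X'X` first; the count is
#' attached as attribute `"n_mults"`.
#'
#' @param data an [dataset()].
#' @return numeric vector of the `d + 1` diagonal entries, with attribute
#'   `n_mults`.
#' @export
simplified_hessian_diag <- function(data) {
  stopifnot(inherits(data, "sfhe_dataset"))
  r <- rowSums(data$X)                     # additions only
  h <- -drop(crossprod(data$X, r)) / 4     # N*(d+1) scalar multiplications
  attr(h, "n_mults") <- data$N * (data$d + 1L)
  h
}

#' Test non-negative definiteness
#'
#' Returns `TRUE` iff the smallest eigenvalue of the symmetric matrix `A` is
#' `>= -tol`. Used to verify Loewner orderings such as
#' `H(beta) >= -X'X/4 >= Htilde`.
#'
#' @param A symmetric numeric matrix.
#' @param tol eigenvalue tolerance (default `1e-9`, appropriate for
#'   double-precision Gram matrices at desk scale).
#' @return logical scalar.
#' @export
loewner_nonneg <- function(A, tol = 1e-9) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 1e-8)) stop("matrix must be symmetric")
  min(eigen(A, symmetric = TRUE, only.values = TRUE)$values) >= -tol
}

#' Division-free reciprocal by Newton iteration
#'
#' Applies `x <- x * (2 - a * x)` `iters` times starting from `x0`. This is
#' Newton's method for `f(x) = 1/x - a`; it converges quadratically to `1/a`
#' iff `0 < a * x0 < 2`, and uses only additions and multiplications, so it can
#' be evaluated under homomorphic encryption. After one step the relative
#' error is exactly `(1 - a*x0)^2`, so any start within 30% of `1/a` yields a
#' reciprocal within 9%.
#'
#' @param a nonzero number to invert.
#' @param x0 start value.
#' @param iters number of iterations (`>= 0`).
#' @return the iterate after `iters` steps (divergence is the caller's
#'   responsibility).
#' @examples
#' invert_scalar_newton(4, 0.2, 1)   # 0.24
#' invert_scalar_newton(5, 0.1, 10)  # ~ 0.2
#' @export
invert_scalar_newton <- function(a, x0, iters = 1L) {
  if (a == 0) stop("cannot invert zero")
  if (iters < 0) stop("iters must be >= 0")
  x <- x0
  for (k in seq_len(iters)) x <- x * (2 - a * x)
  x
}

#' Start value for the Newton reciprocal of the simplified Hessian
#'
#' The diagonal entries of the simplified Hessian scale like
#' `-N * (d+1) * E[x]^2 / 4`, so `x0 = -4 / ((d+1) * N * mu)` lands within the
#' convergence basin of [invert_scalar_newton()] for typical data. `mu` is a
#' per-dataset mean-magnitude constant: 1 for binary covariates, 1/2 for
#' min-max-normalised continuous covariates.
#'
#' When `base` is supplied, `x0` is snapped to `-4 * base^k` with `base^k`
#' the power of the w-NIBNAF base nearest to `|x0|/4`. The encrypted circuit
#' inverts the positive row sums `h = -4 * Htilde` starting from
#' `u0 = |x0|/4`, so this makes `u0` a single signed digit (exact to encode)
#' while the plaintext and encrypted Newton steps stay algebraically
#' identical. The snap changes `x0` by at most a factor `sqrt(base)`, far
#' inside the 30% basin.
#'
#' @param N,d training-set dimensions.
#' @param mu mean-magnitude constant; default 1 (binary-style data).
#' @param base optional w-NIBNAF base for power rounding.
#' @return negative scalar start value for inverting the (negative) diagonal
#'   entries.
#' @export
newton_x0 <- function(N, d, mu = 1, base = NULL) {
  x0 <- -4 / ((d + 1) * N * mu)
  if (!is.null(base)) {
    k <- round(log(abs(x0) / 4) / log(base))
    x0 <- -4 * base^k
  }
  x0
}

#' Train a logistic model with the simplified fixed Hessian method
#'
#' Starting from `beta = 0`, each iteration performs
#' `beta <- beta - Htilde^{-1} grad_taylor(beta)` where `Htilde` is the
#' diagonal simplified Hessian (computed once before the loop, never updated)
#' and `grad_taylor` is the Taylor-linearised gradient. Because `Htilde` is
#' diagonal, the inverse is entrywise; it is either exact (`inversion =
#' "exact"`) or a `inv_iters`-step division-free Newton reciprocal from `x0`
#' (`inversion = "newton"`), the variant the encrypted circuit evaluates.
#'
#' @param data an [dataset()].
#' @param iters number of SFH iterations (`>= 0`; 0 returns the zero model).
#' @param inversion `"exact"` or `"newton"`.
#' @param x0 Newton-reciprocal start value for the diagonal entries (all
#'   entries share one start, as in the encrypted circuit). Default:
#'   [newton_x0()] with `mu` inferred from the data range (1 if all covariates
#'   are 0/1, else 1/2).
#' @param inv_iters Newton-reciprocal iterations (default 1).
#' @return numeric coefficient vector of length `d + 1`, named like the design
#'   columns.
#' @examples
#' d <- dataset(matrix(c(1, 0), 2), c(1, -1))
#' sfh_train(d, iters = 1)   # (0, 1)
#' @export
sfh_train <- function(data, iters = 1L, inversion = c("exact", "newton"),
                      x0 = NULL, inv_iters = 1L) {
  inversion <- match.arg(inversion)
  stopifnot(inherits(data, "sfhe_dataset"))
  if (iters < 0) stop("iters must be >= 0")
  h <- simplified_hessian_diag(data)
  if (any(h == 0))
    stop("zero diagonal entry in the simplified Hessian ",
         "(degenerate all-zero covariate column)")
  hinv <- if (inversion == "exact") {
    1 / h
  } else {
    if (is.null(x0)) {
      binary <- all(data$X[, -1L] %in% c(0, 1))
      x0 <- newton_x0(data$N, data$d, mu = if (binary) 1 else 0.5)
    }
    vapply(h, invert_scalar_newton, numeric(1), x0 = x0, iters = inv_iters)
  }
  beta <- numeric(data$d + 1L)
  for (k in seq_len(iters)) {
    beta <- beta - hinv * gradient(beta, data, mode = "taylor")
  }
  names(beta) <- colnames(data$X)
  beta
}

#' Maximum-likelihood reference fit (IRLS)
#'
#' Exact Newton-Raphson / iteratively reweighted least squares fit of the
#' logistic model, the accuracy oracle against which the SFH approximations
#' are compared. Implemented over `stats::glm.fit` with the binomial family.
#' On (quasi-)separable data the optimiser diverges; coefficients are then
#' capped at `cap` in absolute value with a warning rather than failing,
#' since the SFH trainer itself is well defined there.
#'
#' @param data an [dataset()].
#' @param max_iter IRLS iteration cap.
#' @param tol IRLS convergence tolerance.
#' @param cap absolute coefficient cap applied on non-convergence/separation.
#' @return numeric coefficient vector of length `d + 1`.
#' @export
irls_reference <- function(data, max_iter = 50L, tol = 1e-10, cap = 30) {
  stopifnot(inherits(data, "sfhe_dataset"))
  fit <- suppressWarnings(
    stats::glm.fit(data$X, (data$y + 1) / 2,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol, maxit = max_iter))
  )
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  if (!fit$converged || any(abs(beta) > cap)) {
    warning("IRLS did not converge cleanly (data may be separable); ",
            "capping coefficients at ", cap)
    beta <- pmin(pmax(beta, -cap), cap)
  }
  names(beta) <- colnames(data$X)
  beta
}

#' Predicted class-1 probability and thresholded label
#'
#' `predict_proba()` evaluates the *true* sigmoid of `beta' x` (the Taylor
#' surrogate is a training-circuit device only, never used at prediction
#' time). `classify()` maps a probability to a label: `+1` iff `p >= tau`
#' (boundary inclusive), else `-1`.
#'
#' @param beta coefficient vector of length `d + 1`.
#' @param X either an `sfhe_dataset` or a covariate matrix (`N x d`, no
#'   intercept column) or a single record vector of length `d`.
#' @return `predict_proba`: numeric vector of probabilities in `(0, 1)`.
#' @export
predict_proba <- function(beta, X) {
  if (inherits(X, "sfhe_dataset")) {
    Xd <- X$X
  } else {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    Xd <- cbind(1, as.matrix(X))
  }
  if (ncol(Xd) != length(beta)) stop("dimension mismatch between beta and X")
  sigmoid(drop(Xd %*% beta))
}

#' @rdname predict_proba
#' @param p numeric vector of probabilities.
#' @param tau classification threshold in `(0, 1)`; default 1/2.
#' @return `classify`: integer labels in `{-1, +1}`.
#' @export
classify <- function(p, tau = 0.5) {
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  ifelse(p >= tau, 1, -1)
}

#' Model I/O as key=value text
#'
#' A trained coefficient vector is stored one `name=value` pair per line, with
#' full double precision.
#'
#' @param beta named coefficient vector.
#' @param path file path.
#' @return `write_model`: `path` invisibly; `read_model`: named numeric vector.
#' @export
write_model <- function(beta, path) {
  nm <- names(beta)
  if (is.null(nm)) nm <- c("(Intercept)", paste0("x", seq_len(length(beta) - 1L)))
  writeLines(sprintf("%s=%.17g", nm, as.numeric(beta)), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)
  beta <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
  names(beta) <- vapply(kv, `[`, character(1), 1)
  beta
}
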