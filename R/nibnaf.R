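# Package-local cache for numerically calibrated encoding bases.
.sfhe_cache <- new.env(parent = emptyenv())

# Check the w-spacing property of the greedy expansion in base b on a probe
# set of worst-case inputs. The greedy step is scale-covariant (expanding
# b^k * theta shifts all exponents by k), so probing theta in [1, b) covers
# all magnitudes; midpoints between consecutive powers maximise the remainder.
.greedy_spacing_ok <- function(b, w, n_probe = 129L, max_digits = 24L) {
  logb <- log(b)
  probes <- unique(c((1 + b) / 2, seq(1, b, length.out = n_probe)))
  for (theta in probes) {
    rem <- theta
    prev <- Inf
    for (k in seq_len(max_digits)) {
      if (rem == 0) break
      e <- .nearest_exponent(abs(rem), logb)
      if (is.finite(prev) && e > prev - w) return(FALSE)
      prev <- e
      rem <- rem - sign(rem) * exp(e * logb)
      if (abs(rem) < 1e-200) break
    }
  }
  TRUE
}

# Exponent of the power of b nearest to the positive number v; on an exact
# midpoint the smaller exponent wins (deterministic tie-break).
.nearest_exponent <- function(v, logb) {
  e <- log(v) / logb
  lo <- floor(e)
  if (abs(v - exp(lo * logb)) <= abs(exp((lo + 1) * logb) - v)) lo else lo + 1
}

#' Non-integral base of the w-NIBNAF encoding
#'
#' The greedy signed-digit expansion in a base `1 < b < 2` produces digits in
#' `{-1, 0, 1}`; the sparsity guarantee -- at most one nonzero digit in any
#' window of `w` consecutive exponents -- holds only when `b` is close enough
#' to 1 relative to `w`. This function calibrates such a base numerically: it
#' bisects for the largest base whose greedy expansions satisfy the spacing
#' property on a probe set of worst-case (midpoint) inputs, then backs the
#' result off by a safety factor of 0.85 on `b - 1`. Larger `w` hence smaller
#' `b - 1` gives sparser encodings at the cost of longer expansions.
#'
#' All encoding correctness contracts in this package depend only on the
#' digit-set, spacing and round-trip properties, never on a specific base
#' value. Results are cached per `w`.
#'
#' @param w spacing parameter (positive integer).
#' @return the base, a scalar in `(1, 2)`.
#' @export
nibnaf_base <- function(w) {
  if (w < 1) stop("w must be >= 1")
  key <- paste0("b", w)
  if (!is.null(.sfhe_cache[[key]])) return(.sfhe_cache[[key]])
  lo <- 1 + 1e-9
  hi <- 2 - 1e-9
  if (!.greedy_spacing_ok(lo, w)) stop("no admissible base found for w = ", w)
  if (.greedy_spacing_ok(hi, w)) {
    b_found <- hi
  } else {
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (.greedy_spacing_ok(mid, w)) lo <- mid else hi <- mid
      if (hi - lo < 1e-12) break
    }
    b_found <- lo
  }
  b <- 1 + 0.85 * (b_found - 1)
  .sfhe_cache[[key]] <- b
  b
}

#' Encoding configuration
#'
#' Collects everything the fixed-point layer needs: the spacing parameter `w`
#' and its base `b_w`, the ring degree `D` the encodings must fit in, the
#' plaintext moduli `t_factors` (pairwise coprime; their product is the
#' effective plaintext modulus `t`), and the fractional `precision` (digits at
#' exponents below `-precision` are truncated).
#'
#' The default precision targets an absolute round-trip error below `1e-7`
#' for inputs in `[-1, 1]` -- one decimal order inside the `1e-6` contract --
#' via the tail bound `b^(-precision) / (1 - b^(-w))`.
#'
#' @param w spacing parameter.
#' @param D ring degree (power of two).
#' @param t_factors integer vector of pairwise-coprime plaintext moduli.
#' @param b base override; default [nibnaf_base()] of `w`.
#' @param precision fractional truncation bound; default as above.
#' @return An object of class `sfhe_encoding`.
#' @export
encoding_config <- function(w, D, t_factors, b = NULL, precision = NULL) {
  if (w < 1) stop("w must be >= 1")
  t_factors <- as.numeric(t_factors)
  if (any(t_factors < 2)) stop("plaintext moduli must be >= 2")
  if (length(t_factors) > 1) {
    for (i in seq_along(t_factors)[-1]) for (j in seq_len(i - 1)) {
      a <- t_factors[i]; bb <- t_factors[j]
      while (bb) { r <- a %% bb; a <- bb; bb <- r }
      if (a != 1) stop("plaintext moduli must be pairwise coprime")
    }
  }
  if (is.null(b)) b <- nibnaf_base(w)
  if (b <= 1 || b >= 2) stop("base must lie in (1, 2)")
  if (is.null(precision)) {
    tail_c <- 1 / (1 - b^(-w))
    precision <- ceiling(log(1e7 * tail_c) / log(b))
  }
  structure(list(w = as.integer(w), b = b, D = as.integer(D),
                 t_factors = t_factors, t = prod(t_factors),
                 precision = as.integer(precision)),
            class = "sfhe_encoding")
}

#' @export
print.sfhe_encoding <- function(x, ...) {
  cat(sprintf("<sfhe_encoding> w = %d, b = %.9f, D = %d, t = %s, precision = %d\n",
              x$w, x$b, x$D,
              paste(format(x$t_factors, scientific = FALSE), collapse = " * "),
              x$precision))
  invisible(x)
}

#' Shipped encoding presets
#'
#' `"genomic"` (`w = 715`, `t = 5179 * 5189 * 5197`, `D = 4096`) and
#' `"financial"` (`w = 150`, `t = 2237 * 2239`, `D = 4096`) are the plaintext
#' configurations used with the full-scale scheme parameters for binary and
#' min-max-normalised data respectively; `"toy"` (`w = 6`, single modulus
#' 65537, `D = 256`) is a small configuration for fast tests.
#'
#' @param name preset name.
#' @return An [encoding_config()].
#' @export
encoding_preset <- function(name = c("genomic", "financial", "toy")) {
  name <- match.arg(name)
  switch(name,
    genomic = encoding_config(w = 715, D = 4096, t_factors = c(5179, 5189, 5197)),
    financial = encoding_config(w = 150, D = 4096, t_factors = c(2237, 2239)),
    toy = encoding_config(w = 6, D = 256, t_factors = 65537)
  )
}

#' Greedy w-NIBNAF expansion of a real number
#'
#' Expands `theta` as a sparse signed-digit Laurent polynomial in the base
#' `b_w`: digits in `{-1, 0, 1}`, at most one nonzero digit in any window of
#' `w` consecutive exponents, fractional digits truncated below
#' `-cfg$precision`. Exact zeros encode to the empty digit set; 1 encodes to a
#' single digit at exponent 0.
#'
#' @param theta finite real number.
#' @param cfg an [encoding_config()].
#' @return An object of class `sfhe_digits`: list with integer vector `exp`
#'   (strictly decreasing exponents) and `sign` (values in `{-1, 1}`).
#' @export
nibnaf_encode <- function(theta, cfg) {
  stopifnot(inherits(cfg, "sfhe_encoding"))
  if (!is.finite(theta)) stop("theta must be finite")
  logb <- log(cfg$b)
  exps <- integer(0)
  sgns <- integer(0)
  rem <- theta
  prev <- Inf
  while (rem != 0) {
    e <- .nearest_exponent(abs(rem), logb)
    if (e < -cfg$precision) break
    if (is.finite(prev) && e > prev - cfg$w)
      stop("internal spacing violation; the configured base is not w-safe")
    s <- if (rem > 0) 1L else -1L
    exps <- c(exps, as.integer(e))
    sgns <- c(sgns, s)
    rem <- rem - s * exp(e * logb)
    prev <- e
  }
  if (length(exps) && exps[1] - min(-cfg$precision, exps[length(exps)]) >= cfg$D)
    stop("encoding overflow: exponent span exceeds D - 1")
  structure(list(exp = exps, sign = sgns, b = cfg$b), class = "sfhe_digits")
}

#' @export
print.sfhe_digits <- function(x, ...) {
  if (!length(x$exp)) cat("<sfhe_digits> 0\n")
  else cat("<sfhe_digits>",
           paste(ifelse(x$sign > 0, "+", "-"), "b^", x$exp, sep = "", collapse = " "),
           "\n")
  invisible(x)
}

#' Real value of a digit expansion
#'
#' Evaluates `sum_k sign_k * b^exp_k`, the inverse of [nibnaf_encode()] up to
#' the truncation tail.
#'
#' @param digits an `sfhe_digits` object.
#' @param b base; defaults to the base recorded at encoding time.
#' @return scalar.
#' @export
digits_value <- function(digits, b = digits$b) {
  if (!length(digits$exp)) return(0)
  sum(digits$sign * exp(digits$exp * log(b)))
}

#' Fold a Laurent expansion into the plaintext ring
#'
#' Maps a digit expansion into `Z[X]/(X^D + 1)`: a digit at exponent `e >= 0`
#' lands at position `e`, and a digit at `e < 0` wraps to position `D + e`
#' with its sign flipped, using `X^D = -1` (equivalently `X^{-j} = -X^{D-j}`,
#' so X is invertible in the ring and folding is a ring homomorphism).
#'
#' @param digits an `sfhe_digits` object (or a list with integer `exp` and
#'   `sign`/`coef`).
#' @param D ring degree.
#' @return integer coefficient vector of length `D` (position `j` holds the
#'   coefficient of `X^{j-1}`).
#' @export
laurent_fold <- function(digits, D) {
  coefs <- if (!is.null(digits$sign)) digits$sign else digits$coef
  if (!length(digits$exp)) return(integer(D))
  if (max(digits$exp) - min(digits$exp) >= D)
    stop("exponent span exceeds D - 1: cannot fold")
  if (max(digits$exp) >= D || min(digits$exp) <= -D)
    stop("exponent out of range for degree-", D, " ring")
  poly <- integer(D)
  pos <- ifelse(digits$exp >= 0, digits$exp + 1L, D + digits$exp + 1L)
  if (anyDuplicated(pos))
    stop("digit collision after folding: D too small for this exponent span")
  poly[pos] <- ifelse(digits$exp >= 0, coefs, -coefs)
  poly
}

#' Unfold ring positions back to Laurent exponents
#'
#' Inverse of [laurent_fold()] given the fractional span: the top `frac_span`
#' positions `D - frac_span, ..., D - 1` are interpreted as exponents
#' `-frac_span, ..., -1` (with the sign flip undone); the rest are
#' non-negative exponents.
#'
#' @param poly integer coefficient vector of length `D`.
#' @param frac_span number of top positions that hold fractional digits.
#' @return list with `exp` and `coef` for the nonzero coefficients.
#' @export
laurent_unfold <- function(poly, frac_span) {
  D <- length(poly)
  if (frac_span < 0 || frac_span >= D) stop("frac_span must lie in [0, D)")
  nz <- which(poly != 0)
  pos <- nz - 1L
  neg <- pos >= D - frac_span
  list(exp = ifelse(neg, pos - D, pos),
       coef = ifelse(neg, -poly[nz], poly[nz]))
}

#' Decode a plaintext polynomial to a real number
#'
#' Lifts the (centered) coefficients to signed integers, unfolds the top
#' `frac_span` positions to negative exponents, and evaluates at `b_w`.
#' Coefficients at the modulus boundary are ambiguous in sign after centering
#' and indicate that the effective plaintext modulus `t` was too small for the
#' computation; this is reported as an error rather than decoded silently.
#'
#' @param poly numeric coefficient vector of length `cfg$D`, centered
#'   representatives mod `cfg$t`.
#' @param cfg an [encoding_config()].
#' @param frac_span number of top positions holding fractional (wrap-around)
#'   digits; after homomorphic multiplications the spans of the factors add.
#' @return scalar.
#' @export
nibnaf_decode <- function(poly, cfg, frac_span) {
  stopifnot(inherits(cfg, "sfhe_encoding"))
  if (length(poly) != cfg$D) stop("polynomial has wrong degree")
  bound <- floor(cfg$t / 2)
  if (any(abs(poly) >= bound))
    stop("coefficient at the plaintext modulus boundary: t too small ",
         "for this computation")
  u <- laurent_unfold(poly, frac_span)
  if (!length(u$exp)) return(0)
  sum(u$coef * exp(u$exp * log(cfg$b)))
}

#' Validate the w-NIBNAF digit contracts
#'
#' Checks the two sparsity conditions: every digit in `{-1, 0, 1}` and no two
#' nonzero digits closer than `w` exponent positions.
#'
#' @param digits an `sfhe_digits` object.
#' @param w spacing parameter.
#' @return logical scalar.
#' @export
nibnaf_digits_valid <- function(digits, w) {
  if (!length(digits$exp)) return(TRUE)
  if (!all(digits$sign %in% c(-1L, 1L))) return(FALSE)
  e <- sort(digits$exp, decreasing = TRUE)
  if (anyDuplicated(e)) return(FALSE)
  all(-diff(e) >= w)
}

#' Centered representative mod m
#'
#' Reduces `x` into `(-m/2, m/2]`, the representative convention used for
#' every modulus in the package (plaintext and ciphertext alike).
#'
#' @param x numeric vector of integers.
#' @param m modulus.
#' @return numeric vector of centered representatives.
#' @export
centered_mod <- function(x, m) {
  r <- x %% m
  ifelse(r > m / 2, r - m, r)
}

#' CRT split and join of plaintext polynomials
#'
#' `crt_split()` reduces a polynomial over `Z` (or `Z_t`) coefficient-wise
#' modulo each factor `t_i`, with centered representatives; the training
#' circuit then runs independently in every `R_{t_i}`. `crt_join()` inverts
#' the split by Garner's algorithm, returning centered representatives mod
#' `t = prod(t_factors)`; the round trip is exact for coefficients in
#' `(-t/2, t/2]`.
#'
#' @param poly numeric coefficient vector with integer values.
#' @param t_factors pairwise-coprime moduli.
#' @return `crt_split`: list of coefficient vectors, one per factor;
#'   `crt_join`: a single coefficient vector.
#' @examples
#' crt_split(7, c(3, 5))        # residues 1 and 2
#' crt_join(list(1, 2), c(3, 5))
#' @export
crt_split <- function(poly, t_factors) {
  lapply(t_factors, function(ti) centered_mod(poly, ti))
}

#' @rdname crt_split
#' @param residues list of coefficient vectors as produced by `crt_split`.
#' @export
crt_join <- function(residues, t_factors) {
  n <- length(t_factors)
  if (length(residues) != n) stop("need one residue vector per modulus")
  if (n == 1L) return(centered_mod(residues[[1]], t_factors[1]))
  # Garner: x = v1 + t1*v2 + t1*t2*v3 + ... with v_i mod t_i
  t <- prod(t_factors)
  x <- centered_mod(residues[[1]], t_factors[1]) %% t_factors[1]
  pprod <- t_factors[1]
  for (i in 2:n) {
    ti <- t_factors[i]
    inv <- .modinv(pprod %% ti, ti)
    vi <- ((residues[[i]] - x) * inv) %% ti
    vi <- ((vi %% ti) + ti) %% ti
    x <- x + pprod * vi
    pprod <- pprod * ti
  }
  centered_mod(x, t)
}

# Modular inverse by extended Euclid (scalar, double-precision integers).
.modinv <- function(a, m) {
  a <- a %% m
  t0 <- 0; t1 <- 1; r0 <- m; r1 <- a
  while (r1 != 0) {
    q <- r0 %/% r1
    tmp <- t0 - q * t1; t0 <- t1; t1 <- tmp
    tmp <- r0 - q * r1; r0 <- r1; r1 <- tmp
  }
  if (r0 != 1) stop("not invertible: moduli not coprime")
  t0 %% m
}
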