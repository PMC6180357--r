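#' FV scheme parameters
#'
#' The ciphertext space is `R_q x R_q` with `R_q = Z_q[X]/(X^D + 1)`; the
#' plaintext space is `R_t`. The ciphertext modulus is restricted to a power
#' of two, `q = 2^qbits`, which makes centering a bit mask and the FV
#' scale-and-round `round(t*c/q)` an exact shift; the full-scale parameter
#' set uses `q = 2^186`. The scaling factor is `Delta = floor(q/t)`.
#'
#' Security is a property of `(D, q, sigma)` asserted by configuration; the
#' shipped full-scale set (`D = 4096`, `q = 2^186`, `sigma = 20`) is rated at
#' 78 bits by the standard LWE hardness estimation, and the toy set has no
#' security at all -- it exists for fast testing.
#'
#' @param D power-of-two ring degree (`<= 4096`).
#' @param qbits ciphertext modulus bit size, `q = 2^qbits` (20..192).
#' @param t plaintext modulus (one CRT factor; `2 <= t < 2^31`).
#' @param sigma standard deviation of the discrete-Gaussian error sampler
#'   (rounded continuous Gaussian truncated at `6*sigma`).
#' @param relin_base_bits decomposition base `2^w` of the relinearisation
#'   key-switching (version 1).
#' @return An object of class `sfhe_fv_params` (a validated list).
#' @export
fv_params <- function(D, qbits, t, sigma = 20, relin_base_bits = 32) {
  if (D < 4 || bitwAnd(D, D - 1L) != 0 || D > 4096)
    stop("D must be a power of two in [4, 4096]")
  if (qbits < 20 || qbits > 192) stop("qbits must lie in [20, 192]")
  if (t < 2 || t >= 2^31) stop("t must lie in [2, 2^31)")
  if (t >= 2^qbits) stop("need q >> t")
  structure(list(D = as.integer(D), qbits = as.integer(qbits), t = as.numeric(t),
                 sigma = as.numeric(sigma),
                 relin_base_bits = as.integer(relin_base_bits)),
            class = "sfhe_fv_params")
}

#' @export
print.sfhe_fv_params <- function(x, ...) {
  cat(sprintf("<sfhe_fv_params> D = %d, q = 2^%d, t = %s, sigma = %g, relin base = 2^%d\n",
              x$D, x$qbits, format(x$t, scientific = FALSE), x$sigma,
              x$relin_base_bits))
  invisible(x)
}

#' Shipped scheme parameter presets
#'
#' `"fullscale"` is the full-scale set `D = 4096`, `q = 2^186`, `sigma = 20`
#' (relinearisation base `2^32`), used with the `"genomic"`/`"financial"`
#' encoding presets; `t` defaults to the first genomic CRT factor and is
#' overridden per factor by the pipeline. `"toy"` is a fast set
#' (`D = 256`, `q = 2^140`, `t = 65537`, relinearisation base `2^16`) sized so
#' the four-level training circuit on a few dozen records still decrypts with
#' noise and plaintext-coefficient room to spare.
#'
#' @param name preset name.
#' @param t optional plaintext-modulus override.
#' @return An [fv_params()].
#' @export
fv_params_preset <- function(name = c("fullscale", "toy"), t = NULL) {
  name <- match.arg(name)
  p <- switch(name,
    fullscale = fv_params(D = 4096, qbits = 186, t = 5179, sigma = 20,
                      relin_base_bits = 32),
    toy = fv_params(D = 256, qbits = 140, t = 65537, sigma = 20,
                    relin_base_bits = 16)
  )
  if (!is.null(t)) p$t <- as.numeric(t)
  p
}

.par_list <- function(params) unclass(params)

#' Generate FV key material
#'
#' Samples the secret key `s` from the ternary key distribution (uniform
#' coefficients in `{-1, 0, 1}`), the public key `(b, a)` with `a` uniform in
#' `R_q` and `b = [-(a s + e)]_q`, and the version-1 relinearisation keys
#' `(b_j, a_j)` with `b_j = [-(a_j s + e_j) + 2^(j w) s^2]_q`. Fully
#' deterministic given `seed`.
#'
#' @param params an [fv_params()].
#' @param seed integer seed for the key-generation RNG.
#' @return An object of class `sfhe_fv_keys`.
#' @export
fv_keygen <- function(params, seed = 1) {
  stopifnot(inherits(params, "sfhe_fv_params"))
  ptr <- .fv_keygen_cpp(.par_list(params), as.numeric(seed))
  structure(list(ptr = ptr, params = params, has_sk = TRUE),
            class = "sfhe_fv_keys")
}

#' @export
print.sfhe_fv_keys <- function(x, ...) {
  cat(sprintf("<sfhe_fv_keys> %s D = %d, q = 2^%d, t = %s\n",
              if (x$has_sk) "secret+public+relin," else "evaluation-only (no sk),",
              x$params$D, x$params$qbits,
              format(x$params$t, scientific = FALSE)))
  invisible(x)
}

#' Evaluation-only key material
#'
#' Returns a copy of the key object with the secret key removed: it can
#' encrypt, add and multiply but neither decrypt nor measure noise. This is
#' what an untrusted evaluating server would hold.
#'
#' @param keys an [fv_keygen()] result.
#' @return An `sfhe_fv_keys` without secret key.
#' @export
fv_evaluation_keys <- function(keys) {
  stopifnot(inherits(keys, "sfhe_fv_keys"))
  structure(list(ptr = .fv_strip_sk_cpp(keys$ptr), params = keys$params,
                 has_sk = FALSE),
            class = "sfhe_fv_keys")
}

.as_pt <- function(m, D) {
  m <- as.integer(m)
  if (length(m) == 1L) m <- c(m, integer(D - 1L))
  if (length(m) != D) stop("plaintext must have length D (or be a scalar)")
  m
}

.new_ct <- function(data, params, level) {
  structure(list(data = data, params = params, level = as.integer(level)),
            class = "sfhe_fv_ct")
}

#' @export
print.sfhe_fv_ct <- function(x, ...) {
  cat(sprintf("<sfhe_fv_ct> D = %d, q = 2^%d, t = %s, level = %d\n",
              x$params$D, x$params$qbits,
              format(x$params$t, scientific = FALSE), x$level))
  invisible(x)
}

.check_same_params <- function(a, b) {
  pa <- a$params; pb <- b$params
  if (pa$D != pb$D || pa$qbits != pb$qbits || pa$t != pb$t)
    stop("ciphertext parameter mismatch")
}

#' Encrypt a plaintext polynomial
#'
#' `c0 = Delta*m + b*u + e1`, `c1 = a*u + e2` with `u` ternary and `e1, e2`
#' Gaussian. `m` is an integer coefficient vector of length `D` with centered
#' values mod `t` (a scalar is placed in the constant coefficient).
#' Deterministic given `seed`.
#'
#' @param keys an [fv_keygen()] (secret key not required).
#' @param m integer plaintext polynomial (length `D`) or scalar.
#' @param seed integer seed for the encryption randomness.
#' @return An `sfhe_fv_ct` at level 0.
#' @export
fv_encrypt <- function(keys, m, seed = 1) {
  stopifnot(inherits(keys, "sfhe_fv_keys"))
  m <- .as_pt(m, keys$params$D)
  half <- floor(keys$params$t / 2)
  if (any(abs(m) > half)) stop("plaintext coefficients out of range mod t")
  .new_ct(.fv_encrypt_cpp(keys$ptr, m, as.numeric(seed)), keys$params, 0L)
}

#' Trivial (noiseless) lift of a plaintext to a ciphertext
#'
#' Produces the pair `(Delta*m, 0)`, a valid ciphertext of `m` with zero
#' noise and no randomness. Public constants enter the encrypted training
#' circuit this way, so that multiplying by them is a uniform
#' ciphertext-ciphertext multiplication.
#'
#' @param params an [fv_params()].
#' @param m integer plaintext polynomial or scalar.
#' @return An `sfhe_fv_ct` at level 0.
#' @export
fv_lift <- function(params, m) {
  stopifnot(inherits(params, "sfhe_fv_params"))
  .new_ct(.fv_lift_cpp(.par_list(params), .as_pt(m, params$D)), params, 0L)
}

#' Decrypt a ciphertext
#'
#' Computes `[c0 + c1 s]_q`, scales by `t/q` and rounds, reducing into
#' centered representatives mod `t`. Exact while the noise satisfies
#' `||e||_inf < Delta/2` (see [fv_noise_budget()]); beyond that the result is
#' silently wrong -- callers that care use the noise budget as the guard.
#'
#' @param keys key material including the secret key.
#' @param ct an `sfhe_fv_ct`.
#' @return integer plaintext polynomial (centered mod `t`).
#' @export
fv_decrypt <- function(keys, ct) {
  stopifnot(inherits(keys, "sfhe_fv_keys"), inherits(ct, "sfhe_fv_ct"))
  if (!keys$has_sk) stop("decryption requires the secret key")
  .fv_decrypt_cpp(keys$ptr, ct$data)
}

#' Homomorphic addition, subtraction, negation
#'
#' Componentwise polynomial operations mod `q`; noise adds. The level of the
#' result is the maximum of the operand levels.
#'
#' @param a,b ciphertexts with identical parameters.
#' @return An `sfhe_fv_ct`.
#' @export
fv_add <- function(a, b) {
  stopifnot(inherits(a, "sfhe_fv_ct"), inherits(b, "sfhe_fv_ct"))
  .check_same_params(a, b)
  .new_ct(.fv_add_cpp(.par_list(a$params), a$data, b$data), a$params,
          max(a$level, b$level))
}

#' @rdname fv_add
#' @export
fv_sub <- function(a, b) fv_add(a, fv_neg(b))

#' @rdname fv_add
#' @export
fv_neg <- function(a) {
  stopifnot(inherits(a, "sfhe_fv_ct"))
  .new_ct(.fv_neg_cpp(.par_list(a$params), a$data), a$params, a$level)
}

#' Homomorphic multiplication
#'
#' `fv_mul()` is the FV tensor multiplication: the exact integer tensor of
#' the two ciphertext pairs is scaled by `t/q` and rounded, and the quadratic
#' component is relinearised back to two components with the base-`2^w`
#' key-switching keys. The result's `level` (count of ciphertext-ciphertext
#' multiplications on its critical path) increments. `fv_pt_mul()` multiplies
#' by a plaintext polynomial directly -- no relinearisation, no level
#' increase.
#'
#' @param a,b ciphertexts.
#' @param keys key material carrying the relinearisation keys (secret key not
#'   required).
#' @return An `sfhe_fv_ct`.
#' @export
fv_mul <- function(a, b, keys) {
  stopifnot(inherits(a, "sfhe_fv_ct"), inherits(b, "sfhe_fv_ct"),
            inherits(keys, "sfhe_fv_keys"))
  .check_same_params(a, b)
  .new_ct(.fv_mul_cpp(keys$ptr, a$data, b$data), a$params,
          max(a$level, b$level) + 1L)
}

#' @rdname fv_mul
#' @param m integer plaintext polynomial or scalar.
#' @export
fv_pt_mul <- function(a, m) {
  stopifnot(inherits(a, "sfhe_fv_ct"))
  .new_ct(.fv_pt_mul_cpp(.par_list(a$params), a$data, .as_pt(m, a$params$D)),
          a$params, a$level)
}

#' Remaining noise budget of a ciphertext, in bits
#'
#' `log2(Delta / (2 * ||e||_inf))` where `e = [c0 + c1 s]_q - Delta*m` is the
#' noise component. Decryption is exact while the budget is positive; every
#' homomorphic operation spends budget (multiplication heavily, addition
#' barely).
#'
#' @param keys key material including the secret key.
#' @param ct an `sfhe_fv_ct`.
#' @return scalar bits (capped at `log2(Delta) - 1` for noiseless inputs).
#' @export
fv_noise_budget <- function(keys, ct) {
  stopifnot(inherits(keys, "sfhe_fv_keys"), inherits(ct, "sfhe_fv_ct"))
  if (!keys$has_sk) stop("noise measurement requires the secret key")
  .fv_noise_budget_cpp(keys$ptr, ct$data)
}

#' Bit-packed ciphertext serialisation
#'
#' `fv_pack()` writes the two component polynomials at exactly `qbits` bits
#' per coefficient, little-endian bit order: the payload is exactly
#' `2 * D * qbits` bits, the storage cost of a ciphertext (about 186 kB for
#' the full-scale parameter set). `fv_unpack()` inverts it bit-exactly given
#' the parameters and level.
#'
#' @param ct an `sfhe_fv_ct`.
#' @return `fv_pack`: a raw vector of `2 * D * qbits / 8` bytes.
#' @export
fv_pack <- function(ct) {
  stopifnot(inherits(ct, "sfhe_fv_ct"))
  .fv_pack_cpp(.par_list(ct$params), ct$data)
}

#' @rdname fv_pack
#' @param payload raw vector from `fv_pack`.
#' @param params an [fv_params()].
#' @param level multiplicative level of the packed ciphertext.
#' @export
fv_unpack <- function(payload, params, level = 0L) {
  stopifnot(inherits(params, "sfhe_fv_params"))
  .new_ct(.fv_unpack_cpp(.par_list(params), payload), params, level)
}

#' Ciphertext and key file I/O
#'
#' Ciphertext files carry a short header (magic, D, qbits, t, level) followed
#' by the bit-packed payload of [fv_pack()]; key files serialise the
#' parameters and the raw key polynomials. Both round-trip bit-exactly.
#'
#' @param ct an `sfhe_fv_ct`.
#' @param path file path.
#' @return the read object, or `path` invisibly for writers.
#' @export
write_ciphertext <- function(ct, path) {
  stopifnot(inherits(ct, "sfhe_fv_ct"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SFHECT1\n"), con)
  writeBin(as.integer(c(ct$params$D, ct$params$qbits, ct$level,
                        ct$params$relin_base_bits)), con, size = 4L)
  writeBin(c(ct$params$t, ct$params$sigma), con, size = 8L)
  writeBin(fv_pack(ct), con)
  invisible(path)
}

#' @rdname write_ciphertext
#' @export
read_ciphertext <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(rawToChar(magic), "SFHECT1\n"))
    stop("not an sfhe ciphertext file: ", path)
  ints <- readBin(con, "integer", 4L, size = 4L)
  dbls <- readBin(con, "double", 2L, size = 8L)
  params <- fv_params(D = ints[1], qbits = ints[2], t = dbls[1],
                      sigma = dbls[2], relin_base_bits = ints[4])
  nbytes <- 2 * params$D * params$qbits / 8
  payload <- readBin(con, "raw", nbytes)
  if (length(payload) != nbytes) stop("truncated ciphertext file: ", path)
  fv_unpack(payload, params, level = ints[3])
}

#' @rdname write_ciphertext
#' @param keys an `sfhe_fv_keys`.
#' @param with_sk include the secret key in the file (default `TRUE`).
#' @export
write_keys <- function(keys, path, with_sk = TRUE) {
  stopifnot(inherits(keys, "sfhe_fv_keys"))
  writeBin(.fv_keys_serialize_cpp(keys$ptr, with_sk), path)
  invisible(path)
}

#' @rdname write_ciphertext
#' @export
read_keys <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  ptr <- .fv_keys_deserialize_cpp(raw)
  info <- .fv_params_of_cpp(ptr)
  params <- fv_params(D = info$D, qbits = info$qbits, t = info$t,
                      sigma = info$sigma, relin_base_bits = info$relin_base_bits)
  structure(list(ptr = ptr, params = params, has_sk = isTRUE(info$has_sk)),
            class = "sfhe_fv_keys")
}

#' Exact negacyclic ring product mod t
#'
#' Multiplies two integer coefficient vectors in `Z_t[X]/(X^D + 1)` with
#' centered representatives -- plaintext-side ring arithmetic used by the
#' reference circuit evaluator.
#'
#' @param a,b integer coefficient vectors of equal power-of-two length.
#' @param t modulus.
#' @return integer coefficient vector, centered mod `t`.
#' @export
ring_mul <- function(a, b, t) {
  .ring_mul_cpp(as.integer(a), as.integer(b), as.numeric(t))
}

#' @rdname ring_mul
#' @export
ring_add <- function(a, b, t) {
  centered_mod(as.numeric(a) + as.numeric(b), t)
}
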