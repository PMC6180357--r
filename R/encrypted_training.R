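#' Per-CRT-factor key material
#'
#' The plaintext modulus `t` only enters key generation through the scaling
#' factor `Delta` used at encryption time; the key polynomials themselves
#' depend on `(D, q, sigma)` and the seed. One logical key pair therefore
#' serves every CRT factor: this helper instantiates, from a single seed, one
#' key object per factor that share identical key polynomials and differ only
#' in `t`.
#'
#' @param params an [fv_params()] (its `t` is ignored).
#' @param t_factors pairwise-coprime plaintext moduli.
#' @param seed key-generation seed.
#' @return list of [fv_keygen()] objects, one per factor.
#' @export
fv_keygen_crt <- function(params, t_factors, seed = 1) {
  lapply(t_factors, function(ti) {
    p <- params
    p$t <- as.numeric(ti)
    fv_keygen(p, seed = seed)
  })
}

#' Encode a dataset as plaintext ring elements
#'
#' Applies the w-NIBNAF encoding to every covariate value and label and folds
#' the expansions into `Z[X]/(X^D + 1)`. Labels (`+-1`) and binary covariates
#' are single-digit encodings at exponent 0, hence exact; continuous values
#' truncate at the configured precision. The all-ones intercept column is
#' public and is not encoded (the circuit injects it as a trivial constant).
#'
#' @param data an [dataset()].
#' @param cfg an [encoding_config()].
#' @return list with `x` (list of `N` lists of `d` integer coefficient
#'   vectors), `y` (list of `N` vectors), `emin`/`emax` (exponent span over
#'   all encodings) and `binary` (flag: all covariates in `{0,1}`).
#' @export
encode_dataset <- function(data, cfg) {
  stopifnot(inherits(data, "sfhe_dataset"), inherits(cfg, "sfhe_encoding"))
  emin <- 0L; emax <- 0L
  enc1 <- function(v) {
    dg <- nibnaf_encode(v, cfg)
    if (length(dg$exp)) {
      emin <<- min(emin, min(dg$exp))
      emax <<- max(emax, max(dg$exp))
    }
    laurent_fold(dg, cfg$D)
  }
  Xc <- data$X[, -1L, drop = FALSE]
  x <- lapply(seq_len(data$N), function(i)
    lapply(seq_len(data$d), function(j) enc1(Xc[i, j])))
  y <- lapply(seq_len(data$N), function(i) enc1(data$y[i]))
  list(x = x, y = y, emin = emin, emax = emax,
       binary = all(Xc %in% c(0, 1)))
}

#' Encrypt a dataset for SFH training
#'
#' Encodes every covariate and label ([encode_dataset()]), reduces each
#' encoding modulo every CRT factor of the plaintext modulus, and encrypts
#' each residue polynomial: the record-wise layout stores `T * (d+1) * N`
#' ciphertexts (`d` covariates plus the label per record and CRT factor; the
#' public intercept column is never encrypted). The serialized size is
#' `T * (d+1) * N * 2 * D * log2(q)` bits.
#'
#' @param data an [dataset()].
#' @param cfg an [encoding_config()].
#' @param keys list of per-factor key objects from [fv_keygen_crt()]
#'   (a secret key is not required).
#' @param seed base seed; each value's encryption randomness is derived from
#'   it deterministically.
#' @return An object of class `sfhe_enc_dataset` with fields `cts` (per
#'   factor: `x[[i]][[j]]` and `y[[i]]` ciphertexts) and `manifest`.
#' @export
encrypt_dataset <- function(data, cfg, keys, seed = 1) {
  stopifnot(inherits(data, "sfhe_dataset"), inherits(cfg, "sfhe_encoding"))
  if (!is.list(keys) || !all(vapply(keys, inherits, TRUE, "sfhe_fv_keys")))
    stop("keys must be a list of sfhe_fv_keys (one per CRT factor)")
  Tn <- length(cfg$t_factors)
  if (length(keys) != Tn) stop("need one key object per CRT factor")
  for (f in seq_len(Tn)) {
    if (keys[[f]]$params$t != cfg$t_factors[f])
      stop("key ", f, " has plaintext modulus ", keys[[f]]$params$t,
           " but the encoding expects ", cfg$t_factors[f])
    if (keys[[f]]$params$D != cfg$D) stop("ring degree mismatch: keys vs encoding")
  }
  enc <- encode_dataset(data, cfg)
  ctr <- 0L
  nxt <- function() { ctr <<- ctr + 1L; seed * 2^20 + ctr }
  cts <- lapply(seq_len(Tn), function(f) {
    ti <- cfg$t_factors[f]
    kf <- keys[[f]]
    list(
      x = lapply(enc$x, function(row)
        lapply(row, function(p) fv_encrypt(kf, centered_mod(p, ti), seed = nxt()))),
      y = lapply(enc$y, function(p)
        fv_encrypt(kf, centered_mod(p, ti), seed = nxt()))
    )
  })
  par <- keys[[1]]$params
  n_ct <- Tn * (data$d + 1L) * data$N
  manifest <- list(N = data$N, d = data$d, T = Tn,
                   t_factors = cfg$t_factors, D = par$D, qbits = par$qbits,
                   layout = "record-wise",
                   n_ct = n_ct,
                   size_bits = encrypted_size_bits(Tn, data$d, data$N,
                                                   par$D, par$qbits),
                   emin = enc$emin, emax = enc$emax, binary = enc$binary,
                   cfg = cfg)
  structure(list(cts = cts, manifest = manifest), class = "sfhe_enc_dataset")
}

#' @export
print.sfhe_enc_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<sfhe_enc_dataset> N = %d, d = %d, T = %d factors, ",
                     "%d ciphertexts, %.1f MB\n"),
              m$N, m$d, m$T, m$n_ct, m$size_bits / 8 / 2^20))
  invisible(x)
}

#' Closed-form encrypted-dataset size
#'
#' `T * (d+1) * N * 2 * D * log2(q)` bits: `T` CRT factors, `d+1` ciphertexts
#' per record (d covariates and the label), `N` records, two degree-`D`
#' polynomials of `log2(q)`-bit coefficients per ciphertext.
#'
#' @param T number of CRT factors.
#' @param d covariate count.
#' @param N record count.
#' @param D ring degree.
#' @param qbits ciphertext modulus bits.
#' @return size in bits.
#' @export
encrypted_size_bits <- function(T, d, N, D, qbits) {
  T * (d + 1) * N * 2 * D * qbits
}

# ---------------------------------------------------------------------------
# Dual-backend circuit driver. The SFH iteration is written once against a
# tiny evaluator interface (lift/add/sub/mul); the "fv" backend runs it on
# ciphertexts, the "rt" backend on plaintext ring elements mod one CRT
# factor. Both see identical topology, so the rt run is the coefficient-exact
# reference for the encrypted run.

.ev_fv <- function(keys) {
  par <- keys$params
  list(lift = function(p) fv_lift(par, p),
       add = fv_add, sub = fv_sub,
       mul = function(a, b) fv_mul(a, b, keys))
}
.ev_rt <- function(ti, D) {
  list(lift = function(p) as.integer(centered_mod(p, ti)),
       add = function(a, b) as.integer(ring_add(a, b, ti)),
       sub = function(a, b) as.integer(ring_add(a, -b, ti)),
       mul = function(a, b) ring_mul(a, b, ti))
}

# value wrapper carrying Laurent-exponent span and multiplicative depth
.vw <- function(v, emin, emax, lvl) list(v = v, emin = emin, emax = emax, lvl = lvl)

# one run of the SFH circuit on pre-encoded inputs under evaluator `ev`;
# `ctr` is an environment collecting the instrumentation
.sfh_circuit <- function(xp, yp, spans, ev, N, d, u0_exp, iters, ctr, D) {
  vadd <- function(a, b) {
    ctr$ct_adds <- ctr$ct_adds + 1L
    .vw(ev$add(a$v, b$v), min(a$emin, b$emin), max(a$emax, b$emax),
        max(a$lvl, b$lvl))
  }
  vsub <- function(a, b) {
    ctr$ct_adds <- ctr$ct_adds + 1L
    .vw(ev$sub(a$v, b$v), min(a$emin, b$emin), max(a$emax, b$emax),
        max(a$lvl, b$lvl))
  }
  vmul <- function(a, b) {
    ctr$ct_mult_ops <- ctr$ct_mult_ops + 1L
    .vw(ev$mul(a$v, b$v), a$emin + b$emin, a$emax + b$emax,
        max(a$lvl, b$lvl) + 1L)
  }
  stage <- function() ctr$ct_mults <- ctr$ct_mults + 1L
  lift_int <- function(k) {
    p <- integer(D); p[1] <- k
    .vw(ev$lift(p), 0L, 0L, 0L)
  }
  lift_digit <- function(e) { # single +1 digit at exponent e
    p <- laurent_fold(list(exp = as.integer(e), sign = 1L), D)
    .vw(ev$lift(p), min(e, 0L), max(e, 0L), 0L)
  }
  emn <- as.integer(spans$emin)
  emx <- as.integer(spans$emax)
  x <- lapply(seq_len(N), function(i) lapply(seq_len(d), function(j)
    .vw(xp[[i]][[j]], emn, emx, 0L)))
  y <- lapply(seq_len(N), function(i) .vw(yp[[i]], 0L, 0L, 0L))
  one <- lift_int(1L)
  two <- lift_int(2L)

  if (iters == 0L) {
    zero <- lift_int(0L)
    beta <- rep(list(zero), d + 1L)
  } else {
    # record row sums r_i = 1 + sum_j x_ij  (ciphertext additions only)
    r <- lapply(x, function(row) Reduce(vadd, row, one))
    # stage 1: diagonal row-sum products h_k = sum_i x_ik r_i  (h = -4*Htilde)
    stage()
    h <- vector("list", d + 1L)
    h[[1]] <- Reduce(vadd, r)
    for (k in seq_len(d))
      h[[k + 1]] <- Reduce(vadd, lapply(seq_len(N), function(i) vmul(x[[i]][[k]], r[[i]])))
    # stage 2: gradient kernel G_k = sum_i y_i x_ik
    stage()
    G <- vector("list", d + 1L)
    G[[1]] <- Reduce(vadd, y)
    for (k in seq_len(d))
      G[[k + 1]] <- Reduce(vadd, lapply(seq_len(N), function(i) vmul(y[[i]], x[[i]][[k]])))
    g2 <- lapply(G, function(Gk) vadd(Gk, Gk)) # 2G (exact integer doubling)
    # stages 3-4: one division-free Newton step for 1/h_k from the public
    # start u0 = b^u0_exp, entering as a trivially lifted ciphertext
    u0 <- lift_digit(u0_exp)
    stage()
    u <- lapply(h, function(hk) vmul(hk, u0))
    stage()
    inv <- lapply(u, function(uk) vmul(u0, vsub(two, uk)))
    beta <- NULL
    for (it in seq_len(iters)) {
      if (it == 1L) {
        # at beta = 0 the Taylor gradient is G/2; the model update
        # -Htilde^{-1} grad = inv * 2G folds all scalar constants into
        # the exact integer 2  (stage 5)
        stage()
        beta <- mapply(function(ik, gk) vmul(ik, gk), inv, g2, SIMPLIFY = FALSE)
      } else {
        # general iteration: grad_taylor = G/2 - (X'X) beta / 4, update
        # beta + inv * (2G - M) with M_k = sum_i x_ik (x_i' beta)
        stage()
        s <- lapply(seq_len(N), function(i)
          Reduce(vadd, lapply(seq_len(d), function(k) vmul(beta[[k + 1]], x[[i]][[k]])),
                 beta[[1]]))
        stage()
        M <- vector("list", d + 1L)
        M[[1]] <- Reduce(vadd, s)
        for (k in seq_len(d))
          M[[k + 1]] <- Reduce(vadd, lapply(seq_len(N), function(i) vmul(x[[i]][[k]], s[[i]])))
        stage()
        beta <- mapply(function(bk, ik, gk, mk) vadd(bk, vmul(ik, vsub(gk, mk))),
                       beta, inv, g2, M, SIMPLIFY = FALSE)
      }
    }
  }
  ctr$max_level <- max(vapply(beta, function(b) as.integer(b$lvl), integer(1)))
  beta
}

.new_ctr <- function() {
  ctr <- new.env(parent = emptyenv())
  ctr$ct_mults <- 0L; ctr$ct_mult_ops <- 0L
  ctr$ct_adds <- 0L; ctr$pt_mults <- 0L; ctr$max_level <- 0L
  ctr
}

.report_of <- function(ctr, factors) {
  structure(list(ct_mults = ctr$ct_mults, ct_mult_ops = ctr$ct_mult_ops,
                 ct_adds = ctr$ct_adds, pt_mults = ctr$pt_mults,
                 max_level = ctr$max_level, factors = factors),
            class = "sfhe_circuit_report")
}

#' @export
print.sfhe_circuit_report <- function(x, ...) {
  cat("<sfhe_circuit_report>\n")
  cat(sprintf("  ct-ct multiplication stages : %d\n", x$ct_mults))
  cat(sprintf("  ct-ct multiplication ops    : %d (x %d CRT factors)\n",
              x$ct_mult_ops, x$factors))
  cat(sprintf("  ciphertext additions        : %d\n", x$ct_adds))
  cat(sprintf("  plaintext multiplications   : %d\n", x$pt_mults))
  cat(sprintf("  multiplicative depth        : %d\n", x$max_level))
  invisible(x)
}

# resolve the Newton start for a dataset shape; returns list(x0, u0_exp)
.resolve_x0 <- function(x0, N, d, binary, b) {
  if (is.null(x0)) x0 <- newton_x0(N, d, mu = if (binary) 1 else 0.5, base = b)
  u0 <- abs(x0) / 4
  u0_exp <- round(log(u0) / log(b))
  if (abs(u0 - b^u0_exp) > 1e-9 * u0)
    stop("x0/(-4) must be a power of the encoding base; ",
         "use newton_x0(..., base = cfg$b)")
  list(x0 = -4 * b^u0_exp, u0_exp = as.integer(u0_exp))
}

#' Run SFH training iterations on an encrypted dataset
#'
#' Evaluates the simplified fixed Hessian update as an arithmetic circuit on
#' ciphertexts, independently for every CRT factor. The first iteration
#' consists of exactly five ciphertext-ciphertext multiplication stages (a
#' stage applied elementwise across coordinates counts once):
#' row-sum products `h_k = sum_i x_ik r_i`, gradient kernel
#' `G_k = sum_i y_i x_ik`, the two multiplications of the division-free
#' Newton reciprocal `inv = u0 (2 - h u0)`, and the model update
#' `beta = inv * 2G`. All scalar constants are exact: small integers embed as
#' constant polynomials and the public Newton start `u0` is a single
#' signed digit of the encoding base, entering as a trivially lifted
#' ciphertext. Each further iteration re-linearises the Taylor gradient
#' around the current model and costs three more stages; the diagonal
#' Hessian bound and its approximate inverse are never recomputed.
#'
#' @param enc an [encrypt_dataset()] result.
#' @param keys per-factor key list from [fv_keygen_crt()] (relinearisation
#'   keys required; the secret key is not).
#' @param iters number of SFH iterations (0 returns an encryption of the zero
#'   model; the shipped parameter sets support one iteration, after which the
#'   noise budget of deeper iterations must be checked by the caller).
#' @param x0 Newton-reciprocal start value (negative, for the Hessian
#'   diagonal); `-x0/4` must be a power of the encoding base. Default:
#'   [newton_x0()] with `mu` inferred from the data and `base = cfg$b`.
#' @return An object of class `sfhe_enc_model`: per-factor encrypted
#'   coefficients, span metadata for decoding, the `x0` used, and the
#'   [print.sfhe_circuit_report()] instrumentation.
#' @export
encrypted_sfh_iteration <- function(enc, keys, iters = 1L, x0 = NULL) {
  stopifnot(inherits(enc, "sfhe_enc_dataset"))
  m <- enc$manifest
  if (length(keys) != m$T) stop("need one key object per CRT factor")
  cfg <- m$cfg
  st <- .resolve_x0(x0, m$N, m$d, m$binary, cfg$b)
  beta_cts <- vector("list", m$T)
  spans <- NULL
  report <- NULL
  for (f in seq_len(m$T)) {
    ctr <- .new_ctr()
    ev <- .ev_fv(keys[[f]])
    xp <- lapply(enc$cts[[f]]$x, function(row) row)
    yp <- enc$cts[[f]]$y
    beta <- .sfh_circuit(xp, yp, list(emin = m$emin, emax = m$emax), ev,
                         m$N, m$d, st$u0_exp, iters, ctr, m$D)
    beta_cts[[f]] <- lapply(beta, `[[`, "v")
    spans <- list(emin = min(vapply(beta, function(b) as.integer(b$emin), integer(1))),
                  emax = max(vapply(beta, function(b) as.integer(b$emax), integer(1))))
    report <- .report_of(ctr, m$T)
  }
  structure(list(beta = beta_cts, spans = spans, report = report,
                 x0 = st$x0, u0_exp = st$u0_exp, cfg = cfg,
                 N = m$N, d = m$d, t_factors = m$t_factors),
            class = "sfhe_enc_model")
}

#' @export
print.sfhe_enc_model <- function(x, ...) {
  cat(sprintf("<sfhe_enc_model> d+1 = %d encrypted coefficients x %d CRT factors\n",
              length(x$beta[[1]]), length(x$beta)))
  print(x$report)
  invisible(x)
}

#' Decrypt and decode a trained model
#'
#' Decrypts every coefficient ciphertext per CRT factor, recombines the
#' residues by the Chinese remainder theorem, and decodes the resulting
#' plaintext polynomials at the encoding base using the fractional span
#' propagated through the circuit. Fails loudly if any recombined
#' coefficient sits at the modulus boundary (plaintext modulus too small).
#'
#' @param keys per-factor key list including secret keys.
#' @param model an [encrypted_sfh_iteration()] result.
#' @return numeric coefficient vector of length `d + 1`.
#' @export
decrypt_model <- function(keys, model) {
  stopifnot(inherits(model, "sfhe_enc_model"))
  Tn <- length(model$t_factors)
  if (length(keys) != Tn) stop("need one key object per CRT factor")
  cfg <- model$cfg
  frac_span <- max(0L, -model$spans$emin)
  if (model$spans$emax >= cfg$D - frac_span)
    stop("positive and fractional exponent ranges overlap: D too small")
  beta <- vapply(seq_along(model$beta[[1]]), function(k) {
    residues <- lapply(seq_len(Tn), function(f)
      fv_decrypt(keys[[f]], model$beta[[f]][[k]]))
    joined <- crt_join(residues, model$t_factors)
    nibnaf_decode(joined, cfg, frac_span)
  }, numeric(1))
  names(beta) <- c("(Intercept)", paste0("x", seq_len(length(beta) - 1L)))
  beta
}

#' Fixed-point reference of the encrypted computation
#'
#' Runs the identical SFH circuit on the *encoded plaintexts* in
#' `R_{t_i}` for every CRT factor (no encryption involved), recombines and
#' decodes. This is the value the encrypted pipeline reproduces exactly,
#' coefficient for coefficient, whenever the noise budget stays positive --
#' useful both as a test oracle and to predict fixed-point behaviour without
#' paying for encryption.
#'
#' @param data an [dataset()].
#' @param cfg an [encoding_config()].
#' @inheritParams encrypted_sfh_iteration
#' @return list with `beta` (decoded numeric vector), `polys` (per-factor
#'   ring-element coefficients of each beta), `report`, `spans`, `x0`.
#' @export
rt_sfh_iteration <- function(data, cfg, iters = 1L, x0 = NULL) {
  stopifnot(inherits(data, "sfhe_dataset"), inherits(cfg, "sfhe_encoding"))
  enc <- encode_dataset(data, cfg)
  st <- .resolve_x0(x0, data$N, data$d, enc$binary, cfg$b)
  Tn <- length(cfg$t_factors)
  polys <- vector("list", Tn)
  spans <- NULL; report <- NULL
  for (f in seq_len(Tn)) {
    ti <- cfg$t_factors[f]
    ctr <- .new_ctr()
    ev <- .ev_rt(ti, cfg$D)
    xp <- lapply(enc$x, function(row) lapply(row, function(p) ev$lift(p)))
    yp <- lapply(enc$y, function(p) ev$lift(p))
    beta <- .sfh_circuit(xp, yp, list(emin = enc$emin, emax = enc$emax), ev,
                         data$N, data$d, st$u0_exp, iters, ctr, cfg$D)
    polys[[f]] <- lapply(beta, `[[`, "v")
    spans <- list(emin = min(vapply(beta, function(b) as.integer(b$emin), integer(1))),
                  emax = max(vapply(beta, function(b) as.integer(b$emax), integer(1))))
    report <- .report_of(ctr, Tn)
  }
  frac_span <- max(0L, -spans$emin)
  if (spans$emax >= cfg$D - frac_span)
    stop("positive and fractional exponent ranges overlap: D too small")
  beta <- vapply(seq_along(polys[[1]]), function(k) {
    joined <- crt_join(lapply(polys, `[[`, k), cfg$t_factors)
    nibnaf_decode(joined, cfg, frac_span)
  }, numeric(1))
  names(beta) <- c("(Intercept)", paste0("x", seq_len(length(beta) - 1L)))
  list(beta = beta, polys = polys, report = report, spans = spans, x0 = st$x0)
}
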