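#' Experiment configuration
#'
#' Describes one reproducible train/evaluate run: where the data comes from
#' (a CSV path or the synthetic generator), how it is split, which scheme and
#' encoding presets to use, how many SFH iterations to run, and whether to
#' run the encrypted pipeline alongside the plaintext one. Every random
#' choice downstream is derived from the seeds recorded here.
#'
#' @param data_path CSV path, or `NULL` to use the synthetic generator.
#' @param N,d,kind,beta_true synthetic-generator parameters (ignored when
#'   `data_path` is given); `beta_true = NULL` draws a moderate-norm vector
#'   via [gen_beta_true()].
#' @param n_train training records; the rest are the test set.
#' @param shuffle_seed seed of the split permutation (`NULL`: keep row order,
#'   first `n_train` rows train).
#' @param scheme,encoding preset names ([fv_params_preset()],
#'   [encoding_preset()]); used only when `encrypted = TRUE`.
#' @param encrypted also run the encrypted pipeline (costly at the full-scale
#'   preset).
#' @param iters SFH iterations for the plaintext trainer (the encrypted run
#'   always performs one iteration).
#' @param tau classification threshold.
#' @param seed master seed (data generation, key generation, encryption).
#' @return An object of class `sfhe_run_config`.
#' @export
run_config <- function(data_path = NULL, N = 1000, d = 10,
                       kind = c("binary", "continuous"), beta_true = NULL,
                       n_train = NULL, shuffle_seed = NULL,
                       scheme = c("toy", "fullscale"),
                       encoding = c("toy", "genomic", "financial"),
                       encrypted = FALSE, iters = 1L, tau = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  scheme <- match.arg(scheme)
  encoding <- match.arg(encoding)
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  if (iters < 1) stop("iters must be >= 1")
  structure(list(data_path = data_path, N = N, d = d, kind = kind,
                 beta_true = beta_true, n_train = n_train,
                 shuffle_seed = shuffle_seed, scheme = scheme,
                 encoding = encoding, encrypted = encrypted,
                 iters = as.integer(iters), tau = tau, seed = as.integer(seed)),
            class = "sfhe_run_config")
}

#' Run a full plaintext-vs-encrypted training comparison
#'
#' Loads or generates the dataset, splits it, trains the SFH model (exact and
#' Newton-inverse variants), the IRLS maximum-likelihood reference, and
#' optionally the encrypted pipeline on the same training split; evaluates
#' every model on the test split by AUC. When `out_dir` is given, the report,
#' the models, and the ROC sweeps are written as plain text files.
#'
#' @param cfg an [run_config()].
#' @param out_dir optional output directory.
#' @return An object of class `sfhe_report`: a list with the trained
#'   coefficient vectors, test AUCs, AUC differences against the IRLS
#'   reference, the circuit report (if encrypted), and the seed manifest.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sfhe_run_config"))
  if (!is.null(cfg$data_path)) {
    data <- read_dataset(cfg$data_path)
  } else {
    beta_true <- cfg$beta_true
    if (is.null(beta_true)) beta_true <- gen_beta_true(cfg$d, cfg$kind, seed = cfg$seed)
    data <- gen_synthetic(cfg$N, cfg$d, cfg$kind, beta_true, seed = cfg$seed)
  }
  n_train <- if (is.null(cfg$n_train)) floor(data$N * 0.7) else cfg$n_train
  if (n_train >= data$N) stop("n_train must leave at least one test record")
  sp <- train_test_split(data, n_train, shuffle_seed = cfg$shuffle_seed)

  beta_sfh <- sfh_train(sp$train, iters = cfg$iters, inversion = "exact")
  enc_cfg <- encoding_preset(cfg$encoding)
  x0 <- newton_x0(sp$train$N, sp$train$d,
                  mu = if (all(sp$train$X[, -1] %in% c(0, 1))) 1 else 0.5,
                  base = enc_cfg$b)
  beta_newton <- sfh_train(sp$train, iters = cfg$iters, inversion = "newton", x0 = x0)
  beta_irls <- irls_reference(sp$train)

  auc_of <- function(beta) roc_auc(predict_proba(beta, sp$test), sp$test$y)
  roc_sfh <- auc_of(beta_sfh)
  roc_newton <- auc_of(beta_newton)
  roc_irls <- auc_of(beta_irls)

  enc_part <- NULL
  if (cfg$encrypted) {
    params <- fv_params_preset(cfg$scheme)
    keys <- fv_keygen_crt(params, enc_cfg$t_factors, seed = cfg$seed + 1L)
    enc <- encrypt_dataset(sp$train, enc_cfg, keys, seed = cfg$seed + 2L)
    model <- encrypted_sfh_iteration(enc, keys, iters = 1L, x0 = x0)
    beta_enc <- decrypt_model(keys, model)
    enc_part <- list(beta = beta_enc, roc = auc_of(beta_enc),
                     report = model$report,
                     size_bits = enc$manifest$size_bits)
  }

  report <- structure(list(
    config = cfg,
    n_train = n_train, n_test = data$N - n_train,
    beta = list(sfh = beta_sfh, sfh_newton = beta_newton, irls = beta_irls,
                encrypted = enc_part$beta),
    auc = c(sfh = roc_sfh$auc, sfh_newton = roc_newton$auc,
            irls = roc_irls$auc,
            encrypted = if (!is.null(enc_part)) enc_part$roc$auc else NA_real_),
    auc_diff_vs_irls = c(sfh = abs(roc_sfh$auc - roc_irls$auc),
                         sfh_newton = abs(roc_newton$auc - roc_irls$auc)),
    roc = list(sfh = roc_sfh, irls = roc_irls),
    circuit = enc_part$report,
    size_bits = enc_part$size_bits,
    seeds = list(master = cfg$seed, shuffle = cfg$shuffle_seed,
                 keygen = if (cfg$encrypted) cfg$seed + 1L else NULL,
                 encrypt = if (cfg$encrypted) cfg$seed + 2L else NULL),
    x0 = x0
  ), class = "sfhe_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_model(beta_sfh, file.path(out_dir, "model_sfh.txt"))
    write_model(beta_irls, file.path(out_dir, "model_irls.txt"))
    if (!is.null(enc_part))
      write_model(enc_part$beta, file.path(out_dir, "model_encrypted.txt"))
    write_roc(roc_sfh, file.path(out_dir, "roc_sfh.csv"))
    write_roc(roc_irls, file.path(out_dir, "roc_irls.csv"))
    writeLines(format_report(report), file.path(out_dir, "report.txt"))
  }
  report
}

#' @export
print.sfhe_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Plain-text rendering of an experiment report
#'
#' @param report an `sfhe_report`.
#' @return character vector of `key = value` lines.
#' @export
format_report <- function(report) {
  a <- report$auc
  out <- c(
    sprintf("n_train = %d", report$n_train),
    sprintf("n_test = %d", report$n_test),
    sprintf("iters = %d", report$config$iters),
    sprintf("auc_sfh = %.6f", a[["sfh"]]),
    sprintf("auc_sfh_newton = %.6f", a[["sfh_newton"]]),
    sprintf("auc_irls = %.6f", a[["irls"]]),
    sprintf("auc_gap_sfh_vs_irls = %.6f", report$auc_diff_vs_irls[["sfh"]]),
    sprintf("x0 = %.10g", report$x0),
    sprintf("seed_master = %d", report$seeds$master)
  )
  if (!is.na(a[["encrypted"]])) {
    out <- c(out,
      sprintf("auc_encrypted = %.6f", a[["encrypted"]]),
      sprintf("ct_mult_stages = %d", report$circuit$ct_mults),
      sprintf("encrypted_dataset_bits = %.0f", report$size_bits))
  }
  out
}
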