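#' Construct a training dataset
#'
#' Bundles a design matrix and a vector of class labels into the container used
#' throughout the package. The intercept is handled internally: `X` holds the
#' `d` covariate columns only, and a leading all-ones column is prepended so
#' that every record is `x = (1, x_1, ..., x_d)`.
#'
#' @param X numeric matrix with `N` rows and `d` covariate columns (no
#'   intercept column; it is added here).
#' @param y numeric vector of `N` class labels in `{-1, +1}`. Labels in
#'   `{0, 1}` are accepted and remapped to `{-1, +1}` with a warning.
#' @return An object of class `sfhe_dataset`: a list with elements `X` (the
#'   `N x (d+1)` design matrix including the intercept column), `y`, `N`, `d`.
#' @examples
#' d <- dataset(matrix(c(1, 0, 1, 1), 2), c(1, -1))
#' d$N; d$d
#' @export
dataset <- function(X, y) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("covariates must be numeric")
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) < 1L || ncol(X) < 1L) stop("need N >= 1 records and d >= 1 covariates")
  if (all(y %in% c(0, 1)) && any(y == 0)) {
    warning("labels look like {0,1}; remapping to {-1,+1}")
    y <- 2 * y - 1
  }
  if (!all(y %in% c(-1, 1))) stop("labels must lie in {-1,+1} (or {0,1})")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xd <- cbind(`(Intercept)` = 1, X)
  structure(list(X = Xd, y = y, N = nrow(X), d = ncol(X)),
            class = "sfhe_dataset")
}

#' @export
print.sfhe_dataset <- function(x, ...) {
  cat(sprintf("<sfhe_dataset> N = %d records, d = %d covariates, %d positive / %d negative\n",
              x$N, x$d, sum(x$y > 0), sum(x$y < 0)))
  invisible(x)
}

#' Read a dataset from CSV
#'
#' Expects a header row and a label column named `y` with values in `{-1,+1}`
#' (values in `{0,1}` are remapped with a warning). All remaining columns are
#' covariates. The intercept column is never stored on disk.
#'
#' @param path path to a CSV file.
#' @return An `sfhe_dataset`.
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"y" %in% names(df)) stop("no label column named 'y' in ", path)
  y <- df[["y"]]
  X <- as.matrix(df[setdiff(names(df), "y")])
  dataset(X, y)
}

#' Write a dataset to CSV
#'
#' Inverse of [read_dataset()]: covariate columns plus a `y` label column,
#' without the internal intercept column.
#'
#' @param data an `sfhe_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "sfhe_dataset"))
  df <- as.data.frame(data$X[, -1L, drop = FALSE])
  df$y <- data$y
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Min-max normalisation to [0, 1]
#'
#' Rescales every column of `X` as `(x - min) / (max - min)`, the preprocessing
#' applied to continuous (financial-style) covariates before training. Constant
#' columns carry no information and cannot be rescaled; they are rejected.
#'
#' @param X numeric matrix.
#' @return Matrix of the same shape with every column spanning `[0, 1]`.
#' @examples
#' minmax_normalize(cbind(a = c(2, 4, 6)))
#' @export
minmax_normalize <- function(X) {
  X <- as.matrix(X)
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  bad <- which(hi <= lo)
  if (length(bad)) {
    nm <- colnames(X)
    lab <- if (is.null(nm)) as.character(bad) else nm[bad]
    stop("constant column(s) cannot be min-max normalised: ",
         paste(lab, collapse = ", "))
  }
  sweep(sweep(X, 2, lo, "-"), 2, hi - lo, "/")
}

#' Split a dataset into training and test parts
#'
#' The first `n_train` rows (after an optional seeded shuffle) become the
#' training set and the remainder the test set.
#'
#' @param data an `sfhe_dataset`.
#' @param n_train number of training records; must leave at least one test
#'   record unless `n_train == data$N`.
#' @param shuffle_seed optional integer; when given, rows are permuted
#'   reproducibly before splitting.
#' @return list with elements `train` and `test` (both `sfhe_dataset`, `test`
#'   may be `NULL` when all rows are used for training).
#' @export
train_test_split <- function(data, n_train, shuffle_seed = NULL) {
  stopifnot(inherits(data, "sfhe_dataset"))
  if (n_train < 1L || n_train > data$N) stop("n_train must be in [1, N]")
  idx <- seq_len(data$N)
  if (!is.null(shuffle_seed)) {
    idx <- with_seed(shuffle_seed, sample(idx))
  }
  tr <- idx[seq_len(n_train)]
  te <- setdiff(idx, tr)
  Xc <- data$X[, -1L, drop = FALSE]
  list(
    train = dataset(Xc[tr, , drop = FALSE], data$y[tr]),
    test = if (length(te)) dataset(Xc[te, , drop = FALSE], data$y[te]) else NULL
  )
}

# Evaluate `expr` under a temporary R RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
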