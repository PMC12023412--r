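# The correction model itself: occurrence encoding, design matrices,
# closed-form ridge, fitting and prediction for the three modes.
#
# Modes:
#   dd   -- ddG = a0 * (S_m - S_w) + sum_i a_i O_i     (21 coefficients)
#   rose -- ddG = a0 * (S_m - S_w) + a1 * (R_m - R_w)  (2 coefficients)
#   only -- ddG = sum_i a_i O_i                        (20 coefficients)
#
# O is the 20-element occurrence vector (-1 at the wild-type residue, +1 at
# the mutant, 0 elsewhere); R is a per-residue scale. All three forms are
# odd functions of the mutation direction, so prediction is exactly
# antisymmetric: reversing a mutation negates the output. No intercept is
# ever fitted -- a constant term would break that structural antisymmetry.

MBC_MODES <- c("dd", "rose", "only")

#' Occurrence encoding of a single-point mutation
#'
#' A 20-element integer vector indexed by residue in alphabetical one-letter
#' order: -1 at the wild-type residue, +1 at the mutant, 0 elsewhere
#' (all zeros for an identity mutation). Entries always sum to zero, which
#' is why the residue coefficients of the fitted models carry a gauge
#' freedom: adding a constant to all 20 leaves predictions unchanged.
#'
#' @param wt,mut One-letter residue codes (scalars).
#' @return Named integer vector of length 20.
#' @examples
#' encode_mutation("A", "V")
#' @export
encode_mutation <- function(wt, mut) {
  wt <- aa_normalize(wt, "wild-type")
  mut <- aa_normalize(mut, "mutant")
  stopifnot(length(wt) == 1L, length(mut) == 1L)
  o <- stats::setNames(integer(20L), AA_ALPHABET)
  if (wt != mut) {
    o[wt] <- -1L
    o[mut] <- 1L
  }
  o
}

# Vectorized encoding: n x 20 matrix, one row per mutation.
encode_mutations <- function(wt, mut) {
  wt <- aa_normalize(wt, "wild-type")
  mut <- aa_normalize(mut, "mutant")
  n <- length(wt)
  O <- matrix(0, n, 20L, dimnames = list(NULL, AA_ALPHABET))
  iw <- match(wt, AA_ALPHABET)
  im <- match(mut, AA_ALPHABET)
  same <- iw == im
  O[cbind(seq_len(n), iw)] <- -1
  O[cbind(seq_len(n), im)] <- O[cbind(seq_len(n), im)] + 1
  O[same, ] <- 0
  O
}

# Score delta for each record, from score_delta or the per-state scores.
.record_score_delta <- function(ds, required = TRUE) {
  d <- ds$score_delta
  from_states <- is.na(d) & !is.na(ds$score_wt) & !is.na(ds$score_mut)
  d[from_states] <- ds$score_mut[from_states] - ds$score_wt[from_states]
  if (required && anyNA(d)) {
    mbc_stop("mbc_incomplete_record",
             "missing base-method score in row(s): %s",
             paste(which(is.na(d)), collapse = ", "))
  }
  d
}

#' Build the regression design matrix for a mode
#'
#' @param ds An `mbc_dataset`.
#' @param mode `"dd"` (columns `[score_delta, O_A..O_Y]`, p = 21),
#'   `"only"` (occurrence columns only, p = 20), or
#'   `"rose"` (columns `[score_delta, scale_delta]`, p = 2).
#' @param scale Required for `mode = "rose"`: a scale name or named vector.
#' @param require_y If `TRUE`, `ddg_exp` must be present on every row and is
#'   returned as the target vector.
#' @return List of class `mbc_design` with `X` (n x p), `y` (or `NULL`),
#'   `row_ids`, `mode`, `scale_name`.
#' @export
build_design_matrix <- function(ds, mode = c("dd", "rose", "only"),
                                scale = NULL, require_y = TRUE) {
  mode <- match.arg(mode)
  if (nrow(ds) == 0L) mbc_stop("mbc_empty_input", "dataset has no records")
  scale_name <- NA_character_
  O <- encode_mutations(ds$wt, ds$mut)
  if (mode == "dd") {
    X <- cbind(score_delta = .record_score_delta(ds), O)
  } else if (mode == "only") {
    X <- O
  } else {
    if (is.null(scale)) {
      mbc_stop("mbc_format_error", "mode 'rose' requires a scale")
    }
    if (is.character(scale) && length(scale) == 1L) scale <- get_scale(scale)
    scale_name <- attr(scale, "name") %||% "custom"
    X <- cbind(score_delta = .record_score_delta(ds),
               scale_delta = scale_delta(ds$wt, ds$mut, scale))
  }
  y <- NULL
  if (require_y) {
    if (anyNA(ds$ddg_exp)) {
      mbc_stop("mbc_incomplete_record",
               "missing ddg_exp in row(s): %s",
               paste(which(is.na(ds$ddg_exp)), collapse = ", "))
    }
    y <- ds$ddg_exp
  }
  structure(list(X = X, y = y, row_ids = ds$id, mode = mode,
                 scale_name = scale_name),
            class = "mbc_design")
}

#' Closed-form ridge regression (no intercept)
#'
#' Minimizes `||y - X b||^2 + lambda ||b||^2` via the normal equations
#' `(X'X + lambda I) b = X'y`. No intercept and no feature standardization:
#' occurrence features are already on a unit scale, and coefficients stay
#' interpretable in kcal/mol. `lambda = 0` reproduces ordinary least
#' squares and requires full column rank.
#'
#' @param X Numeric matrix (n x p), finite entries.
#' @param y Numeric vector of length n.
#' @param lambda Ridge penalty, >= 0, in squared target units.
#' @return Coefficient vector of length p (named if X has column names).
#' @export
ridge_solve <- function(X, y, lambda = 1.0) {
  X <- as.matrix(X)
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0) {
    mbc_stop("mbc_format_error", "lambda must be a single number >= 0")
  }
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    mbc_stop("mbc_format_error", "design matrix and targets must be finite")
  }
  if (nrow(X) != length(y)) {
    mbc_stop("mbc_shape_error", "nrow(X) = %d but length(y) = %d",
             nrow(X), length(y))
  }
  p <- ncol(X)
  A <- crossprod(X) + diag(lambda, p)
  if (lambda == 0 && qr(X)$rank < p) {
    mbc_stop("mbc_singular_system",
             "X is rank-deficient (rank %d < %d columns) and lambda = 0; use lambda > 0",
             qr(X)$rank, p)
  }
  beta <- tryCatch(solve(A, crossprod(X, y)),
                   error = function(e) {
                     mbc_stop("mbc_singular_system",
                              "normal equations are singular; use lambda > 0 (%s)",
                              conditionMessage(e))
                   })
  stats::setNames(as.numeric(beta), colnames(X))
}

#' Fit a mass-balance correction model
#'
#' Optionally augments the training data with the antisymmetric complement
#' of every mutation (default on), builds the design matrix for the chosen
#' mode and solves the ridge system. The penalty `lambda` is defined per
#' *original* mutation: when augmentation doubles the rows the solver
#' penalty is doubled with them, so with no intercept the augmented and
#' unaugmented fits are identical -- augmentation could only matter through
#' an intercept, which this model structurally excludes. It is kept as the
#' default protocol so that any intercept-bearing variant would still be
#' driven to antisymmetry by the data.
#'
#' @param ds Training `mbc_dataset` with `ddg_exp` on every row.
#' @param mode `"dd"`, `"rose"` or `"only"`.
#' @param lambda Ridge penalty; default 1.0 for `dd`/`only` and 0 (plain
#'   least squares) for the two-parameter `rose` mode.
#' @param scale Scale (name or named vector) for `mode = "rose"`.
#' @param augment Apply antisymmetric augmentation before fitting.
#' @return An `mbc_model`: coefficients (`a0`, `a`, `a1` as the mode
#'   requires), `lambda`, `scale_name`, and `fit_meta` (n, augmented flag,
#'   intercept policy, timestamp).
#' @export
mbc_fit <- function(ds, mode = c("dd", "rose", "only"), lambda = NULL,
                    scale = NULL, augment = TRUE) {
  mode <- match.arg(mode)
  if (nrow(ds) == 0L) mbc_stop("mbc_empty_input", "dataset has no records")
  if (is.null(lambda)) lambda <- if (mode == "rose") 0.0 else 1.0
  fit_ds <- if (augment) augment_antisymmetric(ds) else ds
  dm <- build_design_matrix(fit_ds, mode, scale = scale)
  lambda_eff <- lambda * nrow(fit_ds) / nrow(ds)  # per-original-row penalty
  beta <- ridge_solve(dm$X, dm$y, lambda_eff)
  model <- list(mode = mode, lambda = lambda,
                scale_name = dm$scale_name,
                fit_meta = list(n = nrow(fit_ds), n_input = nrow(ds),
                                augmented = augment, intercept = FALSE,
                                timestamp = format(Sys.time(), tz = "UTC",
                                                   usetz = TRUE)))
  if (mode == "dd") {
    model$a0 <- unname(beta[1L])
    model$a <- stats::setNames(unname(beta[-1L]), AA_ALPHABET)
  } else if (mode == "only") {
    model$a <- stats::setNames(unname(beta), AA_ALPHABET)
  } else {
    model$a0 <- unname(beta[1L])
    model$a1 <- unname(beta[2L])
    if (is.character(scale) && length(scale) == 1L) scale <- get_scale(scale)
    model$scale_values <- .as_scale_values(scale)
  }
  structure(model, class = "mbc_model")
}

#' Hand-build a correction model from coefficients
#'
#' Mainly for testing and for applying published coefficient tables.
#'
#' @param mode Model mode.
#' @param a0 Score weight (`dd`, `rose`).
#' @param a Named 20-vector of residue coefficients (`dd`, `only`),
#'   kcal/mol.
#' @param a1 Scale-delta weight (`rose`).
#' @param scale Scale for `rose` (name or named vector).
#' @param lambda Recorded penalty (metadata only).
#' @return An `mbc_model`.
#' @export
mbc_model <- function(mode, a0 = NULL, a = NULL, a1 = NULL, scale = NULL,
                      lambda = NA_real_) {
  if (!mode %in% MBC_MODES) {
    mbc_stop("mbc_format_error", "unknown mode '%s'", mode)
  }
  model <- list(mode = mode, lambda = lambda, scale_name = NA_character_,
                fit_meta = list(n = NA_integer_, augmented = NA,
                                intercept = FALSE, timestamp = NA_character_))
  if (mode %in% c("dd", "only")) {
    if (is.null(a)) mbc_stop("mbc_format_error", "mode '%s' needs 'a'", mode)
    model$a <- .as_scale_values(a)  # same validation: total over 20 residues
  }
  if (mode %in% c("dd", "rose")) {
    if (is.null(a0)) mbc_stop("mbc_format_error", "mode '%s' needs 'a0'", mode)
    model$a0 <- as.numeric(a0)
  }
  if (mode == "rose") {
    if (is.null(a1) || is.null(scale)) {
      mbc_stop("mbc_format_error", "mode 'rose' needs 'a1' and 'scale'")
    }
    model$a1 <- as.numeric(a1)
    if (is.character(scale) && length(scale) == 1L) {
      model$scale_name <- scale
      scale <- get_scale(scale)
    } else {
      model$scale_name <- attr(scale, "name") %||% "custom"
    }
    model$scale_values <- .as_scale_values(scale)
  }
  structure(model, class = "mbc_model")
}

#' Predict corrected ddG values
#'
#' Applies the model's linear form to every record of `newdata`; output is
#' aligned with record order, in kcal/mol. Exactly antisymmetric: the
#' prediction for a mutation's antisymmetric complement is the negated
#' prediction for the mutation.
#'
#' @param object An `mbc_model`.
#' @param newdata An `mbc_dataset` carrying the fields the mode requires.
#' @param ... Unused.
#' @return Numeric vector, one prediction per record.
#' @export
predict.mbc_model <- function(object, newdata, ...) {
  ds <- newdata
  if (nrow(ds) == 0L) return(numeric(0))
  pred <- numeric(nrow(ds))
  if (object$mode %in% c("dd", "rose")) {
    pred <- pred + object$a0 * .record_score_delta(ds)
  }
  if (object$mode %in% c("dd", "only")) {
    O <- encode_mutations(ds$wt, ds$mut)
    pred <- pred + as.numeric(O %*% object$a[AA_ALPHABET])
  }
  if (object$mode == "rose") {
    pred <- pred + object$a1 * scale_delta(ds$wt, ds$mut, object$scale_values)
  }
  pred
}

#' @export
coef.mbc_model <- function(object, ...) {
  switch(object$mode,
    dd = c(a0 = object$a0, object$a),
    only = object$a,
    rose = c(a0 = object$a0, a1 = object$a1))
}

#' @export
print.mbc_model <- function(x, ...) {
  cat(sprintf("Mass-balance correction model [mode: %s, lambda: %s]\n",
              x$mode, format(x$lambda)))
  if (x$mode == "rose") {
    cat(sprintf("  a0 = %.4f, a1 = %.4f (scale: %s)\n",
                x$a0, x$a1, x$scale_name))
  } else {
    if (x$mode == "dd") cat(sprintf("  a0 = %.4f\n", x$a0))
    cat("  residue coefficients (kcal/mol):\n")
    print(round(x$a, 3))
  }
  if (!is.na(x$fit_meta$n)) {
    cat(sprintf("  fitted on n = %d rows (augmented: %s)\n",
                x$fit_meta$n, x$fit_meta$augmented))
  }
  invisible(x)
}

MODEL_SCHEMA_VERSION <- 1L

#' Save / load a model as JSON
#'
#' The document is `{schema_version, mode, lambda, a0, a (keyed by residue),
#' a1, scale_name, scale_values, fit_metadata}`. Coefficients are written at
#' full double precision, so a save/load round trip is lossless.
#'
#' @param model An `mbc_model`.
#' @param path File path.
#' @return `load_model` returns the `mbc_model`; `save_model` returns
#'   `path` invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "mbc_model")) {
    mbc_stop("mbc_format_error", "not an mbc_model")
  }
  doc <- list(schema_version = MODEL_SCHEMA_VERSION,
              mode = model$mode, lambda = model$lambda,
              scale_name = model$scale_name,
              fit_metadata = model$fit_meta)
  if (!is.null(model$a0)) doc$a0 <- model$a0
  if (!is.null(model$a)) doc$a <- as.list(model$a)
  if (!is.null(model$a1)) doc$a1 <- model$a1
  if (!is.null(model$scale_values)) doc$scale_values <- as.list(model$scale_values)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) mbc_stop("mbc_not_found", "no such file: %s", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    mbc_stop("mbc_format_error", "cannot parse model file %s: %s",
                             path, conditionMessage(e))
                  })
  if (is.null(doc$schema_version) || doc$schema_version != MODEL_SCHEMA_VERSION) {
    mbc_stop("mbc_format_error",
             "model file %s: unsupported schema_version '%s' (expected %d)",
             path, format(doc$schema_version), MODEL_SCHEMA_VERSION)
  }
  if (is.null(doc$mode) || !doc$mode %in% MBC_MODES) {
    mbc_stop("mbc_format_error", "model file %s: missing or unknown mode", path)
  }
  model <- list(mode = doc$mode,
                lambda = as.numeric(doc$lambda %||% NA_real_),
                scale_name = doc$scale_name %||% NA_character_,
                fit_meta = lapply(doc$fit_metadata %||% list(), identity))
  if (!is.null(doc$a0)) model$a0 <- as.numeric(doc$a0)
  if (!is.null(doc$a1)) model$a1 <- as.numeric(doc$a1)
  if (!is.null(doc$a)) {
    a <- unlist(doc$a)
    model$a <- .as_scale_values(a)
  }
  if (!is.null(doc$scale_values)) {
    model$scale_values <- .as_scale_values(unlist(doc$scale_values))
  }
  needed <- switch(model$mode,
                   dd = c("a0", "a"), only = "a", rose = c("a0", "a1"))
  miss <- setdiff(needed, names(model))
  if (length(miss)) {
    mbc_stop("mbc_format_error",
             "model file %s (mode %s): missing field(s) %s",
             path, model$mode, paste(miss, collapse = ", "))
  }
  fm <- model$fit_meta
  model$fit_meta <- list(
    n = as.integer(fm$n %||% NA_integer_),
    n_input = as.integer(fm$n_input %||% NA_integer_),
    augmented = fm$augmented %||% NA,
    intercept = fm$intercept %||% FALSE,
    timestamp = fm$timestamp %||% NA_character_)
  structure(model, class = "mbc_model")
}
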