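# Assessment metrics: Pearson correlation, RMSE, direct/inverse
# antisymmetry diagnostics, and coefficient-scale correlation analysis.

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation between experimental and predicted
#' values. Degenerate inputs (zero variance, n < 2) raise a typed error
#' rather than returning NaN, so a silent NaN can never propagate into a
#' benchmark report.
#'
#' @param experimental,predicted Equal-length numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(experimental, predicted) {
  .check_pair(experimental, predicted)
  if (length(experimental) < 2L) {
    mbc_stop("mbc_degenerate_input", "need at least 2 pairs for correlation")
  }
  if (stats::sd(experimental) == 0 || stats::sd(predicted) == 0) {
    mbc_stop("mbc_degenerate_input",
             "zero variance in %s",
             paste(c("experimental", "predicted")[
               c(stats::sd(experimental) == 0, stats::sd(predicted) == 0)],
               collapse = " and "))
  }
  stats::cor(experimental, predicted, method = "pearson")
}

#' Root mean square error
#'
#' @param experimental,predicted Equal-length numeric vectors (kcal/mol).
#' @return RMSE in kcal/mol, >= 0.
#' @export
rmse <- function(experimental, predicted) {
  .check_pair(experimental, predicted)
  if (length(experimental) == 0L) {
    mbc_stop("mbc_degenerate_input", "need at least 1 pair for RMSE")
  }
  sqrt(mean((predicted - experimental)^2))
}

.check_pair <- function(e, p) {
  if (length(e) != length(p)) {
    mbc_stop("mbc_shape_error", "length mismatch: %d vs %d",
             length(e), length(p))
  }
  if (anyNA(e) || anyNA(p) || !all(is.finite(c(e, p)))) {
    mbc_stop("mbc_degenerate_input", "inputs must be finite and non-missing")
  }
}

#' Direct/inverse antisymmetry diagnostics
#'
#' For paired predictions on direct mutations and on their antisymmetric
#' complements, reports the conventional pair of statistics:
#' `r_dir_inv`, the Pearson correlation between the direct predictions and
#' the *negated* inverse predictions (1 for a perfectly antisymmetric
#' predictor), and `bias`, the mean of `(pred_direct + pred_inverse) / 2`
#' in kcal/mol (0 for a perfectly antisymmetric predictor).
#'
#' @param pred_direct,pred_inverse Paired numeric vectors; entry i of
#'   `pred_inverse` is the prediction for the complement of mutation i.
#' @return List with `r_dir_inv` and `bias`.
#' @export
antisymmetry_metrics <- function(pred_direct, pred_inverse) {
  .check_pair(pred_direct, pred_inverse)
  list(r_dir_inv = pearson(pred_direct, -pred_inverse),
       bias = mean((pred_direct + pred_inverse) / 2))
}

#' Pairwise correlations among residue-coefficient vectors and scales
#'
#' Useful for comparing fitted residue coefficients across base methods and
#' against hydrophobicity/burial scales: vectors that correlate strongly
#' encode the same per-residue signal up to an affine transform (which is
#' all the gauge freedom allows one to compare anyway).
#'
#' @param named_vectors Named list of numeric vectors, each covering the 20
#'   canonical residues (named by residue, any order) or unnamed length-20
#'   in alphabetical residue order.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
coefficient_correlations <- function(named_vectors) {
  if (!is.list(named_vectors) || is.null(names(named_vectors)) ||
      length(named_vectors) < 2L) {
    mbc_stop("mbc_shape_error",
             "need a named list of at least two 20-vectors")
  }
  mat <- vapply(named_vectors, function(v) {
    if (length(v) != 20L) {
      mbc_stop("mbc_shape_error", "all vectors must have length 20")
    }
    if (!is.null(names(v))) v <- .as_scale_values(v)
    as.numeric(v)
  }, numeric(20L))
  stats::cor(mat, method = "pearson")
}

#' Evaluate predictions against experimental values
#'
#' @param experimental,predicted Paired ddG vectors, kcal/mol.
#' @param pred_inverse Optional paired predictions on the antisymmetric
#'   complements, to include antisymmetry diagnostics.
#' @return An `mbc_eval` report: `n`, `pcc`, `rmse`, optional
#'   `antisymmetry` (`r_dir_inv`, `bias`).
#' @export
evaluate_predictions <- function(experimental, predicted,
                                 pred_inverse = NULL) {
  rep <- list(n = length(experimental),
              pcc = pearson(experimental, predicted),
              rmse = rmse(experimental, predicted))
  if (!is.null(pred_inverse)) {
    rep$antisymmetry <- antisymmetry_metrics(predicted, pred_inverse)
  }
  structure(rep, class = "mbc_eval")
}

#' @export
print.mbc_eval <- function(x, ...) {
  cat(sprintf("n = %d, PCC = %.4f, RMSE = %.4f kcal/mol\n",
              x$n, x$pcc, x$rmse))
  if (!is.null(x$antisymmetry)) {
    cat(sprintf("antisymmetry: r(dir, -inv) = %.4f, bias = %.4g kcal/mol\n",
                x$antisymmetry$r_dir_inv, x$antisymmetry$bias))
  }
  invisible(x)
}

#' Write an evaluation report
#'
#' JSON for machine consumption, or a one-line TSV (`n`, `pcc`, `rmse`,
#' `r_dir_inv`, `bias`) convenient for tabulating many methods.
#'
#' @param report An `mbc_eval`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = I(17), pretty = TRUE)
  } else {
    row <- data.frame(n = report$n, pcc = report$pcc, rmse = report$rmse,
                      r_dir_inv = report$antisymmetry$r_dir_inv %||% NA_real_,
                      bias = report$antisymmetry$bias %||% NA_real_)
    utils::write.table(row, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
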