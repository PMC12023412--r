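# Per-amino-acid scales and the scale-delta used by the two-parameter
# correction model.

#' The 20 canonical amino acids
#'
#' One-letter codes in fixed alphabetical order. This order indexes the
#' occurrence vector and every coefficient vector in the package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte & Doolittle (1982) J Mol Biol 157:105-132, hydropathy index.
# Transcribed from the published table; dimensionless.
.KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Rose, Geselowitz, Lesser, Lee & Zehfus (1985) Science 229:834-838,
# mean area buried on transfer from the standard state to the folded
# protein (A^2). Transcribed from the published table.
.ROSE_AREA_BURIED <- c(
  A =  86.6, C = 132.3, D =  97.8, E = 113.9, F = 194.1,
  G =  62.9, H = 155.8, I = 158.0, K = 115.5, L = 164.1,
  M = 172.9, N = 103.3, P =  92.9, Q = 119.2, R = 162.2,
  S =  85.6, T = 106.5, V = 141.0, W = 224.6, Y = 177.7
)

# Mutable registry so users can add custom scales at run time.
.scale_registry <- new.env(parent = emptyenv())

.init_scale_registry <- function() {
  assign("kyte_doolittle", .KYTE_DOOLITTLE, envir = .scale_registry)
  assign("rose", .ROSE_AREA_BURIED, envir = .scale_registry)
}

.onLoad <- function(libname, pkgname) {
  .init_scale_registry()
}

#' Normalize and validate one-letter amino-acid codes
#'
#' Codes are case-insensitive on input and normalized to uppercase.
#' Non-canonical symbols (including B, Z, X, U, O) are rejected: the
#' occurrence encoding is defined only over the 20 canonical residues.
#'
#' @param aa Character vector of one-letter codes.
#' @param what Label used in error messages.
#' @return Uppercase character vector of canonical codes.
#' @export
aa_normalize <- function(aa, what = "residue") {
  aa <- toupper(as.character(aa))
  bad <- is.na(aa) | !(aa %in% AA_ALPHABET)
  if (any(bad)) {
    mbc_stop("mbc_invalid_residue",
             "invalid %s code(s): %s (must be one of %s)",
             what, paste(unique(aa[bad]), collapse = ", "),
             paste(AA_ALPHABET, collapse = ""))
  }
  aa
}

#' Retrieve a registered amino-acid scale
#'
#' Built-in scales are `"kyte_doolittle"` (hydropathy) and `"rose"`
#' (mean area buried in folded proteins). Additional scales can be added
#' with [register_scale()] or loaded from TSV with [read_scale_tsv()].
#'
#' @param name Scale identifier.
#' @return Named numeric vector of length 20 (class `mbc_scale`), one finite
#'   value per canonical residue, in alphabetical one-letter order.
#' @examples
#' get_scale("kyte_doolittle")[["I"]]  # 4.5
#' @export
get_scale <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    mbc_stop("mbc_not_found", "scale name must be a single string")
  }
  if (!exists(name, envir = .scale_registry, inherits = FALSE)) {
    mbc_stop("mbc_not_found",
             "unknown scale '%s'; registered scales: %s",
             name, paste(sort(list_scales()), collapse = ", "))
  }
  structure(get(name, envir = .scale_registry),
            name = name, class = "mbc_scale")
}

#' List registered scale names
#' @return Character vector of identifiers accepted by [get_scale()].
#' @export
list_scales <- function() ls(envir = .scale_registry)

#' Register a custom amino-acid scale
#'
#' @param name Identifier for later lookup with [get_scale()].
#' @param values Named numeric vector with one finite value for each of the
#'   20 canonical residues. Names may be lowercase; order is irrelevant.
#' @return The registered scale, invisibly.
#' @export
register_scale <- function(name, values) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    mbc_stop("mbc_format_error", "scale name must be a non-empty string")
  }
  if (is.null(names(values))) {
    mbc_stop("mbc_format_error", "scale values must be named by residue")
  }
  res <- aa_normalize(names(values), what = "scale residue")
  if (anyDuplicated(res)) {
    mbc_stop("mbc_format_error", "duplicate residue in scale '%s'", name)
  }
  if (length(res) != 20L) {
    mbc_stop("mbc_format_error",
             "scale '%s' covers %d residues; all 20 are required",
             name, length(res))
  }
  v <- as.numeric(values)
  if (!all(is.finite(v))) {
    mbc_stop("mbc_format_error", "scale '%s' has non-finite values", name)
  }
  names(v) <- res
  v <- v[AA_ALPHABET]
  assign(name, v, envir = .scale_registry)
  invisible(structure(v, name = name, class = "mbc_scale"))
}

#' Scale difference between mutant and wild-type residue
#'
#' Computes `scale[mut] - scale[wt]`, the regressor of the two-parameter
#' correction model. Vectorized over `wt`/`mut`; antisymmetric by
#' construction: swapping the two residues negates the result.
#'
#' @param wt,mut One-letter codes (vectors of equal length, or length 1).
#' @param scale A scale from [get_scale()], a scale name, or any named
#'   numeric vector covering the 20 canonical residues.
#' @return Numeric vector of deltas, in the scale's units.
#' @examples
#' scale_delta("A", "I", get_scale("kyte_doolittle"))  # 2.7
#' @export
scale_delta <- function(wt, mut, scale) {
  if (is.character(scale) && length(scale) == 1L) scale <- get_scale(scale)
  v <- .as_scale_values(scale)
  wt <- aa_normalize(wt, "wild-type")
  mut <- aa_normalize(mut, "mutant")
  unname(v[mut] - v[wt])
}

.as_scale_values <- function(scale) {
  if (is.null(names(scale)) || !is.numeric(scale)) {
    mbc_stop("mbc_format_error",
             "scale must be a named numeric vector over the 20 residues")
  }
  miss <- setdiff(AA_ALPHABET, names(scale))
  if (length(miss)) {
    mbc_stop("mbc_format_error",
             "scale lacks values for: %s", paste(miss, collapse = ", "))
  }
  as.numeric(scale[AA_ALPHABET]) -> v
  names(v) <- AA_ALPHABET
  v
}

#' Read / write a scale as two-column TSV
#'
#' The file format is `residue<TAB>value` with a header line, one row per
#' canonical residue. `read_scale_tsv()` optionally registers the scale.
#'
#' @param path File path.
#' @param name Identifier to register the scale under (`NULL` = do not
#'   register; the basename is used when `name` is `TRUE`).
#' @return The scale as a named numeric vector.
#' @export
read_scale_tsv <- function(path, name = NULL) {
  if (!file.exists(path)) mbc_stop("mbc_not_found", "no such file: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    mbc_stop("mbc_format_error",
             "scale TSV must have two columns (residue, value): %s", path)
  }
  v <- stats::setNames(as.numeric(df[[2L]]), df[[1L]])
  if (isTRUE(name)) name <- tools::file_path_sans_ext(basename(path))
  if (!is.null(name)) return(invisible(register_scale(name, v)))
  res <- aa_normalize(names(v), "scale residue")
  names(v) <- res
  .as_scale_values(v)
}

#' @rdname read_scale_tsv
#' @param scale Scale to write (named numeric vector).
#' @export
write_scale_tsv <- function(scale, path) {
  v <- .as_scale_values(scale)
  utils::write.table(
    data.frame(residue = names(v), value = unname(v)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.mbc_scale <- function(x, ...) {
  cat(sprintf("Amino-acid scale '%s'\n", attr(x, "name")))
  print(stats::setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}
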