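# Mutation tables: construction, parsing, merging with precedence, and
# antisymmetric augmentation.
#
# A dataset is a plain data.frame with class "mbc_dataset" and the canonical
# columns id, structure_id, chain, position, wt, mut, ddg_exp, score_wt,
# score_mut, score_delta (+ optional logical is_complement). Metadata
# (method name, ddG sign-convention label, source) travels in attr "meta"
# and is stored, never interpreted: this package does not normalize sign
# conventions.

DATASET_COLUMNS <- c("id", "structure_id", "chain", "position",
                     "wt", "mut", "ddg_exp",
                     "score_wt", "score_mut", "score_delta")

#' Build a mutation dataset from vectors or a data.frame
#'
#' Validates residue codes, reconciles the three score fields, and attaches
#' metadata. Each row is one single-point mutation with an (optional)
#' experimental ddG in kcal/mol and the base method's score(s) in the
#' method's own units: either per-state scores `score_wt` / `score_mut`, or
#' a precomputed `score_delta` (= score_mut - score_wt).
#'
#' @param df data.frame with at least columns `wt` and `mut`; missing
#'   canonical columns are added as `NA`.
#' @param method Base-method name (free text).
#' @param sign_convention ddG sign-convention label (free text, stored not
#'   interpreted).
#' @param source Source label.
#' @return An `mbc_dataset` (data.frame).
#' @export
mutation_dataset <- function(df, method = NA_character_,
                             sign_convention = NA_character_,
                             source = NA_character_) {
  if (!is.data.frame(df)) {
    mbc_stop("mbc_format_error", "a mutation dataset must be a data.frame")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- setdiff(c("wt", "mut"), names(df))
  if (length(need)) {
    mbc_stop("mbc_format_error",
             "missing required column(s): %s", paste(need, collapse = ", "))
  }
  for (col in setdiff(DATASET_COLUMNS, names(df))) {
    proto <- if (col %in% c("id", "structure_id", "chain")) {
      NA_character_
    } else if (col == "position") NA_integer_ else NA_real_
    df[[col]] <- rep(proto, nrow(df))
  }
  if (nrow(df)) {
    df$wt <- aa_normalize(df$wt, "wild-type")
    df$mut <- aa_normalize(df$mut, "mutant")
    if (all(is.na(df$id))) df$id <- sprintf("rec%04d", seq_len(nrow(df)))
  }
  df$position <- suppressWarnings(as.integer(df$position))
  for (col in c("ddg_exp", "score_wt", "score_mut", "score_delta")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df <- .check_score_consistency(df)
  keep <- c(DATASET_COLUMNS, intersect("is_complement", names(df)))
  df <- df[, keep, drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            meta = list(method = method, sign_convention = sign_convention,
                        source = source),
            class = c("mbc_dataset", "data.frame"))
}

# If both per-state scores and a delta are present they must agree; if only
# per-state scores are present, derive the delta.
.check_score_consistency <- function(df, tol = 1e-6) {
  both <- !is.na(df$score_wt) & !is.na(df$score_mut)
  derived <- df$score_mut - df$score_wt
  has_delta <- !is.na(df$score_delta)
  clash <- both & has_delta & abs(df$score_delta - derived) > tol
  if (any(clash)) {
    mbc_stop("mbc_record_error",
             "score_delta disagrees with score_mut - score_wt (> %g) in row(s): %s",
             tol, paste(which(clash), collapse = ", "))
  }
  fill <- both & !has_delta
  df$score_delta[fill] <- derived[fill]
  df
}

#' @export
print.mbc_dataset <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Mutation dataset: %d records", nrow(x)))
  if (!is.null(meta) && !is.na(meta$method)) {
    cat(sprintf(" [method: %s]", meta$method))
  }
  cat("\n")
  print.data.frame(utils::head(x, 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Parse compact mutation strings
#'
#' Splits strings like `"A123V"` into wild-type residue, integer position
#' and mutant residue.
#'
#' @param x Character vector of mutation strings.
#' @return data.frame with columns `wt`, `position`, `mut`.
#' @export
parse_mutation_string <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    mbc_stop("mbc_record_error",
             "unparseable mutation string(s): %s",
             paste(unique(x[bad]), collapse = ", "))
  }
  data.frame(
    wt = vapply(m, `[[`, "", 2L),
    position = as.integer(vapply(m, `[[`, "", 3L)),
    mut = vapply(m, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

#' Read a mutation table from CSV/TSV
#'
#' The canonical dialect is UTF-8 CSV with a header row and the canonical
#' column names; other dialects are handled through `format_config`, a named
#' list mapping canonical names to the file's column names. A compact
#' mutation-string column (e.g. `"A123V"`) may replace the separate
#' wt/position/mut columns via `format_config$mutation`.
#'
#' @param path File path (`.tsv`/`.tab` are read tab-separated, anything
#'   else comma-separated; override with `sep`).
#' @param format_config Named list, e.g.
#'   `list(mutation = "mut_str", ddg_exp = "ddG", score_delta = "pred")`.
#'   Entries absent from the list are looked up under their canonical name.
#' @param strict If `TRUE` (default) any unparseable row aborts with an
#'   error naming the rows; if `FALSE` such rows are dropped and counted in
#'   the parse report.
#' @param sep Field separator; default inferred from the file extension.
#' @param ... Passed to [mutation_dataset()] (method, sign_convention,
#'   source).
#' @return An `mbc_dataset` with a `parse_report` attribute
#'   (`n_read`, `n_kept`, `n_rejected`, `rejected_rows`, `reasons`).
#' @export
read_mutation_table <- function(path, format_config = NULL, strict = TRUE,
                                sep = NULL, ...) {
  if (!file.exists(path)) mbc_stop("mbc_not_found", "no such file: %s", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  fc <- format_config %||% list()
  pick <- function(canon) {
    nm <- fc[[canon]] %||% canon
    if (nm %in% names(raw)) raw[[nm]] else NULL
  }

  n <- nrow(raw)
  out <- data.frame(row = seq_len(n))
  mut_col <- pick("mutation")
  if (!is.null(mut_col)) {
    parsed <- .parse_mutation_lenient(mut_col)
    out$wt <- parsed$wt; out$position <- parsed$position; out$mut <- parsed$mut
    bad_mut <- parsed$bad
  } else {
    out$wt <- pick("wt"); out$mut <- pick("mut"); out$position <- pick("position")
    if (is.null(out$wt) || is.null(out$mut)) {
      mbc_stop("mbc_format_error",
               "%s: no wt/mut columns and no mutation-string column (mapped names: %s)",
               path, paste(names(raw), collapse = ", "))
    }
    bad_mut <- rep(FALSE, n)
  }
  for (canon in c("id", "structure_id", "chain", "ddg_exp",
                  "score_wt", "score_mut", "score_delta")) {
    val <- pick(canon)
    if (!is.null(val)) out[[canon]] <- val
  }
  flag <- pick("is_complement")
  if (!is.null(flag)) out$is_complement <- as.logical(flag)

  bad_res <- !(toupper(out$wt) %in% AA_ALPHABET) |
             !(toupper(out$mut) %in% AA_ALPHABET)
  bad <- bad_mut | bad_res
  reasons <- character(0)
  if (any(bad_mut)) {
    reasons <- c(reasons, sprintf("unparseable mutation string (rows %s)",
                                  paste(which(bad_mut), collapse = ",")))
  }
  if (any(bad_res & !bad_mut)) {
    reasons <- c(reasons, sprintf("non-canonical residue (rows %s)",
                                  paste(which(bad_res & !bad_mut), collapse = ",")))
  }
  if (any(bad) && strict) {
    mbc_stop("mbc_record_error", "%s: %s", path,
             paste(reasons, collapse = "; "))
  }
  kept <- out[!bad, setdiff(names(out), "row"), drop = FALSE]
  ds <- mutation_dataset(kept, ...)
  attr(ds, "parse_report") <- list(
    n_read = n, n_kept = nrow(kept), n_rejected = sum(bad),
    rejected_rows = which(bad), reasons = reasons)
  ds
}

.parse_mutation_lenient <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))
  ok <- vapply(m, length, 1L) == 4L
  get <- function(i) vapply(m, function(g) if (length(g) == 4L) g[[i]] else NA_character_, "")
  list(wt = get(2L), position = as.integer(get(3L)), mut = get(4L), bad = !ok)
}

#' Write a mutation table in the canonical CSV dialect
#'
#' @param ds An `mbc_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(ds, path) {
  df <- as.data.frame(ds)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Records are keyed by (structure_id, chain, position, wt, mut).
record_keys <- function(ds) {
  paste(ds$structure_id, ds$chain, ds$position, ds$wt, ds$mut, sep = "|")
}

#' Merge two mutation datasets with precedence
#'
#' Union of records; when the same mutation key (structure_id, chain,
#' position, wt, mut) appears in both inputs, the record from `primary`
#' wins. This is the rule used to assemble merged training sets where one
#' source's measurement takes precedence.
#'
#' @param primary,secondary `mbc_dataset`s sharing a key convention.
#' @param strict If `TRUE` (default) duplicate keys *within* one input are
#'   an error; if `FALSE` the first occurrence is kept with a warning.
#' @return Merged `mbc_dataset` with a `merge_report` attribute
#'   (`n_primary`, `n_secondary`, `n_overridden`, `n_out`).
#' @export
merge_datasets <- function(primary, secondary, strict = TRUE) {
  kp <- record_keys(primary); ks <- record_keys(secondary)
  for (nm in list(list("primary", kp), list("secondary", ks))) {
    dup <- duplicated(nm[[2L]])
    if (any(dup)) {
      if (strict) {
        mbc_stop("mbc_duplicate_key",
                 "duplicate mutation key(s) within %s input: %s",
                 nm[[1L]], paste(unique(nm[[2L]][dup]), collapse = "; "))
      }
      warning(sprintf("dropping %d duplicate key(s) in %s input (keep-first)",
                      sum(dup), nm[[1L]]))
    }
  }
  if (!strict) {
    primary <- primary[!duplicated(kp), , drop = FALSE]; kp <- record_keys(primary)
    secondary <- secondary[!duplicated(ks), , drop = FALSE]; ks <- record_keys(secondary)
  }
  overridden <- ks %in% kp
  a <- as.data.frame(primary)
  b <- as.data.frame(secondary)[!overridden, , drop = FALSE]
  # align optional columns (e.g. is_complement) between the two inputs
  for (col in setdiff(names(a), names(b))) b[[col]] <- NA
  for (col in setdiff(names(b), names(a))) a[[col]] <- NA
  out <- rbind(a, b[, names(a), drop = FALSE])
  res <- mutation_dataset(out,
                          method = attr(primary, "meta")$method,
                          sign_convention = attr(primary, "meta")$sign_convention,
                          source = "merged")
  attr(res, "merge_report") <- list(
    n_primary = nrow(primary), n_secondary = nrow(secondary),
    n_overridden = sum(overridden), n_out = nrow(res))
  res
}

#' Antisymmetric augmentation
#'
#' Appends, for every record, its reverse mutation: wild-type and mutant
#' swapped, experimental ddG negated, per-state scores swapped and the
#' score delta negated. The complement's score delta is the negated direct
#' delta -- the base method is not re-run on a mutant structure, which
#' matches the retrofit setting where only direct predictions exist (an
#' approximation for base methods that are not themselves antisymmetric).
#'
#' @param ds `mbc_dataset`; every record must carry `ddg_exp`.
#' @return `mbc_dataset` of size `2 * nrow(ds)`; appended complements carry
#'   `is_complement = TRUE` and ids suffixed `"_inv"`.
#' @export
augment_antisymmetric <- function(ds) {
  if (nrow(ds) == 0L) return(ds)
  if (anyNA(ds$ddg_exp)) {
    mbc_stop("mbc_record_error",
             "cannot augment: missing ddg_exp in row(s) %s",
             paste(which(is.na(ds$ddg_exp)), collapse = ", "))
  }
  direct <- as.data.frame(ds)
  if (!"is_complement" %in% names(direct)) direct$is_complement <- FALSE
  comp <- direct
  comp$wt <- direct$mut
  comp$mut <- direct$wt
  comp$ddg_exp <- -direct$ddg_exp
  comp$score_wt <- direct$score_mut
  comp$score_mut <- direct$score_wt
  comp$score_delta <- -direct$score_delta
  comp$is_complement <- !direct$is_complement
  comp$id <- ifelse(grepl("_inv$", direct$id),
                    sub("_inv$", "", direct$id),
                    paste0(direct$id, "_inv"))
  out <- mutation_dataset(rbind(direct, comp),
                          method = attr(ds, "meta")$method,
                          sign_convention = attr(ds, "meta")$sign_convention,
                          source = attr(ds, "meta")$source)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
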