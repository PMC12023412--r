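# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

toy_df <- function() {
  data.frame(
    id = c("r1", "r2", "r3"),
    structure_id = c("1ABC", "1ABC", "2XYZ"),
    chain = c("A", "A", "B"),
    position = c(1L, 5L, 7L),
    wt = c("A", "L", "G"),
    mut = c("V", "P", "W"),
    ddg_exp = c(1.0, -0.5, 2.3),
    score_delta = c(0.4, -0.2, 1.1),
    stringsAsFactors = FALSE)
}

toy_dataset <- function() mutation_dataset(toy_df(), method = "toy")

# Random dataset with complete scores and ddg, for property tests.
random_dataset <- function(n, seed) {
  pairs <- expand.grid(mut = AA_ALPHABET, wt = AA_ALPHABET,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$wt != pairs$mut, ]
  set.seed(seed)
  idx <- sample.int(nrow(pairs), n, replace = TRUE)
  mutation_dataset(data.frame(
    id = sprintf("r%03d", seq_len(n)),
    position = seq_len(n),
    wt = pairs$wt[idx], mut = pairs$mut[idx],
    ddg_exp = stats::rnorm(n),
    score_delta = stats::rnorm(n),
    stringsAsFactors = FALSE))
}

# A random hand-built model of any mode.
random_model <- function(mode, seed) {
  set.seed(seed)
  a <- stats::setNames(stats::rnorm(20), AA_ALPHABET)
  switch(mode,
    dd = mbc_model("dd", a0 = stats::rnorm(1), a = a),
    only = mbc_model("only", a = a),
    rose = mbc_model("rose", a0 = stats::rnorm(1), a1 = stats::rnorm(1),
                     scale = sample(c("rose", "kyte_doolittle"), 1)))
}

# Independent numerical minimizer of the ridge objective, used as the
# oracle against the closed-form solver.
ridge_oracle <- function(X, y, lambda) {
  obj <- function(b) sum((y - X %*% b)^2) + lambda * sum(b^2)
  grad <- function(b) as.numeric(-2 * crossprod(X, y - X %*% b) + 2 * lambda * b)
  stats::optim(rep(0, ncol(X)), obj, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-16))$par
}

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}
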