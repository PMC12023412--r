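test_that("occurrence encoding puts -1 on wild-type, +1 on mutant, zero-sum", {
  o <- encode_mutation("A", "V")
  expect_equal(o[["A"]], -1L)
  expect_equal(o[["V"]], 1L)
  expect_equal(sum(o != 0L), 2L)
  expect_equal(sum(o), 0L)
  expect_identical(encode_mutation("L", "L"),
                   stats::setNames(integer(20), AA_ALPHABET))
  expect_error(encode_mutation("X", "A"), class = "mbc_invalid_residue")
})

test_that("encoding is antisymmetric over all 380 ordered pairs", {
  g <- expand.grid(w = AA_ALPHABET, m = AA_ALPHABET, stringsAsFactors = FALSE)
  g <- g[g$w != g$m, ]
  for (i in seq_len(nrow(g))) {
    expect_identical(encode_mutation(g$w[i], g$m[i]),
                     -encode_mutation(g$m[i], g$w[i]))
  }
  # vectorized encoder agrees with the scalar one
  O <- mbcorrect:::encode_mutations(g$w, g$m)
  expect_equal(rowSums(O), rep(0, nrow(g)))
  expect_equal(O[1, ], as.numeric(encode_mutation(g$w[1], g$m[1])),
               ignore_attr = TRUE)
})

test_that("design matrices have the mode-specific shape and content", {
  ds <- random_dataset(5, seed = 2)
  dd <- build_design_matrix(ds, "dd")
  expect_equal(dim(dd$X), c(5L, 21L))
  expect_equal(dd$X[, 1], ds$score_delta, ignore_attr = TRUE)

  only <- build_design_matrix(ds, "only")
  expect_equal(dim(only$X), c(5L, 20L))
  expect_false("score_delta" %in% colnames(only$X))

  rose <- build_design_matrix(ds, "rose", scale = "rose")
  expect_equal(dim(rose$X), c(5L, 2L))
  expect_equal(rose$X[, 2],
               scale_delta(ds$wt, ds$mut, get_scale("rose")),
               ignore_attr = TRUE)

  expect_error(build_design_matrix(ds, "rose"), class = "mbc_format_error")
  ds$score_delta[3] <- NA
  err <- expect_error(build_design_matrix(ds, "dd"),
                      class = "mbc_incomplete_record")
  expect_match(conditionMessage(err), "3")
  expect_silent(build_design_matrix(ds, "only"))  # mode only needs no scores
})

test_that("closed-form ridge matches OLS interpolation and penalty limits", {
  set.seed(42)
  X <- matrix(rnorm(16), 4, 4)
  y <- rnorm(4)
  b0 <- ridge_solve(X, y, lambda = 0)
  expect_equal(as.numeric(X %*% b0), y, tolerance = 1e-8)
  bb <- ridge_solve(X, y, lambda = 1e12)
  expect_true(all(abs(bb) < 1e-6))
  # rank-deficient with lambda = 0 must raise, with lambda > 0 must solve
  Xr <- cbind(X, X[, 1])
  expect_error(ridge_solve(Xr, y, 0), class = "mbc_singular_system")
  expect_silent(ridge_solve(Xr, y, 0.1))
  expect_error(ridge_solve(X, y, -1), class = "mbc_format_error")
  expect_error(ridge_solve(X, y[1:3], 1), class = "mbc_shape_error")
})

test_that("ridge solver matches an independent numerical minimizer", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(50 * 21), 50, 21)
    y <- rnorm(50)
    b_closed <- ridge_solve(X, y, lambda = 1.0)
    b_num <- ridge_oracle(X, y, lambda = 1.0)
    expect_lt(max(abs(b_closed - b_num)), 1e-6)
  }
})

test_that("noise-free planted models are recovered exactly", {
  ds <- random_dataset(400, seed = 8)
  a_star <- stats::setNames(rnorm(20), AA_ALPHABET)
  O <- mbcorrect:::encode_mutations(ds$wt, ds$mut)
  ds$ddg_exp <- 0.8 * ds$score_delta + as.numeric(O %*% a_star)
  fit <- mbc_fit(ds, "dd", lambda = 1e-8)
  expect_lt(abs(fit$a0 - 0.8), 1e-4)
  # gauge: compare centered coefficient vectors
  expect_lt(max(abs((fit$a - mean(fit$a)) - (a_star - mean(a_star)))), 1e-4)

  # two-parameter variant: y = 2 * rose-delta exactly
  ds2 <- random_dataset(100, seed = 9)
  ds2$ddg_exp <- 2 * scale_delta(ds2$wt, ds2$mut, get_scale("rose"))
  fit2 <- mbc_fit(ds2, "rose", scale = "rose")
  expect_lt(abs(fit2$a1 - 2), 1e-6)
  expect_lt(abs(fit2$a0 - 0), 1e-6)

  expect_error(mbc_fit(toy_dataset()[0, ], "dd"), class = "mbc_empty_input")
})

test_that("prediction follows the mode's linear form", {
  ds <- toy_dataset()
  ident <- mbc_model("dd", a0 = 1, a = stats::setNames(rep(0, 20), AA_ALPHABET))
  expect_equal(predict(ident, ds), ds$score_delta)

  only <- random_model("only", seed = 1)
  same <- mutation_dataset(data.frame(wt = "L", mut = "L", ddg_exp = 0,
                                      score_delta = 5))
  expect_equal(predict(only, same), 0)

  rose <- mbc_model("rose", a0 = 0.5, a1 = 2, scale = "kyte_doolittle")
  expect_equal(predict(rose, ds),
               0.5 * ds$score_delta + 2 * scale_delta(ds$wt, ds$mut,
                                                      "kyte_doolittle"))
})

test_that("every mode predicts antisymmetrically on augmented complements", {
  ds <- random_dataset(40, seed = 6)
  aug <- augment_antisymmetric(ds)
  n <- nrow(ds)
  for (mode in c("dd", "only", "rose")) {
    for (seed in 1:5) {
      m <- random_model(mode, seed)
      p <- predict(m, aug)
      expect_lt(max(abs(p[1:n] + p[(n + 1):(2 * n)])), 1e-10)
    }
    fitted <- mbc_fit(ds, mode, scale = if (mode == "rose") "rose" else NULL)
    p <- predict(fitted, aug)
    expect_lt(max(abs(p[1:n] + p[(n + 1):(2 * n)])), 1e-10)
  }
})

test_that("residue coefficients carry a gauge freedom", {
  ds <- random_dataset(30, seed = 13)
  for (mode in c("dd", "only")) {
    m <- mbc_fit(ds, mode)
    for (c0 in c(-3.7, 0.01, 12)) {
      shifted <- m
      shifted$a <- m$a + c0
      expect_lt(max(abs(predict(shifted, ds) - predict(m, ds))), 1e-12)
    }
  }
})

test_that("no-intercept ridge fit is invariant under antisymmetric augmentation", {
  ds <- random_dataset(80, seed = 21)
  for (mode in c("dd", "only", "rose")) {
    f1 <- mbc_fit(ds, mode, augment = FALSE,
                  scale = if (mode == "rose") "rose" else NULL)
    f2 <- mbc_fit(ds, mode, augment = TRUE,
                  scale = if (mode == "rose") "rose" else NULL)
    expect_lt(max(abs(coef(f1) - coef(f2))), 1e-8)
  }
})
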