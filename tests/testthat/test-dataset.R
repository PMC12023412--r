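test_that("CSV parsing handles canonical columns and compact mutation strings", {
  path <- write_csv_fixture(toy_df())
  ds <- read_mutation_table(path)
  expect_s3_class(ds, "mbc_dataset")
  expect_equal(nrow(ds), 3L)
  expect_equal(ds$wt, c("A", "L", "G"))
  expect_equal(ds$ddg_exp, c(1.0, -0.5, 2.3))
  expect_equal(attr(ds, "parse_report")$n_rejected, 0L)

  # compact mutation-string dialect via column mapping
  path2 <- write_csv_fixture(data.frame(
    mut_str = c("A1V", "L5P", "G7W"),
    ddG = c(1.0, -0.5, 2.3), pred = c(0.4, -0.2, 1.1)))
  ds2 <- read_mutation_table(path2, format_config = list(
    mutation = "mut_str", ddg_exp = "ddG", score_delta = "pred"))
  expect_equal(ds2$wt, ds$wt)
  expect_equal(ds2$position, c(1L, 5L, 7L))
  expect_equal(ds2$mut, ds$mut)
  expect_equal(ds2$score_delta, ds$score_delta)
})

test_that("mutation strings parse to wt/position/mut and reject garbage", {
  p <- parse_mutation_string("A123V")
  expect_equal(p$wt, "A")
  expect_equal(p$position, 123L)
  expect_equal(p$mut, "V")
  expect_error(parse_mutation_string("A12"), class = "mbc_record_error")
  expect_error(parse_mutation_string("123AV"), class = "mbc_record_error")
})

test_that("strict mode fails on bad rows naming them; lenient skips and reports", {
  df <- toy_df()
  df$wt[2] <- "X"
  path <- write_csv_fixture(df)
  err <- expect_error(read_mutation_table(path), class = "mbc_record_error")
  expect_match(conditionMessage(err), "2")
  ds <- read_mutation_table(path, strict = FALSE)
  expect_equal(nrow(ds), 2L)
  rep <- attr(ds, "parse_report")
  expect_equal(rep$n_read, 3L)
  expect_equal(rep$n_rejected, 1L)
  expect_equal(rep$rejected_rows, 2L)
})

test_that("score fields are reconciled: delta derived from states, clashes rejected", {
  df <- data.frame(wt = "A", mut = "V", score_wt = -3.0, score_mut = -2.5)
  ds <- mutation_dataset(df)
  expect_equal(ds$score_delta, 0.5)
  df$score_delta <- 0.6  # inconsistent with mut - wt
  expect_error(mutation_dataset(df), class = "mbc_record_error")
  df$score_delta <- 0.5 + 1e-9  # inside tolerance
  expect_silent(mutation_dataset(df))
})

test_that("merge keeps the primary record on key collision and counts overrides", {
  prim <- mutation_dataset(data.frame(
    id = "p1", structure_id = "1ABC", chain = "A", position = 1L,
    wt = "A", mut = "V", ddg_exp = 1.0))
  sec <- mutation_dataset(data.frame(
    id = c("s1", "s2"), structure_id = c("1ABC", "1ABC"), chain = "A",
    position = c(1L, 2L), wt = c("A", "C"), mut = c("V", "W"),
    ddg_exp = c(2.0, 0.3)))
  merged <- merge_datasets(prim, sec)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$ddg_exp[record_keys(merged) == record_keys(prim)], 1.0)
  expect_equal(attr(merged, "merge_report")$n_overridden, 1L)

  # disjoint union and identity on empty secondary
  disjoint <- merge_datasets(toy_dataset(), mutation_dataset(data.frame(
    structure_id = "9ZZZ", chain = "C", position = 99L,
    wt = "K", mut = "E", ddg_exp = 0.1)))
  expect_equal(nrow(disjoint), 4L)
  same <- merge_datasets(toy_dataset(), toy_dataset()[0, ])
  expect_equal(nrow(same), 3L)

  # duplicate keys within one input
  dup <- mutation_dataset(rbind(toy_df(), toy_df()[1, ]))
  expect_error(merge_datasets(dup, sec), class = "mbc_duplicate_key")
  expect_warning(m2 <- merge_datasets(dup, sec, strict = FALSE), "duplicate")
  # deduped primary (3) + secondary (2) minus the A1V collision kept from primary
  expect_equal(nrow(m2), 4L)
  expect_equal(attr(m2, "merge_report")$n_overridden, 1L)
})

test_that("antisymmetric augmentation doubles the set with negated complements", {
  ds <- mutation_dataset(data.frame(
    id = "r1", wt = "A", mut = "V", ddg_exp = 1.0,
    score_wt = -3.0, score_mut = -2.6))
  aug <- augment_antisymmetric(ds)
  expect_equal(nrow(aug), 2L)
  comp <- aug[2, ]
  expect_equal(comp$wt, "V")
  expect_equal(comp$mut, "A")
  expect_equal(comp$ddg_exp, -1.0)
  expect_equal(comp$score_wt, -2.6)
  expect_equal(comp$score_mut, -3.0)
  expect_equal(comp$score_delta, -0.4)
  expect_true(comp$is_complement)

  # |augment(D)| = 2|D| on a larger set
  big <- random_dataset(50, seed = 4)
  expect_equal(nrow(augment_antisymmetric(big)), 100L)

  # complement of complement restores the original field-for-field:
  # augmenting twice yields [r1, r1_inv, comp(r1), comp(r1_inv)] and the
  # last row must equal the first
  twice <- augment_antisymmetric(augment_antisymmetric(ds))
  orig <- as.data.frame(twice[4, ])
  direct <- as.data.frame(twice[1, ])
  rownames(orig) <- rownames(direct) <- NULL
  expect_identical(orig, direct)

  expect_error(augment_antisymmetric(mutation_dataset(
    data.frame(wt = "A", mut = "V"))), class = "mbc_record_error")
})

test_that("re-augmenting and deduplicating by (key, ddg sign) is idempotent", {
  ds <- random_dataset(20, seed = 11)
  once <- augment_antisymmetric(ds)
  twice <- augment_antisymmetric(once)
  sig <- function(d) sort(paste(record_keys(d), sign(d$ddg_exp)))
  expect_identical(unique(sig(twice)), unique(sig(once)))
})

test_that("dataset read-write-read is idempotent on the canonical dialect", {
  ds <- augment_antisymmetric(random_dataset(25, seed = 9))
  p1 <- tempfile(fileext = ".csv")
  write_mutation_table(ds, p1)
  ds2 <- read_mutation_table(p1)
  p2 <- tempfile(fileext = ".csv")
  write_mutation_table(ds2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(as.data.frame(ds2)$ddg_exp, as.data.frame(ds)$ddg_exp)
  expect_identical(as.data.frame(ds2)$is_complement,
                   as.data.frame(ds)$is_complement)
})

test_that("model JSON save/load round-trips every mode losslessly", {
  ds <- random_dataset(60, seed = 3)
  for (mode in c("dd", "only", "rose")) {
    model <- mbc_fit(ds, mode,
                     scale = if (mode == "rose") "rose" else NULL)
    path <- tempfile(fileext = ".json")
    save_model(model, path)
    back <- load_model(path)
    expect_identical(back$mode, model$mode)
    expect_identical(back$lambda, model$lambda)
    if (!is.null(model$a)) expect_identical(back$a, model$a)
    if (!is.null(model$a0)) expect_identical(back$a0, model$a0)
    if (!is.null(model$a1)) expect_identical(back$a1, model$a1)
    if (mode == "rose") {
      expect_identical(back$scale_name, "rose")
      expect_identical(back$scale_values, model$scale_values)
    }
    expect_equal(predict(back, ds), predict(model, ds))
  }
})

test_that("corrupt or mismatched model files raise FormatError", {
  ds <- random_dataset(30, seed = 5)
  path <- tempfile(fileext = ".json")
  save_model(mbc_fit(ds, "dd"), path)
  txt <- readLines(path)
  trunc <- tempfile(fileext = ".json")
  writeLines(txt[1:(length(txt) %/% 2)], trunc)
  expect_error(load_model(trunc), class = "mbc_format_error")
  wrong <- tempfile(fileext = ".json")
  writeLines(sub("\"schema_version\": 1", "\"schema_version\": 99", txt), wrong)
  expect_error(load_model(wrong), class = "mbc_format_error")
  expect_error(load_model(tempfile()), class = "mbc_not_found")
})
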