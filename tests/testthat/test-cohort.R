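make_records <- function() {
  # 10 patients: 2 without letters, 1 with a letter but no matched category,
  # 7 with at least one flag (one of them PaG-only)
  features <- data.frame(
    patient_id = sprintf("p%02d", 1:10),
    label = c(1, 1, 2, 3, 0, 1, 2, 3, 0, 1),
    q01 = rnorm(10), q02 = rnorm(10))
  flags <- data.frame(patient_id = sprintf("p%02d", 3:10))
  for (fn in flag_names()) flags[[fn]] <- 0L
  flags$RehabReRe[2:7] <- 1L
  flags$PainRedPaG[8] <- 1L  # PaG-only patient
  flags$has_any_rere <- rowSums(flags[, grep("ReRe$", names(flags))]) > 0
  flags$has_any_pag <- rowSums(flags[, grep("PaG$", names(flags))]) > 0
  merge_letter_flags(features, flags)
}

test_that("inclusion keeps lettered patients with at least one flag", {
  records <- make_records()
  kept <- apply_inclusion(records)
  expect_identical(nrow(kept), 7L)
  expect_false(any(c("p01", "p02", "p03") %in% kept$patient_id))
  expect_true("p10" %in% kept$patient_id)  # retained on a patient goal alone
  expect_identical(apply_inclusion(kept), kept)  # idempotent
  none <- records
  for (fn in flag_names()) none[[fn]] <- 0L
  none$has_any_rere <- FALSE; none$has_any_pag <- FALSE
  expect_identical(nrow(apply_inclusion(none)), 0L)
})

test_that("ED and BD share questionnaire columns; ED adds the chosen flags", {
  kept <- apply_inclusion(make_records())
  ds <- build_datasets(kept, ed_flags = default_ed_flags())
  expect_identical(ncol(ds$ED$x), 2L + 8L)
  expect_identical(ncol(ds$BD$x), 2L)
  expect_identical(ds$ED$x[, c("q01", "q02")], ds$BD$x)
  expect_identical(ds$ED$labels, ds$BD$labels)
  expect_false(anyNA(ds$ED$x[, default_ed_flags()]))

  same <- build_datasets(kept, ed_flags = character(0))
  expect_identical(same$ED$x, same$BD$x)
  expect_error(build_datasets(kept, ed_flags = "NoSuchFlag"), "unknown flag")
})

test_that("evaluation split matches the study's training-count arithmetic", {
  ft <- make_counted_ft(c("1" = 571, "2" = 228, "3" = 109, "0" = 301))
  ft <- split_eval(ft, per_class = 50, seed = 42)
  train_counts <- table(ft$labels[ft$split == "train"])
  expect_identical(as.integer(train_counts[c("1", "2", "3", "0")]),
                   c(521L, 178L, 59L, 251L))
  expect_identical(sum(ft$split == "eval"), 200L)
  # label multiset is conserved between splits
  expect_identical(
    as.integer(table(ft$labels[ft$split == "train"])) +
      as.integer(table(ft$labels[ft$split == "eval"])),
    as.integer(table(ft$labels)))
})

test_that("the split is seeded, exhaustive at per_class = 0, and guarded", {
  ft <- make_counted_ft(c("0" = 30, "1" = 40))
  a <- split_eval(ft, per_class = 10, seed = 7)
  b <- split_eval(ft, per_class = 10, seed = 7)
  expect_identical(a$split, b$split)
  c2 <- split_eval(ft, per_class = 10, seed = 8)
  expect_false(identical(a$split, c2$split))
  expect_true(all(split_eval(ft, per_class = 0)$split == "train"))
  expect_error(split_eval(ft, per_class = 31), "class 0")
})

test_that("z-scoring normalizes per split and preserves missingness", {
  x <- data.frame(a = c(1, 2, 3, 10, 20, 30),
                  b = c(5, 5, 5, 1, NA, 3),
                  c = rnorm(6))
  ft <- feature_table(x, labels = c(0, 0, 1, 1, 0, 1))
  ft$split <- c(rep("train", 3), rep("eval", 3))
  z <- zscore_by_split(ft)
  expect_equal(z$x$a[1:3], c(-1, 0, 1))          # 3-point column
  expect_equal(z$x$b[1:3], c(0, 0, 0))           # constant column maps to 0
  expect_true(is.na(z$x$b[5]))                    # missing stays missing
  for (tag in c("train", "eval")) {
    for (cn in names(z$x)) {
      v <- z$x[[cn]][z$split == tag]
      expect_lt(abs(mean(v, na.rm = TRUE)), 1e-9)
    }
  }
  # population convention divides by n instead
  zp <- zscore_by_split(ft, sd_convention = "population")
  expect_equal(zp$x$a[1:3], c(-1, 0, 1) * sqrt(3 / 2))
})

test_that("evaluation rows can reuse training statistics", {
  x <- data.frame(a = c(0, 2, 4, 100, 102))
  ft <- feature_table(x, labels = c(0, 0, 1, 1, 0))
  ft$split <- c("train", "train", "train", "eval", "eval")
  z <- zscore_by_split(ft, eval_mode = "train_params")
  expect_equal(z$x$a[4:5], (c(100, 102) - 2) / 2)  # train mean 2, sd 2
  z2 <- zscore_by_split(ft, eval_mode = "per_split")
  expect_equal(mean(z2$x$a[4:5]), 0)
})

test_that("mean fill completes tables without moving split means", {
  x <- data.frame(a = c(1, NA, 3, NA, 5, 6))
  ft <- feature_table(x, labels = rep(c(0, 1), 3))
  ft$split <- c(rep("train", 4), rep("eval", 2))
  filled <- fill_missing(ft)
  expect_false(anyNA(filled$x))
  expect_equal(filled$x$a[2], 2)  # mean of observed train values 1, 3
  dropped <- complete_cases(ft, quiet = TRUE)
  expect_identical(nrow(dropped$x), 4L)
})

test_that("rerunning assembly with one seed is bit-stable", {
  kept <- apply_inclusion(make_records())
  run_once <- function() {
    ds <- build_datasets(kept)
    ft <- split_eval(ds$ED, per_class = 1, seed = 99)
    zscore_by_split(ft)
  }
  expect_identical(run_once(), run_once())
})
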