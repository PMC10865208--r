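test_that("weights match the exhaustive brute-force oracle", {
  withr::with_seed(20260901, {
    for (case in 1:6) {
      n <- sample(12:40, 1)
      M <- sample(2:8, 1)
      C <- sample(2:4, 1)
      k <- sample(1:6, 1)
      labels <- sample(0:(C - 1), n, replace = TRUE)
      while (length(unique(labels)) < 2) {
        labels <- sample(0:(C - 1), n, replace = TRUE)
      }
      x <- matrix(rnorm(n * M), n, M,
                  dimnames = list(NULL, paste0("f", 1:M)))
      for (mw in c("class_prior", "uniform")) {
        rk <- suppressWarnings(
          relieff_rank(x, labels, k = k, tau = -Inf, miss_weighting = mw))
        w_pkg <- setNames(rk$weight, rk$feature)[colnames(x)]
        w_brute <- relieff_brute(x, labels, k, mw)
        expect_lt(max(abs(w_pkg - w_brute)), 1e-9)
      }
    }
  })
})

test_that("missing values are handled via the mean observed diff, matching the oracle", {
  withr::with_seed(4, {
    x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
    x[sample(length(x), 15)] <- NA
    labels <- sample(0:1, 30, replace = TRUE)
  })
  rk <- suppressWarnings(relieff_rank(x, labels, k = 3, tau = -Inf))
  w_pkg <- setNames(rk$weight, rk$feature)[colnames(x)]
  expect_lt(max(abs(w_pkg - relieff_brute(x, labels, 3))), 1e-9)
})

test_that("a perfectly separating feature outranks pure noise", {
  withr::with_seed(11, {
    x <- data.frame(sep = rep(c(0, 1), each = 20) + rnorm(40, sd = 0.01),
                    noise = rnorm(40))
  })
  ft <- feature_table(x, labels = rep(c(0L, 1L), each = 20))
  rk <- suppressWarnings(relieff_rank(ft, k = 5, tau = -Inf))
  expect_identical(rk$feature[1], "sep")
  expect_gt(rk$weight[rk$feature == "sep"], rk$weight[rk$feature == "noise"])
})

test_that("constant features score exactly zero", {
  withr::with_seed(2, {
    x <- data.frame(const = rep(3.7, 24), live = rnorm(24))
  })
  ft <- feature_table(x, labels = rep(0:1, 12))
  rk <- suppressWarnings(relieff_rank(ft, k = 3, tau = -Inf))
  expect_identical(rk$weight[rk$feature == "const"], 0)
})

test_that("the score column is the literal opposite-sign statistic", {
  ft <- make_counted_ft(c("0" = 10, "1" = 10), n_feat = 3, seed = 6)
  rk <- suppressWarnings(relieff_rank(ft, k = 2, tau = -Inf))
  expect_equal(rk$score, -rk$weight)
})

test_that("weights are invariant to row permutation and feature rescaling", {
  withr::with_seed(8, {
    x <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("f", 1:5)))
    labels <- sample(0:2, 30, replace = TRUE)
    perm <- sample(30)
  })
  rk1 <- suppressWarnings(relieff_rank(x, labels, k = 4, tau = -Inf))
  rk2 <- suppressWarnings(relieff_rank(x[perm, ], labels[perm], k = 4,
                                       tau = -Inf))
  w1 <- setNames(rk1$weight, rk1$feature)[colnames(x)]
  w2 <- setNames(rk2$weight, rk2$feature)[colnames(x)]
  expect_lt(max(abs(w1 - w2)), 1e-12)

  scaled <- x
  scaled[, 2] <- scaled[, 2] * 250
  rk3 <- suppressWarnings(relieff_rank(scaled, labels, k = 4, tau = -Inf))
  w3 <- setNames(rk3$weight, rk3$feature)[colnames(x)]
  expect_lt(max(abs(w1 - w3)), 1e-12)
})

test_that("selection respects the threshold, rank order and guards", {
  ft <- make_counted_ft(c("0" = 12, "1" = 12), n_feat = 4, seed = 10)
  rk <- suppressWarnings(relieff_rank(ft, k = 3, tau = -Inf))
  all_kept <- select_features(rk, ft)
  expect_identical(feature_names(all_kept), rk$feature)  # ordered by rank
  top2 <- select_features(rk, ft, n_top = 2)
  expect_identical(feature_names(top2), rk$feature[1:2])

  rk_high <- suppressWarnings(relieff_rank(ft, k = 3, tau = 10))
  expect_error(select_features(rk_high, ft), "no feature reaches")
})

test_that("single-class input is rejected and small classes clamp k", {
  ft <- make_counted_ft(c("0" = 10))
  expect_error(suppressWarnings(relieff_rank(ft, k = 2)), "two classes")
  ft2 <- make_counted_ft(c("0" = 20, "1" = 4))
  expect_warning(relieff_rank(ft2, k = 10, tau = -Inf), "clamped")
})
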