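# empirical mutual information (nats) between a binary flag and the class
flag_mi <- function(flag, label) {
  tab <- table(flag, label)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  mi
}

test_that("generation is a pure function of the spec", {
  spec <- cohort_spec(n_patients = 150, seed = 33)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$patients, b$patients)
  expect_identical(lapply(a$letters, unclass), lapply(b$letters, unclass))
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(cohort_spec(n_patients = 150, seed = 34))
  expect_false(identical(a$patients, c2$patients))
})

test_that("an empty cohort yields empty outputs", {
  co <- generate_cohort(cohort_spec(n_patients = 0))
  expect_identical(nrow(co$patients), 0L)
  expect_length(co$letters, 0L)
  expect_identical(nrow(co$truth), 0L)
})

test_that("class proportions approach the study priors in a large cohort", {
  co <- generate_cohort(cohort_spec(n_patients = 5000, seed = 77))
  prop <- as.numeric(table(factor(co$patients$label, levels = 0:3))) / 5000
  expect_true(all(abs(prop - c(0.249, 0.472, 0.189, 0.090)) < 0.02))
})

test_that("questionnaire block has ordinal bins, missing cells and informative shift", {
  spec <- cohort_spec(n_patients = 2000, effect_size = 1, missing_rate = 0.05,
                      seed = 55)
  co <- generate_cohort(spec)
  q <- co$patients[, co$informative[1]]  # q01, ordinal, shifted for class 0
  expect_true(all(q[!is.na(q)] %in% 1:5))
  q02 <- co$patients$q02  # continuous informative feature, shifted for class 1
  expect_gt(mean(q02[co$patients$label == 1], na.rm = TRUE),
            mean(q02[co$patients$label != 1], na.rm = TRUE) + 0.5)
  miss <- mean(is.na(as.matrix(co$patients[, -(1:2)])))
  expect_gt(miss, 0.03); expect_lt(miss, 0.07)
  noise <- co$patients$q40
  for (cl in 0:3) {
    expect_lt(abs(mean(noise[co$patients$label == cl], na.rm = TRUE)), 0.2)
  }
})

test_that("extraction recovers planted categories perfectly on clean templates", {
  spec <- cohort_spec(n_patients = 250, p_no_letter = 0, seed = 66,
                      rere_probs = matrix(1, 4, 5), pag_probs = matrix(1, 4, 4))
  co <- generate_cohort(spec)
  got <- flags_table(co$letters, default_lexicon())
  m <- merge(got, co$truth, by = "patient_id", suffixes = c(".got", ".true"))
  for (fn in flag_names()) {
    expect_identical(m[[paste0(fn, ".got")]],
                     as.integer(m[[paste0(fn, ".true")]]))
  }
})

test_that("signal injection interpolates probabilities elementwise", {
  spec <- cohort_spec()
  mid <- inject_letter_signal(spec, 0.5)
  lo <- inject_letter_signal(spec, 0)
  hi <- inject_letter_signal(spec, 1)
  expect_equal(mid$rere_probs, (lo$rere_probs + hi$rere_probs) / 2)
  expect_equal(hi$rere_probs, default_rere_probs(),
               ignore_attr = TRUE)
  # strength 0 rows are identical across classes
  expect_true(all(apply(lo$rere_probs, 2, function(col) diff(range(col)) == 0)))
  expect_error(inject_letter_signal(spec, 1.5), "\\[0, 1\\]")
})

test_that("letter flags are uninformative at strength 0 and informative at 1", {
  mi_at <- function(strength, seed) {
    spec <- inject_letter_signal(
      cohort_spec(n_patients = 4000, seed = seed), strength)
    co <- generate_cohort(spec)
    keep <- co$truth$has_letter
    mean(vapply(c("AnesthesiologyReRe", "RehabReRe"), function(fn) {
      flag_mi(co$truth[[fn]][keep], co$truth$label[keep])
    }, numeric(1)))
  }
  for (seed in c(101, 102, 103)) {
    expect_lt(mi_at(0, seed), 0.01)
    expect_gt(mi_at(1, seed), mi_at(0, seed))
  }
})

test_that("invalid specifications are rejected", {
  expect_error(cohort_spec(class_priors = c(0.5, 0.5, 0.5, 0.5)), "summing to 1")
  expect_error(cohort_spec(missing_rate = 1.2), "probability")
  expect_error(cohort_spec(n_informative = 50), "cannot exceed")
  expect_error(cohort_spec(rere_probs = matrix(2, 4, 5)), "rere_probs")
})
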