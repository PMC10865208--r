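lex <- default_lexicon()

test_that("normalization folds case, unifies variants and is idempotent", {
  expect_equal(normalize_text("Graag REVALIDATIE.", lex),
               "graag revalidatie.")
  expect_equal(normalize_text("tweede mening", lex), "2e mening")
  expect_equal(normalize_text("", lex), "")
  expect_equal(normalize_text("pati\u00ebnt met  rugklachten\n", lex),
               "patient met rugklachten")
  raw <- c("Graag een TWEEDE Mening", "  witruimte \t hier ", "BLOCKADE")
  once <- normalize_text(raw, lex)
  expect_identical(normalize_text(once, lex), once)
})

test_that("an invalid unification rule is reported as a configuration error", {
  bad <- lex
  bad$unification_rules <- list(list(pattern = "(", replacement = "x"))
  expect_error(as_lex <- lbptriage:::as_triage_lexicon(unclass(bad)),
               "unification rule 1")
})

test_that("lexicon validation rejects duplicate categories and empty patterns", {
  raw <- unclass(lex)
  raw$patient_goal$RehabReRe <- "x"
  expect_error(lbptriage:::as_triage_lexicon(raw), "unique")
  raw2 <- unclass(lex)
  raw2$referral_reason$RehabReRe <- character(0)
  expect_error(lbptriage:::as_triage_lexicon(raw2), "at least one")
})

test_that("segmentation spans marker to next marker or end of text", {
  txt <- normalize_text(
    "intro zin. reden van verwijzing: graag revalidatie. hulpvraag: minder pijn.",
    lex)
  seg <- segment_letter(txt, lex)
  expect_match(seg$rere, "revalidatie")
  expect_false(grepl("pijn", seg$rere))
  expect_match(seg$pag, "minder pijn")
  expect_false(grepl("revalidatie", seg$pag))

  expect_identical(segment_letter("geen markers hier", lex),
                   list(rere = NULL, pag = NULL))

  pag_only <- segment_letter(normalize_text(
    "intro. hulpvraag: ik wil weten wat er aan de hand is.", lex), lex)
  expect_null(pag_only$rere)
  expect_match(pag_only$pag, "aan de hand")
})

test_that("flags fire per category inside the matching segment only", {
  fl <- extract_flags("reden van verwijzing: graag revalidatie.", lex)
  expect_identical(unname(fl$referral_reason["RehabReRe"]), 1L)
  expect_identical(sum(fl$referral_reason), 1L)
  expect_true(fl$has_any_rere)
  expect_false(fl$has_any_pag)

  # multi-label patient goal: pain reduction AND more diagnostics
  fl2 <- extract_flags(
    "hulpvraag: een oplossing voor mijn pijn, en graag een 2e mening.", lex)
  expect_identical(unname(fl2$patient_goal["PainRedPaG"]), 1L)
  expect_identical(unname(fl2$patient_goal["MoreCausePaG"]), 1L)
  expect_false(fl2$has_any_rere)

  # a ReRe code word inside the patient-goal segment must not set a ReRe flag
  fl3 <- extract_flags(
    "reden van verwijzing: advies. hulpvraag: graag revalidatie.", lex)
  expect_identical(unname(fl3$referral_reason["RehabReRe"]), 0L)
  expect_identical(unname(fl3$referral_reason["AdviceReRe"]), 1L)

  empty <- extract_flags("", lex)
  expect_identical(sum(empty$referral_reason) + sum(empty$patient_goal), 0L)
  expect_false(empty$has_any_rere || empty$has_any_pag)
})

test_that("extraction is deterministic and monotone in the lexicon", {
  letters_txt <- c(
    "reden van verwijzing: graag blokkade. hulpvraag: minder pijn.",
    "intro. hulpvraag: advies over mijn rug.",
    "zomaar wat tekst zonder structuur met revalidatie erin.")
  before <- lapply(letters_txt, extract_flags, lexicon = lex)
  expect_identical(lapply(letters_txt, extract_flags, lexicon = lex), before)

  # adding a code word to a category can only switch flags 0 -> 1
  lex2 <- unclass(lex)
  lex2$referral_reason$RehabReRe <- c(lex2$referral_reason$RehabReRe, "rug")
  lex2 <- lbptriage:::as_triage_lexicon(lex2)
  after <- lapply(letters_txt, extract_flags, lexicon = lex2)
  for (i in seq_along(letters_txt)) {
    expect_true(all(after[[i]]$referral_reason >= before[[i]]$referral_reason))
    expect_true(all(after[[i]]$patient_goal >= before[[i]]$patient_goal))
  }
})

test_that("whole-letter fallback applies only when no marker matches", {
  free_text <- "wij vragen om revalidatie voor deze man"
  expect_identical(
    unname(extract_flags(free_text, lex)$referral_reason["RehabReRe"]), 1L)
  no_fallback <- unclass(lex)
  no_fallback$fallback_whole_letter <- FALSE
  no_fallback <- lbptriage:::as_triage_lexicon(no_fallback)
  expect_false(extract_flags(free_text, no_fallback)$has_any_rere)
})

test_that("initial-letter selection is minimal by date with stable ties", {
  l1 <- referral_letter("p1", "2019-05-01", "later")
  l2 <- referral_letter("p1", "2018-12-31", "eerste")
  expect_identical(select_initial_letter(list(l1, l2))$text, "eerste")

  s1 <- referral_letter("p2", "2019-01-01", "a")
  s2 <- referral_letter("p2", "2019-01-01", "b")
  expect_identical(select_initial_letter(list(s1, s2))$text, "a")
  expect_identical(select_initial_letter(list(s2, s1))$text, "b")

  expect_null(select_initial_letter(list()))
  expect_error(select_initial_letter(list(l1, s1)), "one patient")
})

test_that("letters round-trip through JSON lines", {
  letters <- list(
    referral_letter("p1", "2019-01-02", "reden van verwijzing: advies."),
    referral_letter("p2", "2019-03-04", "hulpvraag: minder pijn."))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_letters(letters, path)
  back <- read_letters(path)
  expect_identical(lapply(back, unclass), lapply(letters, unclass))
})

test_that("occurrence report cross-tabulates flags by class with consistent sums", {
  flags <- data.frame(
    SecondOpinionReRe = c(0L, 0L, 0L, 0L), AnesthesiologyReRe = c(0L, 1L, 0L, 0L),
    RehabReRe = c(1L, 1L, 0L, 0L), AdviceReRe = c(0L, 0L, 0L, 0L),
    OptionsReRe = c(0L, 0L, 0L, 0L), MoreCausePaG = c(0L, 0L, 1L, 0L),
    PainRedPaG = c(1L, 0L, 1L, 0L), BetterFuncPaG = c(0L, 0L, 0L, 0L),
    AdvicePaG = c(0L, 0L, 0L, 0L))
  labels <- c(1, 1, 2, 0)
  rpt <- corpus_occurrence_report(flags, labels)
  tab <- rpt$table
  expect_identical(tab$total[tab$category == "RehabReRe"], 2)
  expect_equal(tab$pct_of_family[tab$category == "RehabReRe"], 100 * 2 / 3)
  # per-class cells sum to the overall count for every category
  class_cols <- grep("^class_", names(tab), value = TRUE)
  expect_equal(rowSums(tab[, class_cols]), tab$total)
  # family column sums match the summed table (the printed "Sum" row)
  expect_equal(unname(rpt$class_totals["referral_reason", "class_1"]), 3)

  zero <- corpus_occurrence_report(flags[0, ], integer(0))
  expect_true(all(zero$table$total == 0))
  expect_error(corpus_occurrence_report(flags, c(1, 2)), "length")
})
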