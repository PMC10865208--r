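#' Default class-conditional occurrence probabilities of the letter flags
#'
#' Per-class Bernoulli probabilities that a referral letter of a patient in
#' a given triage class carries each referral-reason (`default_rere_probs`)
#' or patient-goal (`default_pag_probs`) category. The values are the
#' published category-by-class training occurrence counts divided by the
#' training class sizes, so the generated corpus reproduces the study's
#' occurrence structure at any cohort size. Rows are classes 0-3, columns
#' the category names.
#'
#' @return Numeric matrix (4 classes x categories).
#' @export
default_rere_probs <- function() {
  m <- rbind(
    "0" = c(76, 6, 47, 24, 16) / 251,
    "1" = c(167, 22, 302, 71, 85) / 521,
    "2" = c(56, 80, 30, 20, 36) / 178,
    "3" = c(33, 6, 8, 7, 10) / 59)
  colnames(m) <- c("SecondOpinionReRe", "AnesthesiologyReRe", "RehabReRe",
                   "AdviceReRe", "OptionsReRe")
  m
}

#' @rdname default_rere_probs
#' @export
default_pag_probs <- function() {
  m <- rbind(
    "0" = c(30, 65, 44, 5) / 251,
    "1" = c(78, 126, 107, 13) / 521,
    "2" = c(9, 16, 13, 1) / 178,
    "3" = c(2, 4, 4, 0) / 59)
  colnames(m) <- c("MoreCausePaG", "PainRedPaG", "BetterFuncPaG", "AdvicePaG")
  m
}

default_class_priors <- function() {
  setNames(c(301, 571, 228, 109) / 1209, as.character(0:3))
}

default_noise_vocab <- function() {
  # filler Dutch words chosen to contain no code word, marker or substring
  # of either, so noise text can never set a flag
  c("de", "heer", "mevrouw", "heeft", "al", "geruime", "tijd", "last",
    "van", "de", "lage", "rug", "en", "is", "bekend", "bij", "uw",
    "centrum", "wij", "zien", "uw", "beoordeling", "graag", "tegemoet",
    "voorgeschiedenis", "vermeldt", "geen", "bijzonderheden", "medicatie",
    "paracetamol", "gebruikt", "dagelijks", "werkzaam", "als", "conservatief",
    "beleid", "tot", "nu", "toe", "zonder", "blijvend", "resultaat")
}

#' Specify a synthetic triage cohort
#'
#' Bundles every knob of the generator: cohort size, the class imbalance of
#' the study population, the questionnaire feature block (informative
#' features get a class-dependent mean shift of `effect_size` standard
#' deviations; the rest are pure noise; odd-numbered columns are
#' discretised to 1-5 ordinals by fixed cut points shared across classes),
#' per-cell missingness, the probability of lacking a referral letter, the
#' probability of a redundant second letter, and the class-conditional
#' occurrence probabilities of the nine letter-flag categories.
#'
#' @param n_patients Number of patients.
#' @param class_priors Probabilities of classes 0-3 (default: the study's
#'   included-cohort proportions 301:571:228:109).
#' @param n_questionnaire_features Total questionnaire columns (default 40).
#' @param n_informative How many carry class signal (default 10).
#' @param effect_size Mean shift in SD units for informative features
#'   (default 1).
#' @param missing_rate Per-cell probability of a missing questionnaire value
#'   (default 0.05).
#' @param rere_probs,pag_probs Class-by-category occurrence probability
#'   matrices (defaults [default_rere_probs()] / [default_pag_probs()]).
#' @param p_no_letter Probability a patient has no referral letter
#'   (default 0.166).
#' @param p_second_letter Probability a patient with a letter has a later
#'   redundant one (default 0.837); only the initial letter defines truth.
#' @param noise_vocab Filler word list for letter text.
#' @param seed Integer seed; the whole cohort is a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 1608,
                        class_priors = default_class_priors(),
                        n_questionnaire_features = 40,
                        n_informative = 10,
                        effect_size = 1.0,
                        missing_rate = 0.05,
                        rere_probs = default_rere_probs(),
                        pag_probs = default_pag_probs(),
                        p_no_letter = 0.166,
                        p_second_letter = 0.837,
                        noise_vocab = default_noise_vocab(),
                        seed = 1L) {
  stopifnot(n_patients >= 0, n_questionnaire_features >= 1)
  if (n_informative > n_questionnaire_features) {
    stop("n_informative cannot exceed n_questionnaire_features", call. = FALSE)
  }
  class_priors <- as.numeric(class_priors)
  if (length(class_priors) != 4L || any(class_priors < 0) ||
      abs(sum(class_priors) - 1) > 1e-8) {
    stop("class_priors must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  for (nm in c("missing_rate", "p_no_letter", "p_second_letter")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop(nm, " must be a probability in [0, 1]", call. = FALSE)
    }
  }
  check_probs <- function(m, nm, ncat) {
    m <- as.matrix(m)
    if (nrow(m) != 4L || ncol(m) != ncat || any(m < 0) || any(m > 1)) {
      stop(nm, " must be a 4 x ", ncat, " matrix of probabilities",
           call. = FALSE)
    }
    rownames(m) <- as.character(0:3)
    m
  }
  rere_probs <- check_probs(rere_probs, "rere_probs", 5L)
  pag_probs <- check_probs(pag_probs, "pag_probs", 4L)
  structure(
    list(n_patients = as.integer(n_patients),
         class_priors = setNames(class_priors, as.character(0:3)),
         n_questionnaire_features = as.integer(n_questionnaire_features),
         n_informative = as.integer(n_informative),
         effect_size = effect_size, missing_rate = missing_rate,
         rere_probs = rere_probs, pag_probs = pag_probs,
         p_no_letter = p_no_letter, p_second_letter = p_second_letter,
         noise_vocab = as.character(noise_vocab), seed = as.integer(seed)),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> n = %d, %d questionnaire features (%d informative, effect %.2f)\n",
    x$n_patients, x$n_questionnaire_features, x$n_informative, x$effect_size))
  cat(sprintf("  priors: %s | missing %.2f | no-letter %.3f | seed %d\n",
              paste(sprintf("%.3f", x$class_priors), collapse = "/"),
              x$missing_rate, x$p_no_letter, x$seed))
  invisible(x)
}

#' Dial the class signal carried by the referral letters
#'
#' Interpolates the flag occurrence probabilities between a class-independent
#' corpus (`strength = 0`: every class shares the marginal category
#' frequencies, so the flags carry no information about the triage class)
#' and the fully class-conditional study pattern (`strength = 1`, the
#' generator default, where e.g. the anesthesiology referral reason is far
#' likelier under the anesthesiology class). Interpolation is elementwise
#' linear, so `strength = 0.5` gives the exact midpoint matrices.
#'
#' @param spec A [cohort_spec()].
#' @param strength Real in \[0, 1\].
#' @return The spec with `rere_probs` / `pag_probs` replaced.
#' @export
inject_letter_signal <- function(spec, strength) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.numeric(strength) || length(strength) != 1L || is.na(strength) ||
      strength < 0 || strength > 1) {
    stop("strength must be a single value in [0, 1]", call. = FALSE)
  }
  blend <- function(p1) {
    marginal <- colSums(p1 * spec$class_priors)  # class-independent profile
    p0 <- matrix(marginal, nrow = 4, ncol = ncol(p1), byrow = TRUE,
                 dimnames = dimnames(p1))
    (1 - strength) * p0 + strength * p1
  }
  spec$rere_probs <- blend(default_rere_probs())
  spec$pag_probs <- blend(default_pag_probs())
  spec
}

# one canonical planted phrase per category; each fires exactly its own
# category's patterns and no other category of the same family
planted_phrases <- function() {
  c(SecondOpinionReRe = "aanvullend onderzoek",
    AnesthesiologyReRe = "blokkade",
    RehabReRe = "revalidatie",
    AdviceReRe = "advies",
    OptionsReRe = "behandelbare opties",
    MoreCausePaG = "2e mening",
    PainRedPaG = "minder pijn",
    BetterFuncPaG = "beter functioneren",
    AdvicePaG = "advies")
}

#' Generate a fully synthetic triage cohort
#'
#' Draws triage labels from the class priors, builds the questionnaire block
#' (informative feature `j` is mean-shifted by `effect_size` for patients of
#' class `(j - 1) mod 4`; odd columns are binned to 1-5 ordinals with fixed
#' quantile cut points; cells go missing at `missing_rate`), and writes one
#' or two Dutch referral letters per lettered patient. Each letter opens
#' with filler text, then a referral-reason section and/or a patient-goal
#' section — present only when at least one category of that family was
#' planted — whose code words are embedded verbatim. The planted categories
#' of the initial letter are recorded as ground truth, so extraction can be
#' scored exactly.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `synthetic_cohort`: `patients` (data frame with
#'   `patient_id`, `label` and questionnaire columns), `letters` (list of
#'   [referral_letter()]), `truth` (per-patient planted 0/1 categories plus
#'   `has_letter`), `informative` (names of the informative questionnaire
#'   features) and the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  mq <- spec$n_questionnaire_features
  qnames <- sprintf("q%02d", seq_len(mq))
  informative <- qnames[seq_len(spec$n_informative)]
  if (n == 0L) {
    empty_q <- as.data.frame(matrix(numeric(0), 0, mq,
                                    dimnames = list(NULL, qnames)))
    truth <- data.frame(patient_id = character(), label = integer(),
                        has_letter = logical())
    for (fn in flag_names()) truth[[fn]] <- integer()
    return(structure(list(
      patients = cbind(data.frame(patient_id = character(),
                                  label = integer()), empty_q),
      letters = list(), truth = truth, informative = informative,
      spec = spec), class = "synthetic_cohort"))
  }
  withr::with_seed(spec$seed, {
    pid <- sprintf("pt%05d", seq_len(n))
    labels <- sample(0:3, n, replace = TRUE, prob = spec$class_priors)

    x <- matrix(stats::rnorm(n * mq), n, mq, dimnames = list(NULL, qnames))
    for (j in seq_len(spec$n_informative)) {
      target_class <- (j - 1L) %% 4L
      x[, j] <- x[, j] + spec$effect_size * (labels == target_class)
    }
    ordinal <- which(seq_len(mq) %% 2L == 1L)
    cuts <- stats::qnorm(c(0.2, 0.4, 0.6, 0.8))  # fixed, shared across classes
    for (j in ordinal) x[, j] <- findInterval(x[, j], cuts) + 1
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(n * mq) < spec$missing_rate, n, mq)
      x[mask] <- NA_real_
    }

    has_letter <- stats::runif(n) >= spec$p_no_letter
    planted <- matrix(0L, n, 9L, dimnames = list(NULL, flag_names()))
    for (cl in 0:3) {
      rows <- which(labels == cl & has_letter)
      if (!length(rows)) next
      probs <- c(spec$rere_probs[as.character(cl), ],
                 spec$pag_probs[as.character(cl), ])
      draws <- matrix(stats::runif(length(rows) * 9L), length(rows), 9L)
      planted[rows, ] <- ifelse(draws < rep(probs, each = length(rows)),
                                1L, 0L)
    }

    letters <- list()
    base_date <- as.Date("2019-01-01")
    for (i in which(has_letter)) {
      d0 <- base_date + sample.int(365L, 1L)
      letters[[length(letters) + 1L]] <-
        referral_letter(pid[i], d0,
                        compose_letter(planted[i, ], spec$noise_vocab))
      if (stats::runif(1) < spec$p_second_letter) {
        # later, redundant letter: independent content, never the truth
        probs <- c(spec$rere_probs[as.character(labels[i]), ],
                   spec$pag_probs[as.character(labels[i]), ])
        extra <- ifelse(stats::runif(9L) < probs, 1L, 0L)
        letters[[length(letters) + 1L]] <-
          referral_letter(pid[i], d0 + sample.int(120L, 1L),
                          compose_letter(extra, spec$noise_vocab))
      }
    }
  })
  patients <- cbind(data.frame(patient_id = pid, label = labels,
                               stringsAsFactors = FALSE),
                    as.data.frame(x))
  truth <- cbind(data.frame(patient_id = pid, label = labels,
                            has_letter = has_letter,
                            stringsAsFactors = FALSE),
                 as.data.frame(planted))
  structure(list(patients = patients, letters = letters, truth = truth,
                 informative = informative, spec = spec),
            class = "synthetic_cohort")
}

compose_letter <- function(flags, vocab) {
  phrases <- planted_phrases()
  filler <- function(k) paste(sample(vocab, k, replace = TRUE), collapse = " ")
  parts <- c("geachte collega,", filler(sample(4:8, 1)), ".")
  rere_on <- names(flags)[flags == 1L & grepl("ReRe$", names(flags))]
  pag_on <- names(flags)[flags == 1L & grepl("PaG$", names(flags))]
  if (length(rere_on)) {
    parts <- c(parts, "reden van verwijzing: graag",
               paste(phrases[rere_on], collapse = ", "), ".")
  }
  if (length(pag_on)) {
    parts <- c(parts, "hulpvraag: betrokkene wil",
               paste(phrases[pag_on], collapse = ", "), ".")
  }
  parts <- c(parts, "met vriendelijke groet.")
  paste(parts, collapse = " ")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d letters, %d features\n",
              nrow(x$patients), length(x$letters),
              x$spec$n_questionnaire_features))
  invisible(x)
}
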