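#' Load an extraction lexicon
#'
#' The lexicon drives every step of letter mining: category code words
#' (regular-expression patterns) for the 5 referral-reason (ReRe) and 4
#' patient-goal (PaG) categories, the section markers that open the
#' referral-reason and patient-goal segments, and ordered unification
#' rewrites applied before any matching (so variant spellings collapse onto
#' one canonical code word).
#'
#' @param path Path to a YAML or JSON file mirroring the shipped
#'   `inst/extdata/lexicon.yaml`.
#' @return An object of class `triage_lexicon`: a list with elements
#'   `referral_reason`, `patient_goal` (named lists of pattern vectors),
#'   `section_markers` (list with `referral_reason`, `patient_goal`),
#'   `unification_rules` (ordered list of `pattern`/`replacement` pairs) and
#'   `fallback_whole_letter` (logical).
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("no such lexicon file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_triage_lexicon(raw)
}

#' The lexicon shipped with the package
#'
#' Encodes the published ReRe/PaG category exemplars plus documented
#' extensions; treat it as a reconstruction to be adapted per site.
#'
#' @return A `triage_lexicon`.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon.yaml", package = "lbptriage"))
}

as_triage_lexicon <- function(x) {
  stopifnot(is.list(x))
  for (fam in c("referral_reason", "patient_goal")) {
    if (is.null(x[[fam]]) || length(x[[fam]]) == 0L) {
      stop("lexicon lacks any ", fam, " category", call. = FALSE)
    }
    x[[fam]] <- lapply(x[[fam]], function(p) as.character(unlist(p)))
  }
  cats <- c(names(x$referral_reason), names(x$patient_goal))
  if (anyDuplicated(cats)) {
    stop("lexicon category names must be unique; duplicated: ",
         paste(unique(cats[duplicated(cats)]), collapse = ", "), call. = FALSE)
  }
  for (fam in c("referral_reason", "patient_goal")) {
    for (nm in names(x[[fam]])) {
      pats <- x[[fam]][[nm]]
      if (length(pats) < 1L || any(!nzchar(pats))) {
        stop("category ", nm, " must have at least one non-empty pattern",
             call. = FALSE)
      }
      for (p in pats) assert_valid_regex(p, paste0("category ", nm))
    }
  }
  x$section_markers <- lapply(x$section_markers, function(p) as.character(unlist(p)))
  if (is.null(x$section_markers$referral_reason) ||
      is.null(x$section_markers$patient_goal)) {
    stop("lexicon must define section_markers for referral_reason and patient_goal",
         call. = FALSE)
  }
  if (is.null(x$unification_rules)) x$unification_rules <- list()
  for (i in seq_along(x$unification_rules)) {
    r <- x$unification_rules[[i]]
    if (is.null(r$pattern) || is.null(r$replacement)) {
      stop("unification rule ", i, " must have `pattern` and `replacement`",
           call. = FALSE)
    }
    assert_valid_regex(r$pattern, paste0("unification rule ", i))
  }
  if (is.null(x$fallback_whole_letter)) x$fallback_whole_letter <- TRUE
  x$fallback_whole_letter <- isTRUE(x$fallback_whole_letter)
  structure(x, class = "triage_lexicon")
}

assert_valid_regex <- function(pattern, where) {
  ok <- tryCatch({grepl(pattern, "", perl = TRUE); TRUE},
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    stop("invalid regular expression in ", where, ": '", pattern, "'",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.triage_lexicon <- function(x, ...) {
  cat(sprintf(
    "<triage_lexicon> %d referral-reason + %d patient-goal categories, %d unification rules\n",
    length(x$referral_reason), length(x$patient_goal),
    length(x$unification_rules)))
  invisible(x)
}

#' Category names of a lexicon
#' @param lexicon A `triage_lexicon`.
#' @return Character vector of category names (ReRe first, then PaG).
#' @export
lexicon_categories <- function(lexicon) {
  c(names(lexicon$referral_reason), names(lexicon$patient_goal))
}

# lower-case + transliterate diacritics so downstream matching is pure ASCII
transliterate_ascii <- function(x) {
  from <- paste0(
    "\u00e1\u00e0\u00e2\u00e4\u00e3",  # a variants
    "\u00e9\u00e8\u00ea\u00eb",        # e variants
    "\u00ed\u00ec\u00ee\u00ef",        # i variants
    "\u00f3\u00f2\u00f4\u00f6\u00f5",  # o variants
    "\u00fa\u00f9\u00fb\u00fc",        # u variants
    "\u00fd\u00ff\u00e7\u00f1")        # y variants, c-cedilla, n-tilde
  to <- "aaaaaeeeeiiiiooooouuuuyycn"
  x <- chartr(from, to, x)
  out <- iconv(x, from = "UTF-8", to = "ASCII", sub = " ")
  out[is.na(out)] <- x[is.na(out)]
  out
}

#' Normalize referral-letter text
#'
#' Lower-cases, transliterates diacritics to ASCII, applies the lexicon's
#' unification rewrites in order, and collapses whitespace. The operation is
#' idempotent: normalizing twice equals normalizing once.
#'
#' @param raw Character vector of raw letter text (may be empty strings).
#' @param lexicon A `triage_lexicon`; its `unification_rules` are applied in
#'   list order.
#' @return Character vector of normalized text.
#' @examples
#' lex <- default_lexicon()
#' normalize_text("Graag REVALIDATIE.", lex)
#' normalize_text("graag een tweede mening", lex)  # unified to "2e mening"
#' @export
normalize_text <- function(raw, lexicon = default_lexicon()) {
  x <- tolower(as.character(raw))
  x <- transliterate_ascii(x)
  for (i in seq_along(lexicon$unification_rules)) {
    r <- lexicon$unification_rules[[i]]
    x <- tryCatch(
      gsub(r$pattern, r$replacement, x, perl = TRUE),
      error = function(e) {
        stop("unification rule ", i, " ('", r$pattern,
             "') failed to apply: ", conditionMessage(e), call. = FALSE)
      })
  }
  x <- gsub("[ \t\r\n]+", " ", x)
  trimws(x)
}

#' Split a normalized letter into referral-reason and patient-goal segments
#'
#' Each segment runs from the end of its first section marker to the start of
#' the next marker of either family (or the end of text), so segments never
#' overlap. A family whose marker does not occur yields `NULL` — absence is a
#' valid outcome; letters carrying only a patient-goal section are common.
#'
#' @param text A single normalized letter (see [normalize_text()]).
#' @param lexicon A `triage_lexicon` providing `section_markers`.
#' @return List with elements `rere` and `pag` (character or `NULL`).
#' @export
segment_letter <- function(text, lexicon = default_lexicon()) {
  stopifnot(length(text) == 1L)
  hits <- marker_hits(text, lexicon)
  if (nrow(hits) == 0L) return(list(rere = NULL, pag = NULL))
  seg_for <- function(family) {
    fam <- hits[hits$family == family, , drop = FALSE]
    if (nrow(fam) == 0L) return(NULL)
    first <- fam[which.min(fam$start), , drop = FALSE]
    later <- hits$start[hits$start > first$start]
    stop_at <- if (length(later)) min(later) - 1L else nchar(text)
    trimws(substr(text, first$end + 1L, stop_at))
  }
  list(rere = seg_for("rere"), pag = seg_for("pag"))
}

marker_hits <- function(text, lexicon) {
  collect <- function(patterns, family) {
    out <- list()
    for (p in patterns) {
      m <- gregexpr(p, text, perl = TRUE)[[1]]
      if (m[1] != -1L) {
        out[[length(out) + 1L]] <- data.frame(
          family = family, start = as.integer(m),
          end = as.integer(m) + attr(m, "match.length") - 1L)
      }
    }
    out
  }
  rows <- c(collect(lexicon$section_markers$referral_reason, "rere"),
            collect(lexicon$section_markers$patient_goal, "pag"))
  if (length(rows) == 0L) {
    return(data.frame(family = character(), start = integer(), end = integer()))
  }
  do.call(rbind, rows)
}

#' Extract category flags from one referral letter
#'
#' Normalizes and segments the letter, then screens each category's code-word
#' patterns inside the matching segment only: referral-reason patterns in the
#' referral-reason segment, patient-goal patterns in the patient-goal
#' segment. Multiple categories may fire on one letter. When neither section
#' marker is found and `fallback_whole_letter` is enabled in the lexicon,
#' both families are searched over the whole letter instead.
#'
#' @param letter A [referral_letter()] or a single character string.
#' @param lexicon A `triage_lexicon`.
#' @return An object of class `extraction_flags`: named 0/1 integer vectors
#'   `referral_reason` and `patient_goal`, plus logicals `has_any_rere` and
#'   `has_any_pag`.
#' @examples
#' flags <- extract_flags("reden van verwijzing: graag revalidatie.", default_lexicon())
#' flags$referral_reason["RehabReRe"]
#' @export
extract_flags <- function(letter, lexicon = default_lexicon()) {
  text <- if (inherits(letter, "referral_letter")) letter$text else {
    stopifnot(is.character(letter), length(letter) == 1L)
    letter
  }
  norm <- normalize_text(text, lexicon)
  seg <- segment_letter(norm, lexicon)
  if (is.null(seg$rere) && is.null(seg$pag) &&
      isTRUE(lexicon$fallback_whole_letter)) {
    seg <- list(rere = norm, pag = norm)
  }
  match_family <- function(categories, segment) {
    vapply(categories, function(pats) {
      if (is.null(segment) || !nzchar(segment)) return(0L)
      as.integer(any(vapply(pats, function(p) grepl(p, segment, perl = TRUE),
                            logical(1))))
    }, integer(1))
  }
  rere <- match_family(lexicon$referral_reason, seg$rere)
  pag <- match_family(lexicon$patient_goal, seg$pag)
  structure(
    list(referral_reason = rere, patient_goal = pag,
         has_any_rere = any(rere == 1L), has_any_pag = any(pag == 1L)),
    class = "extraction_flags")
}

#' @export
print.extraction_flags <- function(x, ...) {
  on <- c(names(x$referral_reason)[x$referral_reason == 1L],
          names(x$patient_goal)[x$patient_goal == 1L])
  cat("<extraction_flags> ",
      if (length(on)) paste(on, collapse = ", ") else "(none)", "\n", sep = "")
  invisible(x)
}

#' Extract flags for a whole letter corpus, one row per patient
#'
#' Groups letters by patient, keeps each patient's initial letter (see
#' [select_initial_letter()]) and extracts its flags.
#'
#' @param letters List of [referral_letter()] objects (any number per patient).
#' @param lexicon A `triage_lexicon`.
#' @param initial_only Use only the earliest letter per patient (default);
#'   with `FALSE` a category fires if it fires in any letter of the patient.
#' @return Data frame with `patient_id`, one 0/1 column per category, and
#'   `has_any_rere` / `has_any_pag`.
#' @export
flags_table <- function(letters, lexicon = default_lexicon(),
                        initial_only = TRUE) {
  ids <- vapply(letters, function(l) l$patient_id, character(1))
  groups <- split(seq_along(letters), factor(ids, levels = unique(ids)))
  rows <- lapply(names(groups), function(pid) {
    own <- letters[groups[[pid]]]
    fl <- if (initial_only) {
      extract_flags(select_initial_letter(own), lexicon)
    } else {
      all_fl <- lapply(own, extract_flags, lexicon = lexicon)
      Reduce(function(a, b) {
        structure(list(
          referral_reason = pmax(a$referral_reason, b$referral_reason),
          patient_goal = pmax(a$patient_goal, b$patient_goal),
          has_any_rere = a$has_any_rere || b$has_any_rere,
          has_any_pag = a$has_any_pag || b$has_any_pag),
          class = "extraction_flags")
      }, all_fl)
    }
    cbind(data.frame(patient_id = pid, stringsAsFactors = FALSE),
          as.data.frame(t(c(fl$referral_reason, fl$patient_goal))),
          data.frame(has_any_rere = fl$has_any_rere,
                     has_any_pag = fl$has_any_pag))
  })
  do.call(rbind, rows)
}

#' Cross-tabulate category occurrences by triage class
#'
#' Produces the per-category occurrence counts of the extracted flags,
#' overall and split by triage class, with column sums and percentages of
#' each family's total occurrences — the layout used to describe a corpus.
#'
#' @param flags Data frame as returned by [flags_table()] (or a list of
#'   `extraction_flags`).
#' @param labels Vector of triage classes (0-3), aligned with `flags` rows.
#' @return A list of class `occurrence_report`: `table` (one row per
#'   category: family, per-class counts, `total`, `pct_of_family`) and
#'   `class_totals` (per-family column sums by class).
#' @export
corpus_occurrence_report <- function(flags, labels) {
  if (is.list(flags) && !is.data.frame(flags)) {
    flags <- do.call(rbind, lapply(flags, function(fl) {
      as.data.frame(t(c(fl$referral_reason, fl$patient_goal)))
    }))
  }
  if (nrow(flags) != length(labels)) {
    stop("`flags` has ", nrow(flags), " rows but `labels` has length ",
         length(labels), call. = FALSE)
  }
  labels <- as.integer(as.character(labels))
  lex_cols <- setdiff(names(flags),
                      c("patient_id", "has_any_rere", "has_any_pag"))
  fam <- ifelse(grepl("ReRe$", lex_cols), "referral_reason", "patient_goal")
  classes <- sort(unique(c(0:3, labels)))
  counts <- t(vapply(lex_cols, function(cn) {
    vapply(classes, function(cl) sum(flags[[cn]][labels == cl] == 1L,
                                     na.rm = TRUE), numeric(1))
  }, numeric(length(classes))))
  colnames(counts) <- paste0("class_", classes)
  total <- rowSums(counts)
  fam_tot <- tapply(total, fam, sum)
  pct <- 100 * total / ifelse(fam_tot[fam] > 0, fam_tot[fam], 1)
  tab <- data.frame(category = lex_cols, family = fam, counts,
                    total = total, pct_of_family = as.numeric(pct),
                    row.names = NULL, stringsAsFactors = FALSE)
  class_totals <- do.call(rbind, lapply(split(as.data.frame(counts), fam),
                                        colSums))
  structure(list(table = tab, class_totals = class_totals),
            class = "occurrence_report")
}

#' @export
print.occurrence_report <- function(x, ...) {
  cat("<occurrence_report>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
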