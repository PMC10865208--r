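#' Construct a referral letter record
#'
#' A referral letter is the free-text document a general practitioner or
#' second-line specialist writes when sending a patient to the spine centre.
#' One patient may have several letters; downstream processing only ever uses
#' the initial one (see [select_initial_letter()]).
#'
#' @param patient_id Non-empty character scalar identifying the patient.
#' @param letter_date Date (or anything `as.Date()` accepts) the letter was
#'   written; used to order multiple letters of one patient.
#' @param text Letter body as a single character string. May be empty, never
#'   `NULL`/`NA`.
#' @return An object of class `referral_letter`.
#' @examples
#' referral_letter("p001", "2019-03-01", "reden van verwijzing: graag revalidatie.")
#' @export
referral_letter <- function(patient_id, letter_date, text) {
  if (!is.character(patient_id) || length(patient_id) != 1L || is.na(patient_id) ||
      !nzchar(patient_id)) {
    stop("`patient_id` must be a non-empty character scalar", call. = FALSE)
  }
  if (is.null(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single character string (may be empty, not NA)",
         call. = FALSE)
  }
  letter_date <- as.Date(letter_date)
  if (is.na(letter_date)) stop("`letter_date` is not a valid date", call. = FALSE)
  structure(
    list(patient_id = patient_id, letter_date = letter_date,
         text = as.character(text)),
    class = "referral_letter"
  )
}

#' @export
print.referral_letter <- function(x, ...) {
  cat(sprintf("<referral_letter> patient %s, dated %s, %d chars\n",
              x$patient_id, format(x$letter_date), nchar(x$text)))
  invisible(x)
}

#' Select the initial referral letter of one patient
#'
#' When a patient has multiple referral letters, only the referral reasons
#' and patient goals of the initial (earliest) letter are considered. Ties on
#' the date are broken by input order (stable).
#'
#' @param letters List of [referral_letter()] objects sharing one patient id.
#' @return The earliest letter, or `NULL` for an empty list.
#' @export
select_initial_letter <- function(letters) {
  if (length(letters) == 0L) return(NULL)
  ids <- vapply(letters, function(l) l$patient_id, character(1))
  if (length(unique(ids)) != 1L) {
    stop("all letters must belong to one patient; got ids: ",
         paste(unique(ids), collapse = ", "), call. = FALSE)
  }
  dates <- as.Date(vapply(letters, function(l) as.character(l$letter_date),
                          character(1)))
  letters[[order(dates)[1L]]]  # order() is stable: first input wins ties
}

#' Read referral letters from JSON-lines or a directory of text files
#'
#' Two plain-text layouts are supported: a `.jsonl` file with one JSON object
#' per line (keys `patient_id`, `letter_date` in ISO-8601, `text`), or a
#' directory of `.txt` files named `<patient_id>_<date>.txt`.
#'
#' @param path Path to a `.jsonl`/`.json` file or a directory.
#' @return List of [referral_letter()] objects in input order.
#' @export
read_letters <- function(path) {
  if (dir.exists(path)) return(read_letters_dir(path))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln)
    referral_letter(obj$patient_id, obj$letter_date, obj$text)
  })
}

read_letters_dir <- function(path) {
  files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  lapply(files, function(f) {
    base <- sub("\\.txt$", "", basename(f))
    parts <- strsplit(base, "_", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      stop("letter file name must be <patient_id>_<date>.txt: ", basename(f),
           call. = FALSE)
    }
    date <- parts[length(parts)]
    pid <- paste(parts[-length(parts)], collapse = "_")
    referral_letter(pid, date, paste(readLines(f, warn = FALSE), collapse = "\n"))
  })
}

#' Write referral letters as JSON lines
#'
#' @param letters List of [referral_letter()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_letters <- function(letters, path) {
  lines <- vapply(letters, function(l) {
    jsonlite::toJSON(
      list(patient_id = l$patient_id,
           letter_date = format(l$letter_date, "%Y-%m-%d"),
           text = l$text),
      auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
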