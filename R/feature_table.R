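#' Patient-by-feature table with labels, split tags and condition
#'
#' The workhorse container of the pipeline: a numeric feature matrix (stored
#' as a data frame, `NA` = missing), aligned triage labels (0 = other /
#' minimal intervention, 1 = rehabilitation, 2 = anesthesiology,
#' 3 = neurosurgery), per-row split tags (`train` / `eval`), the condition
#' (`ED` = questionnaire + letter flags, `BD` = questionnaire only) and a
#' per-row synthetic marker (set by [smote_balance()]).
#'
#' @param features Data frame of numeric feature columns with unique names.
#' @param labels Integer vector of triage classes in 0-3, one per row.
#' @param patient_id Optional character vector of row identifiers.
#' @param split Optional character vector of `"train"` / `"eval"` tags.
#' @param condition `"ED"` or `"BD"`.
#' @param synthetic Optional logical vector marking oversampled rows.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, labels, patient_id = NULL, split = NULL,
                          condition = c("ED", "BD"), synthetic = NULL) {
  condition <- match.arg(condition)
  features <- as.data.frame(features)
  if (anyDuplicated(names(features))) {
    stop("duplicate feature names: ",
         paste(unique(names(features)[duplicated(names(features))]),
               collapse = ", "), call. = FALSE)
  }
  if (!all(vapply(features, is.numeric, logical(1)))) {
    stop("all feature columns must be numeric", call. = FALSE)
  }
  n <- nrow(features)
  labels <- as.integer(as.character(labels))
  if (length(labels) != n) stop("labels must align with rows", call. = FALSE)
  if (any(is.na(labels)) || !all(labels %in% 0:3)) {
    stop("labels must all be in {0, 1, 2, 3}", call. = FALSE)
  }
  if (is.null(patient_id)) patient_id <- sprintf("row%05d", seq_len(n))
  if (length(patient_id) != n) stop("patient_id must align with rows", call. = FALSE)
  if (!is.null(split)) {
    split <- as.character(split)
    if (length(split) != n || !all(split %in% c("train", "eval"))) {
      stop("split must be 'train'/'eval' per row", call. = FALSE)
    }
  }
  if (is.null(synthetic)) synthetic <- rep(FALSE, n)
  structure(
    list(x = features, labels = labels, patient_id = as.character(patient_id),
         split = split, condition = condition, synthetic = synthetic),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table [%s]> %d patients x %d features\n",
              x$condition, nrow(x$x), ncol(x$x)))
  cat("  classes: ",
      paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$split)) {
    cat("  split:   ",
        paste(sprintf("%s=%d", names(table(x$split)), table(x$split)),
              collapse = ", "), "\n", sep = "")
  }
  if (any(x$synthetic)) {
    cat("  synthetic rows: ", sum(x$synthetic), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' Feature names of a feature table or ranking
#' @param x A `feature_table`.
#' @return Character vector of feature names.
#' @export
feature_names <- function(x) names(x$x)

#' Subset the rows of a feature table
#' @param ft A `feature_table`.
#' @param i Row index (logical or integer).
#' @return A `feature_table` with the selected rows.
#' @export
ft_rows <- function(ft, i) {
  feature_table(ft$x[i, , drop = FALSE], ft$labels[i], ft$patient_id[i],
                if (!is.null(ft$split)) ft$split[i], ft$condition,
                ft$synthetic[i])
}

#' Convert a feature table to a plain data frame
#'
#' Adds `patient_id`, `label`, `split` and `synthetic` columns in front of
#' the feature columns; the format written by [run_pipeline()] CSV outputs.
#'
#' @param x A `feature_table`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.feature_table <- function(x, ...) {
  cbind(data.frame(patient_id = x$patient_id, label = x$labels,
                   split = if (is.null(x$split)) NA_character_ else x$split,
                   synthetic = x$synthetic, stringsAsFactors = FALSE),
        x$x)
}

#' The nine letter-flag column names
#' @return Character vector: 5 ReRe then 4 PaG category names.
#' @export
flag_names <- function() {
  c("SecondOpinionReRe", "AnesthesiologyReRe", "RehabReRe", "AdviceReRe",
    "OptionsReRe", "MoreCausePaG", "PainRedPaG", "BetterFuncPaG", "AdvicePaG")
}

#' Default letter flags merged into the extended data set
#'
#' Four of the five referral-reason categories plus all four patient-goal
#' categories. `AdviceReRe` is dropped by default because its code word
#' duplicates `AdvicePaG`; the choice is configurable wherever `ed_flags`
#' is accepted.
#'
#' @return Character vector of eight flag names.
#' @export
default_ed_flags <- function() setdiff(flag_names(), "AdviceReRe")

#' Join questionnaire features with per-patient letter flags
#'
#' Left-joins the extraction flags onto the questionnaire table by
#' `patient_id`, preserving questionnaire row order. Patients absent from
#' `flags` are marked as having no letter; their flag columns are `NA`.
#'
#' @param features Data frame with `patient_id`, `label` and numeric
#'   questionnaire columns (empty cell = `NA` = missing).
#' @param flags Data frame from [flags_table()] (may cover a subset of
#'   patients).
#' @return Data frame of patient records: questionnaire columns plus
#'   `has_letter`, the 9 flag columns and `has_any_rere` / `has_any_pag`.
#' @export
merge_letter_flags <- function(features, flags) {
  stopifnot(is.data.frame(features), "patient_id" %in% names(features),
            "label" %in% names(features))
  if (is.null(flags) || nrow(flags) == 0L) {
    flags <- data.frame(patient_id = character())
    for (fn in flag_names()) flags[[fn]] <- integer()
    flags$has_any_rere <- logical(); flags$has_any_pag <- logical()
  }
  idx <- match(features$patient_id, flags$patient_id)
  out <- features
  out$has_letter <- !is.na(idx)
  for (cn in setdiff(names(flags), "patient_id")) {
    out[[cn]] <- flags[[cn]][idx]
  }
  out
}

#' Apply the cohort inclusion rule
#'
#' A patient enters the analysis only with a referral letter whose initial
#' document yielded at least one referral-reason or patient-goal flag.
#' Order is preserved and the operation is idempotent.
#'
#' @param records Data frame from [merge_letter_flags()].
#' @return The retained records.
#' @export
apply_inclusion <- function(records) {
  stopifnot(all(c("has_letter", "has_any_rere", "has_any_pag") %in%
                  names(records)))
  keep <- records$has_letter &
    (records$has_any_rere %in% TRUE | records$has_any_pag %in% TRUE)
  records[which(keep), , drop = FALSE]
}

#' Build the extended (ED) and basic (BD) data sets
#'
#' ED = questionnaire columns plus the selected letter-flag columns (0/1,
#' never missing for included patients); BD = questionnaire columns only.
#' Both tables share identical row order, labels and patient ids, so a split
#' computed for one applies verbatim to the other.
#'
#' @param records Included records (see [apply_inclusion()]).
#' @param ed_flags Flag columns merged into the ED; subset of [flag_names()].
#' @return List with elements `ED` and `BD`, both [feature_table()]s.
#' @export
build_datasets <- function(records, ed_flags = default_ed_flags()) {
  unknown <- setdiff(ed_flags, flag_names())
  if (length(unknown)) {
    stop("unknown flag name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  meta <- c("patient_id", "label", "has_letter", "has_any_rere",
            "has_any_pag", flag_names())
  qcols <- setdiff(names(records), meta)
  ed_x <- records[, c(qcols, ed_flags), drop = FALSE]
  if (length(ed_flags)) {
    for (fn in ed_flags) {
      if (anyNA(ed_x[[fn]])) {
        stop("flag column ", fn, " has missing values for included records",
             call. = FALSE)
      }
      ed_x[[fn]] <- as.numeric(ed_x[[fn]])
    }
  }
  list(
    ED = feature_table(ed_x, records$label, records$patient_id,
                       condition = "ED"),
    BD = feature_table(records[, qcols, drop = FALSE], records$label,
                       records$patient_id, condition = "BD"))
}

#' Draw the class-balanced evaluation split
#'
#' Tags exactly `per_class` rows of every triage class as `eval`, drawn
#' uniformly without replacement under the seed; all remaining rows become
#' `train`. Because the tags depend only on the labels, the row order and
#' the seed, calling this on the ED and the BD of one cohort yields
#' identical splits.
#'
#' @param ft A `feature_table`.
#' @param per_class Evaluation rows per class (default 50; 0 = everything
#'   stays in training).
#' @param seed Integer seed.
#' @return The `feature_table` with split tags assigned.
#' @export
split_eval <- function(ft, per_class = 50, seed = 1L) {
  stopifnot(inherits(ft, "feature_table"))
  counts <- table(factor(ft$labels, levels = sort(unique(ft$labels))))
  short <- counts[counts < per_class]
  if (length(short)) {
    stop("class ", paste(names(short), collapse = ", "),
         " has fewer rows than per_class = ", per_class, call. = FALSE)
  }
  split <- rep("train", nrow(ft$x))
  if (per_class > 0) {
    withr::with_seed(as.integer(seed), {
      for (cl in sort(unique(ft$labels))) {
        rows <- which(ft$labels == cl)
        split[sample(rows, per_class)] <- "eval"
      }
    })
  }
  ft$split <- split
  ft
}

#' Z-score-normalize each feature within each split
#'
#' Every feature column is centred and scaled inside each split tag
#' separately (the evaluation rows never influence the training statistics).
#' Missing entries stay missing; zero-variance columns map to 0; binary flag
#' columns are treated like any other numeric column.
#'
#' @param ft A `feature_table` with split tags.
#' @param sd_convention `"sample"` (divide by n-1, the default: a 3-point
#'   column 1,2,3 maps to -1,0,1) or `"population"` (divide by n).
#' @param eval_mode `"per_split"` (default: the evaluation split uses its own
#'   mean/sd) or `"train_params"` (evaluation rows reuse the training split's
#'   statistics, the leak-free deployment convention).
#' @return The normalized `feature_table`.
#' @export
zscore_by_split <- function(ft, sd_convention = c("sample", "population"),
                            eval_mode = c("per_split", "train_params")) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.null(ft$split)) stop("assign split tags first (split_eval)", call. = FALSE)
  sd_convention <- match.arg(sd_convention)
  eval_mode <- match.arg(eval_mode)
  col_stats <- function(v) {
    obs <- v[!is.na(v)]
    m <- if (length(obs)) mean(obs) else 0
    s <- if (length(obs) > 1) {
      if (sd_convention == "sample") stats::sd(obs)
      else sqrt(mean((obs - m)^2))
    } else 0
    c(m = m, s = s)
  }
  train_rows <- ft$split == "train"
  for (cn in names(ft$x)) {
    st_train <- col_stats(ft$x[[cn]][train_rows])
    for (tag in unique(ft$split)) {
      rows <- ft$split == tag
      st <- if (tag != "train" && eval_mode == "train_params") st_train
            else col_stats(ft$x[[cn]][rows])
      v <- ft$x[[cn]][rows]
      ft$x[[cn]][rows] <- if (st["s"] > 0) (v - st["m"]) / st["s"] else
        ifelse(is.na(v), NA_real_, 0)
    }
  }
  ft
}

#' Fill missing feature values with the per-split observed column mean
#'
#' Applied after [zscore_by_split()] the fill value is (numerically) the
#' split mean, i.e. approximately zero, which keeps the fill class-agnostic.
#' This is the pipeline's default preparation for stages that need complete
#' inputs (SMOTE, kNN, SVM, MLP); a strict complete-case mode is available
#' in [run_pipeline()].
#'
#' @param ft A `feature_table` (split tags optional; without tags the whole
#'   table is one group).
#' @return The `feature_table` with no missing values.
#' @export
fill_missing <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  groups <- if (is.null(ft$split)) rep("all", nrow(ft$x)) else ft$split
  for (cn in names(ft$x)) {
    for (tag in unique(groups)) {
      rows <- groups == tag
      v <- ft$x[[cn]][rows]
      if (anyNA(v)) {
        m <- mean(v, na.rm = TRUE)
        if (is.nan(m)) m <- 0
        v[is.na(v)] <- m
        ft$x[[cn]][rows] <- v
      }
    }
  }
  ft
}

#' Drop rows containing missing feature values
#'
#' @param ft A `feature_table`.
#' @param quiet Suppress the message stating how many rows were dropped.
#' @return The `feature_table` restricted to complete rows.
#' @export
complete_cases <- function(ft, quiet = FALSE) {
  keep <- stats::complete.cases(ft$x)
  if (!all(keep) && !quiet) {
    message("dropping ", sum(!keep), " of ", length(keep),
            " rows with missing feature values")
  }
  ft_rows(ft, keep)
}
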