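#' Derive a stage seed from the master seed
#'
#' Deterministically hashes `(master, stage)` into a 31-bit integer so every
#' pipeline stage gets its own independent seed from a single knob.
#'
#' @param master Integer master seed.
#' @param stage Character stage name.
#' @return Integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(master)) %% 1048573) * 2039 + h * 7919) %%
    2147483629L
}

#' Run the full enrichment pipeline on one cohort
#'
#' Executes every stage in order for the requested conditions on one shared
#' split: extract flags from the initial referral letters, apply the
#' inclusion rule, build the extended (ED) and basic (BD) data sets, draw
#' the class-balanced evaluation split, z-score per split, rank features
#' with ReliefF on the pre-balance training rows, restrict both splits to
#' the selected features, handle missing values, SMOTE-balance the training
#' rows, train each model family `n_runs` times, score the evaluation split
#' and compare conditions.
#'
#' A run with `conditions = "BD"` only skips the extraction and inclusion
#' stages entirely (no letters required); the manifest records the skip.
#'
#' @param cohort A `synthetic_cohort`, or a list with elements `patients`
#'   (data frame with `patient_id`, `label`, questionnaire columns) and
#'   `letters` (list of [referral_letter()]).
#' @param lexicon A `triage_lexicon`.
#' @param conditions Character subset of `c("ED", "BD")`.
#' @param per_class Evaluation rows per class (default 50).
#' @param ed_flags Letter flags merged into the ED.
#' @param smote_k SMOTE neighbours (default 5).
#' @param relieff_k ReliefF neighbours per class (default 50).
#' @param tau ReliefF selection threshold (default 0.07).
#' @param selection `"threshold"` (select by `tau`) or `"top_n"` (take the
#'   `n_top` best-ranked features per condition).
#' @param n_top Named vector `c(ED = 30, BD = 29)` used when
#'   `selection = "top_n"` — the selected-feature counts of the original
#'   analysis.
#' @param models Model families to train.
#' @param n_runs Training repetitions per model (default 4); scores are
#'   averaged over runs, only the training seed varies.
#' @param missing_handling `"meanfill"` (default; per-split mean fill after
#'   z-scoring, i.e. approximately zero) or `"complete"` (drop incomplete
#'   rows).
#' @param sd_convention,eval_zscore Passed to [zscore_by_split()].
#' @param seed Master seed; per-stage seeds derive from it.
#' @param out_dir Optional directory; when given, the assembled tables,
#'   rankings, scores and comparison are written as CSV and the manifest as
#'   JSON.
#' @param ... Passed to [train_triage_model()] (e.g. `mlp_epochs`).
#' @return List of class `triage_run`: `reports` (per condition, per model
#'   [score_report()]), `comparison` (when both conditions ran), `rankings`,
#'   `tables` (the normalized, selected feature tables) and `manifest`
#'   (config, per-stage seeds and row counts).
#' @export
run_pipeline <- function(cohort, lexicon = default_lexicon(),
                         conditions = c("ED", "BD"), per_class = 50,
                         ed_flags = default_ed_flags(), smote_k = 5,
                         relieff_k = 50, tau = 0.07,
                         selection = c("threshold", "top_n"),
                         n_top = c(ED = 30, BD = 29),
                         models = c("knn", "svm", "mlp"), n_runs = 4,
                         missing_handling = c("meanfill", "complete"),
                         sd_convention = "sample", eval_zscore = "per_split",
                         seed = 1L, out_dir = NULL, ...) {
  selection <- match.arg(selection)
  missing_handling <- match.arg(missing_handling)
  conditions <- match.arg(conditions, c("ED", "BD"), several.ok = TRUE)
  stopifnot(is.list(cohort), !is.null(cohort$patients))
  patients <- cohort$patients

  manifest <- list(
    config = list(conditions = conditions, per_class = per_class,
                  ed_flags = ed_flags, smote_k = smote_k,
                  relieff_k = relieff_k, tau = tau, selection = selection,
                  n_top = as.list(n_top), models = models, n_runs = n_runs,
                  missing_handling = missing_handling,
                  sd_convention = sd_convention, eval_zscore = eval_zscore,
                  seed = as.integer(seed)),
    seeds = list(split = derive_seed(seed, "split"),
                 smote = derive_seed(seed, "smote")),
    rows = list(n_input = nrow(patients)),
    stages = character(0))

  need_letters <- "ED" %in% conditions
  if (need_letters) {
    if (is.null(cohort$letters) || length(cohort$letters) == 0L) {
      stop("stage extract: cohort has no letters but condition ED requested",
           call. = FALSE)
    }
    flags <- flags_table(cohort$letters, lexicon)
    records <- apply_inclusion(merge_letter_flags(patients, flags))
    manifest$stages <- c(manifest$stages, "extract", "inclusion")
  } else {
    flags <- NULL
    records <- patients
    records$has_letter <- TRUE
    for (fn in flag_names()) records[[fn]] <- 0L
    records$has_any_rere <- FALSE; records$has_any_pag <- FALSE
    manifest$stages <- c(manifest$stages,
                         "extract:skipped", "inclusion:skipped")
  }
  manifest$rows$n_included <- nrow(records)
  if (nrow(records) == 0L) stop("stage inclusion: no records retained",
                                call. = FALSE)

  tables <- build_datasets(records, ed_flags)
  reports <- list(); rankings <- list(); kept_tables <- list()
  for (cond in conditions) {
    ft <- tables[[cond]]
    ft <- split_eval(ft, per_class = per_class, seed = manifest$seeds$split)
    ft <- zscore_by_split(ft, sd_convention = sd_convention,
                          eval_mode = eval_zscore)
    train_ft <- ft_rows(ft, ft$split == "train")
    ranking <- relieff_rank(train_ft, k = relieff_k, tau = tau)
    ft_sel <- if (selection == "top_n") {
      select_features(ranking, ft, n_top = unname(n_top[cond]))
    } else {
      select_features(ranking, ft)
    }
    ft_sel <- if (missing_handling == "meanfill") fill_missing(ft_sel) else
      complete_cases(ft_sel, quiet = TRUE)
    train_sel <- ft_rows(ft_sel, ft_sel$split == "train")
    eval_sel <- ft_rows(ft_sel, ft_sel$split == "eval")
    train_bal <- smote_balance(train_sel, k = smote_k,
                               seed = manifest$seeds$smote)
    manifest$rows[[paste0("n_train_", cond)]] <- nrow(train_sel$x)
    manifest$rows[[paste0("n_eval_", cond)]] <- nrow(eval_sel$x)
    manifest$rows[[paste0("n_train_balanced_", cond)]] <- nrow(train_bal$x)
    manifest[[paste0("eval_ids_", cond)]] <- eval_sel$patient_id
    rankings[[cond]] <- ranking
    kept_tables[[cond]] <- ft_sel
    manifest$stages <- c(manifest$stages,
                         paste0(c("split:", "zscore:", "select:", "balance:"),
                                cond))

    cond_reports <- list()
    for (mod in models) {
      run_f1s <- numeric(n_runs); confusions <- list(); freps <- list()
      for (r in seq_len(n_runs)) {
        mseed <- derive_seed(seed, paste0("train-", mod, "-run", r))
        fit <- train_triage_model(train_bal, model = mod, seed = mseed, ...)
        pred <- predict(fit, eval_sel)
        cm <- confusion(eval_sel$labels, pred)
        fr <- f1_from_confusion(cm)
        run_f1s[r] <- fr$macro_f1
        confusions[[r]] <- cm
        freps[[r]] <- fr
      }
      cond_reports[[mod]] <- score_report(mod, cond, run_f1s, confusions,
                                          freps)
      manifest$stages <- c(manifest$stages,
                           paste0("train:", cond, ":", mod))
    }
    reports[[cond]] <- cond_reports
  }

  comparison <- if (all(c("ED", "BD") %in% conditions)) {
    compare_conditions(unname(reports$ED), unname(reports$BD))
  } else NULL

  out <- structure(
    list(reports = reports, comparison = comparison, rankings = rankings,
         tables = kept_tables, manifest = manifest),
    class = "triage_run")
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

#' @export
print.triage_run <- function(x, ...) {
  cat("<triage_run>\n")
  for (cond in names(x$reports)) {
    for (mod in names(x$reports[[cond]])) {
      r <- x$reports[[cond]][[mod]]
      cat(sprintf("  %s %-4s mean macro F1 = %.4f (%d run%s)\n", cond, mod,
                  r$mean_f1, length(r$run_f1s),
                  if (length(r$run_f1s) > 1) "s" else ""))
    }
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  max ED-BD difference: %.1f percentage points\n",
                attr(x$comparison, "max_diff_pp")))
  }
  invisible(x)
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in names(run$tables)) {
    utils::write.csv(as.data.frame(run$tables[[cond]]),
                     file.path(out_dir, paste0(tolower(cond), ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(run$rankings[[cond]]),
                     file.path(out_dir, paste0("ranking_",
                                               tolower(cond), ".csv")),
                     row.names = FALSE)
  }
  scores <- do.call(rbind, lapply(names(run$reports), function(cond) {
    do.call(rbind, lapply(run$reports[[cond]], function(r) {
      data.frame(model = r$model, condition = cond,
                 run = seq_along(r$run_f1s), macro_f1 = r$run_f1s,
                 mean_f1 = r$mean_f1)
    }))
  }))
  utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  if (!is.null(run$comparison)) {
    utils::write.csv(as.data.frame(run$comparison),
                     file.path(out_dir, "comparison.csv"), row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Replicated ED-versus-BD enrichment experiment on synthetic cohorts
#'
#' Generates `n_reps` independent synthetic cohorts at a chosen letter-signal
#' strength and questionnaire effect size, runs the full pipeline on each
#' (rank-based top-30/top-29 feature selection, one training run per model,
#' with ED and BD sharing the split and the training seeds so the
#' comparison is paired), and collects the per-replicate macro F1 of every
#' model family under both conditions.
#'
#' @param n_reps Number of replicates (default 20).
#' @param n_patients Cohort size per replicate (default 2000).
#' @param strength Letter-signal strength in \[0, 1\] passed to
#'   [inject_letter_signal()].
#' @param effect_size Questionnaire effect size in SD units (default 0.5).
#' @param models Model families.
#' @param per_class Evaluation rows per class.
#' @param n_runs Training runs per model per replicate (default 1; the
#'   replicates provide the averaging).
#' @param seed Master seed; replicate seeds derive from it.
#' @param ... Passed on to [run_pipeline()].
#' @return Data frame with one row per replicate and model: `rep`, `model`,
#'   `f1_ed`, `f1_bd`, `diff_pp`.
#' @export
run_enrichment_experiment <- function(n_reps = 20, n_patients = 2000,
                                      strength = 1, effect_size = 0.5,
                                      models = c("knn", "svm", "mlp"),
                                      per_class = 50, n_runs = 1,
                                      seed = 1L, ...) {
  rows <- list()
  for (rep_i in seq_len(n_reps)) {
    spec <- cohort_spec(n_patients = n_patients, effect_size = effect_size,
                        seed = derive_seed(seed, paste0("cohort", rep_i)))
    spec <- inject_letter_signal(spec, strength)
    cohort <- generate_cohort(spec)
    run <- run_pipeline(cohort, per_class = per_class, models = models,
                        n_runs = n_runs, selection = "top_n",
                        seed = derive_seed(seed, paste0("pipeline", rep_i)),
                        ...)
    cmp <- as.data.frame(run$comparison)
    cmp$rep <- rep_i
    rows[[rep_i]] <- cmp[, c("rep", "model", "f1_ed", "f1_bd", "diff_pp")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
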