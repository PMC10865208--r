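# lbptriage

Referral-letter enrichment for machine-learning triage of low back pain.

Patients with chronic low back pain referred to a multidisciplinary spine
centre are triaged to one of four treatment paths — rehabilitation (1),
anesthesiologic pain therapy (2), neurosurgery (3), or a minimal
information-based intervention (0). Decision-support classifiers trained on
self-report questionnaires alone perform modestly. This package implements
a complete, seeded pipeline that mines the free-text **referral letters**
for two kinds of qualitative information — the clinician's *referral
reason* (ReRe) and the *patient goal* (PaG), each coded into lexicon
categories — and measures how much those extracted flags improve
four-class triage classification.

The pipeline, every stage a tested exported function:

1. **Lexicon/regex extraction** — normalize Dutch letter text (case,
   diacritics, unification rewrites), segment it at section markers
   (`reden van verwijzing …`, `hulpvraag …`), and screen each category's
   code words inside its segment (`extract_flags`, `flags_table`).
2. **Cohort assembly** — inclusion rule (letter + at least one flag),
   extended data set **ED** (questionnaire + flags) vs basic data set
   **BD** (questionnaire only), a class-balanced 50-per-class evaluation
   split, per-split z-scoring (`apply_inclusion`, `build_datasets`,
   `split_eval`, `zscore_by_split`).
3. **SMOTE** — from-scratch minority oversampling of the training split to
   the majority count; each synthetic row is `x + u·(x_nn − x)` with
   `x_nn` one of the seed row's k = 5 nearest same-class neighbours
   (`smote_balance`).
4. **ReliefF** — deterministic multiclass feature ranking (`m = n`,
   `k = 50` neighbours per class, min-max-normalized diffs, prior-weighted
   miss classes; compiled kernel, brute-force-verified) with threshold or
   rank-based selection (`relieff_rank`, `select_features`). Feature `f`
   accumulates `W_f += (Σ_c p_c · d̄_miss,c(f) − d̄_hit(f)) / m`.
5. **Classification** — kNN, RBF-SVM, and an in-package MLP (one hidden
   ReLU layer, softmax cross-entropy, Adam, early stopping) behind one
   interface (`train_triage_model`, `predict`).
6. **Evaluation** — confusion matrices and per-class precision/recall/F1
   (`P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`), macro-averaged
   and run-averaged; ED-vs-BD differences in percentage points
   (`confusion`, `f1_from_confusion`, `compare_conditions`).
7. **Synthetic cohort** — because the clinical records are not public, a
   seeded generator emulates the study's statistical structure:
   class-imbalanced labels, class-shifted questionnaire features with
   ordinal binning and missingness, and section-structured Dutch letters
   with class-conditionally planted code words plus recorded ground truth
   (`cohort_spec`, `inject_letter_signal`, `generate_cohort`).

`run_pipeline()` orchestrates all stages on one shared split;
`run_enrichment_experiment()` replicates the ED-vs-BD comparison over many
seeded cohorts.

## Worked example

```r
library(lbptriage)

spec   <- inject_letter_signal(
  cohort_spec(n_patients = 1000, effect_size = 0.8, seed = 2024), strength = 1)
cohort <- generate_cohort(spec)
run    <- run_pipeline(cohort, per_class = 30, n_runs = 2,
                       selection = "top_n", seed = 11)
run$comparison
#> <condition_comparison> ED vs BD mean macro F1
#>  model  f1_ed  f1_bd diff_pp
#>    knn 0.5219 0.3558  16.615
#>    svm 0.4742 0.4019   7.231
#>    mlp 0.5222 0.4297   9.251
#> max difference: 16.6 percentage points

head(as.data.frame(run$rankings$ED), 3)
#>              feature     weight       score rank selected
#> 1          RehabReRe 0.18481223 -0.18481223    1     TRUE
#> 2 AnesthesiologyReRe 0.13036218 -0.13036218    2     TRUE
#> 3                q09 0.04313597 -0.04313597    3    FALSE
```

Read: on a synthetic cohort whose letters carry class signal, every model
family scores a higher run-averaged macro F1 on the extended data set than
on the questionnaire-only basic data set (here up to 16.6 percentage
points), and ReliefF ranks the two class-informative referral-reason flags
— rehabilitation and anesthesiology — above every questionnaire feature.
Per-run 4×4 confusion matrices live in `run$reports[[condition]][[model]]`.

The methods vignette (`vignettes/referral-triage-enrichment.Rmd`) documents
the model, every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, and the package's design
decisions.

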