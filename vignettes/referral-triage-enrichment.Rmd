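---
title: "Enriching questionnaire-based triage with referral-letter text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enriching questionnaire-based triage with referral-letter text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients with chronic low back pain referred to a multidisciplinary spine
centre must be triaged to one of four treatment paths: rehabilitation
(class 1), anesthesiologic pain therapy (class 2), neurosurgery (class 3),
or a minimal intervention based on information and advice (class 0).
Decision-support models built on self-report questionnaires alone achieve
modest accuracy. Referral letters, stored as free text in the electronic
health record, carry two additional kinds of information: the *referral
reason* (what the referring clinician asks for) and the *patient goal*
(what the patient asks for). `lbptriage` implements, as composable tested
functions, a pipeline that (a) extracts these as binary category flags with
a lexicon/regex recognizer and (b) quantifies how much the flags improve
four-class triage classification.

Two feature tables are compared throughout: the **extended data set (ED)**
— questionnaire items plus the letter flags — and the **basic data set
(BD)** — the identical questionnaire items only. The headline quantity is
the difference in run-averaged macro F1 between ED and BD, in percentage
points, per classifier family.

## Letter mining

Extraction is deliberately simple and auditable — a lexicon of Dutch code
words matched with regular expressions, no statistical language model:

1. **Normalization.** Lower-casing, diacritic transliteration to ASCII,
   ordered unification rewrites (e.g. `tweede mening` → `2e mening`),
   whitespace collapse. The operation is idempotent, and rewrites run
   *before* segmentation because section markers themselves may have
   variant spellings.
2. **Segmentation.** Section markers (configurable; defaults include
   `reden van verwijzing` and `hulpvraag`) open the referral-reason and
   patient-goal segments; a segment ends at the next marker of either
   family or the end of text, so segments never overlap. Absence of a
   marker is a valid outcome — letters carrying only a patient-goal section
   are retained.
3. **Matching.** Each of the 5 referral-reason and 4 patient-goal
   categories fires iff at least one of its patterns occurs inside the
   matching segment. Matching is substring-based on normalized text, so
   `pijn` fires inside compounds such as `pijnklachten` — a deliberate
   choice for Dutch compounding. Multiple categories per letter are
   supported.

Two design points were genuinely open and are resolved as follows:

* **Whole-letter fallback.** Real letters are often unstructured. When
  *neither* family marker matches, both families are searched over the
  whole letter (configurable). The fallback is intentionally not
  per-family: if the referral-reason family fell back while a patient-goal
  section exists, referral-reason patterns would fire inside the
  patient-goal segment and violate segment containment.
* **Which referral-reason flag enters the ED.** Four of the five
  referral-reason categories are merged into the ED by default.
  `AdviceReRe` is the one dropped, because its code word duplicates the
  `AdvicePaG` patient-goal category; the choice is a configuration
  (`ed_flags`), not a constant.

When a patient has several letters, only the initial one (earliest date,
stable tie-break by input order) defines the flags. The shipped lexicon
encodes the published category exemplars plus documented extensions and
should be treated as a reconstruction; deployments are expected to edit it.

## Cohort assembly

Patients enter the analysis only if they have a referral letter whose
initial document produced at least one flag. The evaluation split draws
exactly 50 original samples per class (uniformly, seeded); everything else
is training data. Because the split depends only on labels, row order and
seed, ED and BD receive identical splits. Evaluation rows are always
original samples — oversampling happens strictly after, and only in, the
training split.

**Z-scoring.** Every feature is centred and scaled within each split
separately. The default divides by `n − 1` (so a three-point column
`1, 2, 3` maps to `−1, 0, 1`); a population (`n`) convention is available.
Two evaluation-split conventions are implemented: `per_split` (the
evaluation split uses its own statistics — the default, the procedure as
literally stated) and `train_params` (evaluation rows reuse training
statistics — the deployment-faithful convention). Binary flags
are normalized like any other column.

**Missing data.** Questionnaire missingness is preserved through assembly
— no imputation at the data level. Downstream stages need complete inputs,
and two modes exist: the pipeline default fills each missing cell with the
per-split observed column mean *after* z-scoring (numerically ≈ 0, a
class-agnostic neutral value); a strict complete-case mode drops incomplete
rows instead. The fill is the default because at realistic per-cell
missingness (5%) a complete-case rule over ~30 selected features retains
only about a quarter of the rows, which destabilizes every downstream
estimate. ReliefF itself needs neither: a diff involving a missing entry
contributes the feature's mean observed diff, so ranking uses all rows.

## SMOTE balancing

Class balancing is implemented from scratch (`smote_balance`): every class
is raised to the pre-balance majority count; each synthetic row is
`x + u (x_nn − x)` with `x` a uniformly drawn minority row, `x_nn` one of
its `k = 5` nearest same-class neighbours (Euclidean), and
`u ~ Uniform(0, 1)`. Originals pass through verbatim and synthetic rows are
tagged. `k` clamps to `class size − 1` with a warning on tiny classes.
Flags are interpolated like any numeric column (fractional values may
appear); the test suite verifies every synthetic point against an
exhaustive convex-segment oracle. Balancing runs after normalization, on
the training split only.

## ReliefF feature selection

Feature ranking uses multiclass ReliefF with `m = n` (every pre-balance
training row visited once — fully deterministic) and `k = 50` neighbours
per class. For each visited row, the `k` nearest same-class hits and `k`
nearest misses per other class are found under a Manhattan distance on
min-max-scaled features; feature `f`'s weight accumulates
`(Σ_c p_c · meanDiff_miss,c(f) − meanDiff_hit(f)) / m`, with miss classes
weighted by their prior `P(c)/(1 − P(class(i)))` by default (a `uniform`
mode is provided). Min-max scaling of diffs bounds `|W| ≤ 1` and makes the
weight invariant to positive rescaling of a feature; constant features
score exactly 0; distance ties break by row index so results are
permutation-invariant. The hot loop is compiled (Rcpp); an independent
plain-R brute-force oracle in the test suite checks it to `1e−9`.

Two statistics are reported: `weight` (W, larger = more relevant) and
`score` (S), the companion sum with the opposite orientation. The study's
feature ranking is descending in a quantity behaving like W, so W drives
ranking and selection and S is reported for completeness.

Selection is by threshold `W ≥ τ` with **τ defaulting to 0.07**: the study's
selected-feature weights span 0.070–0.128, so the nominally stated 0.7
would select nothing and is treated as a misprint; τ is fully
configurable. For the synthetic-cohort experiments the
pipeline instead uses rank-based selection of the top 30 (ED) / 29 (BD)
features — the selected-feature counts of the original analysis — because
a τ threshold is a calibration of one particular data set and need not
transfer to a synthetic cohort.

## Classifiers

Three families share one interface (`train_triage_model` / `predict`):

* **kNN** (`class::knn`, k = 5) and **SVM** (`e1071::svm`, RBF kernel,
  cost 1): the study names no hyperparameters for these, so standard
  defaults are used and exposed.
* **MLP**: implemented in the package because the specified combination —
  one hidden ReLU layer, softmax cross-entropy loss, Adam optimisation —
  is not offered by any installed R package. Defaults: one hidden layer of
  64 units, He initialisation, minibatch 32, learning rate 1e−3, at most
  60 epochs, early stopping (patience 8) on one fold of a 4-fold partition
  of the training rows, restoring the best-validation weights. The hidden
  width and epoch budget are artifact choices for the small-data regime,
  not published values.

The study's 4-fold cross-validation is interpreted as internal model
selection/diagnostics on the training split (the fixed 50-per-class
evaluation set stays untouched); `cv_fold_scores()` provides the
alternative reporting mode that scores by CV folds instead.

## Evaluation

`confusion()` builds annotated-row × predicted-column count matrices;
`f1_from_confusion()` derives one-vs-rest precision, recall and F1 per
class with the 0-on-zero-denominator convention, and averages. "The F1" of
a 4-class model is the **unweighted macro mean** — the natural reading
given the deliberately balanced evaluation set — with micro and
support-weighted means reported alongside. Scores are averaged over
`n_runs = 4` training runs by default (only the training seed varies).
ED-vs-BD differences are reported in percentage points of F1 × 100,
matching the convention in which an 0.535 vs 0.355 pair is "an 18%
increase".

## The synthetic cohort

No public version of the clinical data exists, so `generate_cohort()`
produces a fully synthetic stand-in with the statistical structure the
analysis assumes — and nothing more:

* **Labels** drawn from the study's included-cohort class proportions
  (301 : 571 : 228 : 109 over classes 0–3).
* **Questionnaire block**: 40 features, 10 informative. Informative
  feature *j* is a unit-variance draw mean-shifted by `effect_size` for
  patients of class `(j − 1) mod 4`, so every class owns 2–3 marker
  features. Odd-numbered columns are discretised to 1–5 ordinals using
  fixed quantile cut points shared across classes (so class signal
  survives binning); cells go missing independently at rate 0.05.
* **Letters**: 83.4% of patients have one (the study's letter coverage);
  83.7% of those get a later redundant second letter, exercising
  initial-letter selection. Each letter is templated Dutch text — filler
  intro, then a referral-reason and/or patient-goal section present only
  when a category of that family was planted, with the category code words
  embedded verbatim. Per-category planting probabilities are
  class-conditional, calibrated to the published category-by-class
  training proportions (so e.g. the anesthesiology referral reason is
  planted for ~45% of anesthesiology-class letters but ~2–10% elsewhere).
  The filler vocabulary is screened to contain no code word, marker, or
  substring of either, so extraction on clean templates is exact — planted
  truth is recorded per patient and extraction can be scored at 100%
  sensitivity/specificity.
* **Signal dial**: `inject_letter_signal(spec, strength)` interpolates the
  planting probabilities elementwise between class-independent marginals
  (`strength = 0`, flags carry no class information) and the fully
  class-conditional pattern (`strength = 1`).

What the generator does **not** emulate: real Dutch clinical prose,
questionnaire covariance structure, informative missingness, spelling
noise, or scanned/OCR artefacts. Consequently a passing extraction
round-trip certifies the engine's logic, not its recall on messy
real-world letters; the published extraction coverage (90.2% of letters)
cannot be validated synthetically.

## The replicated enrichment experiment

`run_enrichment_experiment()` is the package's own version of the headline
analysis: 20 independent synthetic cohorts of 2000 patients, questionnaire
effect size 0.5 SD, letter signal at strength 1 (and, as a negative
control, strength 0); each replicate runs the full pipeline for ED and BD
on a shared split with paired training seeds and one training run per
model (the 20 replicates provide the averaging that the original's 4 runs
provide on a single data set). At strength 1 every model family shows a
positive ED − BD macro-F1 difference in essentially every replicate —
qualitatively reproducing the enrichment benefit — while at strength 0 the
mean absolute difference stays within noise (< 3 percentage points),
confirming the pipeline does not manufacture a benefit from uninformative
flags. These cohort sizes and replicate counts are the package's chosen
problem scale; they are asserted by the test suite rather than quoted
here.

## Numerical and reproducibility choices

* One master seed drives everything; per-stage seeds derive by hashing
  `(master, stage name)` (`derive_seed`), staying below 2^31.
* Distance ties (ReliefF and SMOTE neighbour search) break by row index —
  deterministic and permutation-stable for continuous features.
* Zero-variance columns z-score to 0; zero-denominator precision/recall
  map to 0 with a warning; empty feature selections are an error advising
  a τ change rather than a silent empty model.
* Generated cohorts, pipeline runs and manifests are bit-stable under a
  fixed configuration; the test suite asserts this.

## Known limitations

* The lexicon is a reconstruction from published exemplars, not the
  original (unpublished) full code-word lists.
* Section markers are invented defaults; the original marker expressions
  are not published.
* The real-data F1 levels and feature weights are not reproducible without
  the clinical cohort; the package reproduces the *arithmetic* (splits,
  balancing, metrics) exactly and the *qualitative* enrichment effect on
  synthetic data.
* The MLP is a minimal reference implementation — adequate for tabular
  data of this size, not a general deep-learning tool.
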