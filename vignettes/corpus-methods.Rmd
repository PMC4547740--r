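---
title: "Building and scoring ground-truth corpora of drug/lab temporal correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and scoring ground-truth corpora of drug/lab temporal correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrcorpus)
```

## The problem

Algorithms that screen electronic health records for adverse drug
reactions need, among the WHO causality criteria, a judgement about the
*temporal relationship* between drug exposure and a laboratory test
abnormality. Developing and validating such algorithms requires a ground
truth: a corpus of drug-administration episodes paired with lab value
curves, each labelled by experts as showing a temporal correlation, no
noteworthy change, or being unassessable. `adrcorpus` implements the
computational side of constructing and evaluating such a corpus — episode
mining, normalization, multi-rater aggregation, and evaluation statistics —
plus a synthetic EHR generator so that the whole pipeline can be exercised
and tested without access to patient data.

## Episode mining

The raw inputs are day-granular event streams: drug administration dates
(no dose), lab observations (parameter, day, absolute value), and
patient-specific reference intervals. Episode extraction applies, in order:

1. **Run finding** (`find_administration_runs()`): each patient's
   administration days are partitioned into maximal runs in which
   consecutive administration days are separated by at most one
   administration-free day (`max_internal_gap_days = 1`). The partition is
   unique, so no search heuristics are involved.
2. **Isolation** (`filter_isolated()`): a run is *solitary* if the patient
   has no administration within 14 days (`isolation_days`) before its first
   or after its last administration day. Where a record simply starts or
   ends inside that margin, the absence of recorded administrations counts
   as administration-free — an anonymized extract has no notion of
   enrollment, so requiring observed coverage would silently drop the first
   and last episode of every patient. Isolation is evaluated against the
   study drug only.
3. **Lab curve attachment** (`attach_lab_curve()`): for each (run, lab
   parameter) pair the observations are counted in three phases — *before*
   (the 7 days preceding the first administration day), *during* (first to
   last administration day) and *after* (the 7 days following the last).
   Each phase must contain at least 5 observations
   (`min_obs_per_phase = 5`); otherwise the candidate is rejected with the
   failing phase named. Observations outside the three windows are
   discarded rather than being grounds for rejection: the 7-day constraint
   bounds the recency of the flanking data, not the existence of other
   data. No minimum administration length is enforced — it arises
   implicitly from the 5-observation rule for the during phase.
4. **Normalization and re-anchoring**: accepted observations are mapped to
   `(value − lower) / (upper − lower)` using the patient- and
   parameter-specific reference interval, so 0 and 1 mark the interval
   bounds; values are *not* clamped (a normalized value of 2.11 means the
   absolute value sat at 2.11 interval-widths above the lower bound). Days
   are re-expressed relative to day 0, the first administration day. The
   transformation is affine, so curve shape and the position relative to
   the reference interval are preserved while the absolute scale (and with
   it any hint of the underlying parameter) is removed.
5. **Sampling** (`sample_corpus()`): a uniform random sample without
   replacement (default 400 episodes) forms the corpus. Episodes are
   sorted by id before seeding so the selection is reproducible and
   independent of input order.

`validate_episode()` re-checks all structural rules independently of the
pipeline; `read_corpus()` applies it to everything it loads, so the miner
and the validator cross-check each other.

## Rater aggregation

Each episode is assessed by a panel (11 raters in the reference design) on
a three-category nominal scale: *temporal correlation*, *no change*, *no
assessment*. `classify_votes()` aggregates:

* **Majority call**: the category with the strictly greatest vote count.
  Ties are *standoffs* and are called "no assessment". The tied maximum
  count is still recorded as the agreement count so that the concordance
  value is total — panels never produced a standoff in the reference study,
  but the type must handle it.
* **Concordance value** `c_i`: agreeing raters divided by the total panel
  size (abstentions stay in the denominator — the denominator is the whole
  panel, not the substantive voters).
* **Intricacy**: a rule-based difficulty class from the agreement count —
  `low` (10 or 11 of 11 agree), `medium` (8 or 9), `high` (7 or fewer).
  The thresholds are absolute counts by default, faithful to the 11-rater
  design; `intricacy_rule(mode = "fractional")` rescales them for other
  panel sizes (low: at least n−1 agree; medium: at least `round(8/11·n)`).

## Evaluation statistics

* **Concordance Score** (`concordance_score()`): to compare an external
  (for example algorithmic) assessment against the ground truth, plain
  percent agreement ignores that some curves are genuinely hard even for
  experts. The score weights each episode by its ground-truth concordance:
  `S_C = Σ m_i·c_i / Σ c_i`, with `m_i = 1` when the external category
  equals the majority call. Missing coverage is an error by default;
  `restrict = TRUE` scores the covered subset.
* **Krippendorff's α** (`krippendorff_alpha()`): nominal-scale,
  coincidence-matrix estimator, any number of raters, missing votes
  allowed. α is undefined (an error, not a number) when every pairable
  vote falls into a single category. Note that chance-corrected agreement
  coefficients assume items of comparable difficulty; on a corpus that
  deliberately retains hard curves, α understates the quality of the easy
  majority — which is exactly why the Concordance Score exists. Bootstrap
  confidence intervals are out of scope.
* **Pearson χ²** (`pearson_chi2_2x2()`): the uncorrected closed form
  `N(ad−bc)²/((a+b)(c+d)(a+c)(b+d))` on one degree of freedom, used for
  2×2 contingency comparisons such as correlation counts in expected-ADR
  frequency groups. No continuity correction is applied.
* **Summaries** (`summarize_corpus()`): call × intricacy counts and
  percentages, per-parameter tallies where a parameter tag exists
  (synthetic corpora), and episode-length statistics. Administration
  length is counted inclusively (a run on relative days 0..9 is 10 days).
  The *overall* length is reported under two definitions — administration
  length plus both 7-day flanks, and the observed first-to-last lab day
  span — because both are defensible and they differ when the flanks are
  not fully sampled.

## The synthetic cohort

`generate_cohort()` emulates the data shape the pipeline assumes, not any
real population:

| parameter | default | meaning |
|---|---|---|
| `n_patients` | 60 | patients in the cohort |
| `span_days` | 365 | record length per patient, days |
| `parameters` | 3 lab parameters | population reference bounds + 10% between-patient jitter |
| `admin_episode_length` | 5–14 d | administration run length |
| `admin_gap_rate` | 0.15 | probability of one internal administration-free day |
| `inter_episode_gap` | 15–40 d | administration-free days between runs (≥15 guarantees isolation) |
| `p_obs` | 0.9 | per-day lab observation probability |
| `p_effect` | 0.33 | probability a (run, parameter) curve carries a drug response |
| `effect_amplitude` | 1.0–2.5 | response size, in reference-interval widths |
| `effect_lag_days` | 0–2 d | onset lag after day 0 |
| `baseline_ar` | 0.7 | AR(1) coefficient of baseline dynamics |
| `noise_sd_frac` | 0.15 | innovation s.d., fraction of interval width |

Baselines wander around a level drawn inside the patient's interval with
first-order autoregressive noise; this produces plausibly meandering
curves without claiming to estimate real lab dynamics. A planted response
ramps up linearly over 2 days from its (possibly lagged) onset, plateaus
while administration lasts, and decays exponentially with a 3-day
half-life afterwards — any monotone on/off response would do for testing;
nothing downstream depends on the shape. Responses go up or down with
equal probability. Each (run, parameter) pair carries its own independent
effect flag, recorded in a truth table keyed by the same
`patient:parameter:first_day` id the extractor assigns, which is how
recovery can be verified end-to-end.

The simulated panel (`simulate_raters()`) votes per episode with
probabilities driven by a logistic difficulty term that falls with the
planted amplitude and is scaled by each rater's unreliability:
`penalty = min(1, 8·(1−reliability)·plogis(3·(0.4 − evidence)))`, with
`evidence` the planted amplitude for effect curves and 1.5 interval-widths
for null curves (a clearly flat curve is easy to call). A rater votes
correctly with probability `reliability·(1 − penalty)`, abstains with
probability `abstain_propensity·(1 − p_correct)`, and otherwise votes the
wrong substantive category. The unreliability scaling is deliberate: a
perfectly reliable rater is always correct whatever the difficulty, and a
rater with zero reliability and full abstain propensity always abstains,
which pins both ends of the model exactly. Small amplitudes split the
panel, which is what produces the medium/high intricacy strata.

### What the generator does and does not show

The generator produces the *structure* the pipeline assumes: isolated
runs, gappy daily sampling, autocorrelated baselines, on/off responses,
difficulty-dependent panels. It does not model dose, confounders
(co-medication, therapies), parameter-specific kinetics, circadian or
sub-daily structure, or the selection biases of hospital data. A pipeline
that passes all tests here is verified as an implementation of the stated
rules, not validated as a detector of real adverse drug reactions.

## Numerical and design choices

* Corpus XML serializes normalized values and concordance with 6 decimal
  places; printed 2-decimal figures elsewhere are display rounding.
  Writing is deterministic (stable order, fixed formatting), so
  write–read–write is a byte-level fixed point. In-memory concordance is
  always the exact integer ratio `agree_count/n_raters`; the reader
  recomputes it and checks the serialized decimal against it.
* Duplicate lab values on the same (patient, parameter, day): the
  last-read value wins, with a warning — daily-scale reduction needs some
  rule, and last-write-wins matches how repeated daily exports behave.
* Episode ids are `patient:parameter:first_day`, which makes extraction
  deterministic and joins against the generator's truth table trivial.
* `sample_corpus()` sorts by episode id before seeding, so the same seed
  gives the same corpus regardless of how the episodes were produced.
* Degenerate inputs: zero-width reference intervals, empty vote sets,
  out-of-range agreement counts, partial external coverage, and zero
  expected disagreement in α all raise classed validation errors instead
  of returning numbers.
* Problem sizes in the test suite (cohorts of 6–60 patients, corpora of
  150–400 episodes, 500-stream oracle sweeps) were chosen to exercise
  every rule at comfortably more than toy scale while keeping the default
  suite fast to run.

## Worked run

```{r pipeline, eval = FALSE}
mf <- run_pipeline(
  gen_config  = generator_config(),
  pipe_config = pipeline_config(sample_size = 400),
  profiles    = rater_profiles(11, reliability = 0.9),
  seed        = 1, out_dir = "corpus_out")
mf$counts
summarize_corpus(mf$corpus)
krippendorff_alpha(mf$corpus$votes)

# score an external assessment against the written corpus
corp <- read_corpus(file.path("corpus_out", "corpus.xml"))
ext  <- read_external_assessment("my_algorithm_output.xml")
concordance_score(ext, corp)
```

## Known limitations

* Single-drug isolation: runs are isolated against the study drug's own
  administrations only; multi-drug interaction windows are out of scope.
* Day granularity throughout; within-day changes are invisible.
* The corpus dialect is this package's own documented XML structure. It
  mirrors the published content description (relative administration days,
  normalized observations, classification with concordance), but reading a
  third-party corpus file requires a schema adapter.
* α is reported as a point value; its limitations on mixed-difficulty
  corpora are inherent and are the motivation for the Concordance Score.
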