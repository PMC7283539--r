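---
title: "Methods: phenotype algorithms, the union benchmark, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype algorithms, the union benchmark, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenofrag)
```

## The problem

Computational phenotyping identifies patients with a condition from
structured EHR data — diagnosis codes, labs, medications, encounters and
NLP-extracted physician assertions. Because patients receive care at more
than one institution, any single institution's record is a fragment of the
patient's clinical history, and a phenotype algorithm run on that fragment
can miss true cases (insufficient evidence) or manufacture spurious
controls (missing disqualifiers). `phenofrag` quantifies this effect: it
runs two phenotype algorithms — a regression-scored rheumatoid arthritis
(RA) definition and a rule-based type 2 diabetes mellitus (T2DM)
definition — on single-source views of a multi-institution event store and
on the deduplicated union of all sources, scores each single-source view
against the union as benchmark, and attributes every disagreement to the
evidence missing from the erring source.

Real linked multi-institution EHR data cannot be distributed, so the
package includes a synthetic cohort generator that reproduces the
*structure* of the problem (latent disease, evidence streams, fragmented
recording) and makes every downstream stage testable end to end.

## Data model and source views

Events are rows of a nine-column table (`patient_id`, `event_type`,
`code_system`, `code`, `value`, `date`, `source_id`, `entry_mode`,
`linkage_key`). The `linkage_key` identifies the same real-world event
across institutions, standing in for the identity resolution that a
record-linkage system performs; the package deliberately does *not* model
probabilistic linkage. A `source_view` restricts the event store to one or
more sources. Two contracts matter:

* a multi-source view keeps one representative per `linkage_key` (earliest
  date, ties to the lexicographically smallest `source_id` — an arbitrary
  but deterministic rule, since copies of a linked event carry the same
  content);
* every view retains the full patient roster, so a patient invisible to a
  source contributes an empty evidence vector rather than disappearing.
  This makes the TP+FP+TN+FN universe identical for every view, which the
  published count tables this design follows also require.

Code lists are declarative: exact codes or trailing-`*` prefix wildcards,
dot literal, case-insensitive, one coding system per list, grouped into
algorithm roles (`ra_dx`, `t2dm_med`, ...). The bundled
`codelists.yaml` vocabulary is a plausible placeholder, not an
authoritative terminology: the published algorithms do not print their
code sets, so the vocabulary is configuration an implementer is expected
to replace.

The analysis window is the closed interval 2010-01-01 to 2017-12-31
("during 2010 and 2017" read inclusively), configurable in
`filter_window()` and `sim_config()`.

## The RA algorithm

Screen-positive patients (at least one RA diagnosis code in the view) are
scored with a logistic model over six features: RA, SLE and psoriatic
arthritis (PA) diagnosis counts, rheumatoid-factor (RF) test count,
positive-RF count, and total encounters. A patient is a case when

$$
\mathrm{logit}^{-1}\Big(\beta_0 + \textstyle\sum_f w_f\,\log(1+x_f)\Big)
\;\ge\; 0.632 ,
$$

with ties counted as cases (the published description fixes the cutoff but
not the tie side; inclusive is the natural reading of "at or above").
Controls are patients with *no* RA diagnosis codes and *no* exclusion
codes; everyone else — including screened patients scoring below the
cutoff — is `neither`. The three labels partition every view.

The published algorithm does not print its fitted coefficients, so the
model is a configuration artifact (`ra_model.yaml`) whose defaults obey
the documented sign structure: positive weights on RA diagnoses and
positive RF results, negative weights on SLE, PA and encounter volume.
The `log1p` transform tempers count skew (a 40-visit patient should not
dominate); `raw` is available for exact algebraic tests. Package tests
rely only on the logistic form, the signs, and the cutoff — never on the
particular default weights. RF positivity is a lab value above a
configurable threshold (default 14 IU/mL, a common upper reference
limit); both the test count and the positive count are kept as features
because the algorithm description treats them as distinct signals.
Encounters enter as the raw window total (per-year normalisation is a
plausible alternative the source does not describe; the raw total is the
simpler reading and is what the negative weight acts on). Model *fitting*
is out of scope — the package applies a fitted model, it does not train
one.

## The T2DM algorithm

The rule-based T2DM case definition is a decision tree over patient-level
evidence: T1DM/T2DM diagnosis counts (billing plus NLP-extracted),
physician-asserted T2DM diagnoses (entry mode `physician` or `nlp`),
medication flags for T1DM and T2DM agents, whether the earliest T2DM
medication predates the earliest T1DM medication, and any abnormal
glucose/HbA1c. The original flowchart is published only as a figure, so
the tree is reconstructed from its factor set as five declarative paths
(`default_t2dm_paths()`, overridable in `t2dm_rules.yaml`):

* **P1** no T1DM dx, T2DM dx, T2DM medication;
* **P2** no T1DM dx, T2DM dx, no T2DM medication, abnormal lab;
* **P3** no T1DM dx, no T2DM dx, T2DM medication *and* abnormal lab;
* **P4** T1DM dx present (possible miscoding), T2DM dx, both medication
  classes, T2DM medication first;
* **P5** T1DM dx present, T2DM dx, T1DM medication only, at least two
  physician-asserted T2DM diagnoses.

The branch *order* of the original figure is not recoverable from text;
only the factor set is authoritative, which is why the path set is data,
not code. Controls must pass six screens: at least two in-person visits
(an encounter-code attribute), at least one glucose measurement, no
abnormal lab, no diabetes-related diagnosis, no diabetes medication or
supplies order, and no self-reported diabetes family history. A case call
takes precedence when both algorithms fire.

Abnormality thresholds default to the standard diagnostic values —
fasting glucose ≥ 126 mg/dL, random glucose ≥ 200 mg/dL, HbA1c ≥ 6.5% —
because the algorithm description says only "abnormal lab". The fasting
threshold applies to the codes in the `fasting_glucose_lab` role; other
glucose codes use the random threshold.

## Benchmark, metrics and attribution

With no chart-review gold standard available, the benchmark is the
algorithm's own output on the union view; `benchmark_calls()` refuses
anything narrower. Confusion counts are set arithmetic over the fixed
roster, and the four metrics are

sensitivity = 100·TP/(TP+FN), specificity = 100·TN/(FP+TN),
PPV = 100·TP/(TP+FP), FNR = 100·FN/(TP+FN),

kept at full precision internally; a zero denominator produces `NA` with a
warning rather than an error. Rounding happens only in reports, half-up,
at a configurable precision (default one decimal; integer precision is
supported because abstracts commonly print whole percentages).

`attribute_missing_info()` explains errors: for each FN/FP subject it
flags every algorithm factor present in the union view but absent in the
erring source, plus (for RA) the total encounter shortfall. Because a
source view's events are always a subset of the union's, evidence is
monotone, and any label disagreement implies at least one evidence
component strictly smaller in the source — the `any_missing` column
records this full-evidence check, so attribution completeness is a
verifiable property, not an aspiration. Note the mechanism is two-sided:
missing *positive* evidence masks cases (FN), while missing *negative*
evidence — encounters and confuser diagnoses for RA, T1DM codes or
disqualifying labs for T2DM — manufactures spurious cases and controls
(FP).

## The synthetic cohort generator

`generate_cohort()` draws, per patient: latent RA status, latent T2DM
status (`case` / `control_eligible` / `neither`), a self-reported family
history flag, a home institution, and a home-affinity probability
`p_home`. Event streams then follow the latent status with
`min + Poisson(λ)` counts per evidence category, and each event is
recorded at the home source with probability `p_home` (otherwise at a
random other source) and additionally captured by each other source with
an origin-specific duplication rate. Copies share a `linkage_key`. Latent
truth lives in a separate table that no classifier input touches.

Default conditions, chosen once and analytically, in order:

* **Prevalences** reproduce the benchmark proportions of the motivating
  45,183-patient biobank cohort: RA 620/45,183 ≈ 1.4%, T2DM cases
  5,215/45,183 ≈ 11.5%, control-eligible 6,293/45,183 ≈ 13.9%.
* **Two sources** (`Mayo`, `REP`) with home shares 0.7/0.3 — a local-EHR
  cohort whose members mostly, but not exclusively, receive care locally.
* **Affinity** `p_home ~ Beta(mean 0.8, concentration 15)`: most care at
  home, with realistic patient-to-patient spread. Sweeps
  (`fragmentation_sweep()`) hold `p_home` constant to isolate the dial.
* **Asymmetric capture** `c(Mayo = 0.95, REP = 0.20)`: the record-linkage
  source sees nearly all locally recorded events, while the local EHR sees
  few external ones. This is the defining asymmetry of a regional linkage
  system and is what makes the linkage source's view nearly complete and
  the local view strongly fragmented.
* **Small per-category evidence counts** for diseased patients (one or two
  medication orders, one or two decisive labs, RA diagnosis counts of
  7 + Poisson(2) against a model that needs most of them): a source must
  see the majority of a patient's union evidence before the algorithms
  fire. This near-threshold regime is deliberate — it is the regime in
  which fragmentation produces false negatives at all, and it makes the
  single-source FNR increase as `p_home` falls, the qualitative phenomenon
  the evaluation exists to measure. With abundant redundant evidence every
  view would classify perfectly and the experiment would be vacuous.
* **Lab values** are log-normal per analyte and disease state (e.g.
  fasting glucose around 160 mg/dL diseased vs 92 mg/dL healthy), so
  abnormality emerges from values crossing clinical thresholds rather than
  from a planted flag.
* **Miscoding** (5% of diseased patients) plants confuser codes — SLE/PA
  for RA cases, T1DM codes with occasional insulin for T2DM cases —
  exercising the negative-weight and T1DM-disambiguation branches.
* Glucose testing among patients with no diabetes-adjacent findings is
  uncommon (Poisson mean 0.15 per window), keeping the control pool from
  swallowing the whole cohort.

The generator's FNR levels under the defaults are tuned to be
*qualitatively* comparable to multi-institution experience — local-EHR
case FNRs of roughly 20–50% against single digits for the linkage source —
not to reproduce any particular published count, which would require the
private data.

### Determinism

All randomness flows from one master seed through a single RNG stream in a
fixed generation order, so a configuration and seed yield byte-identical
cohorts. Per-patient counter-split streams were considered and rejected:
they buy robustness under generation reordering that a fixed vectorised
order does not need, at the cost of a hand-rolled RNG discipline. Sweep
replicates derive per-value seeds deterministically from the base seed.

## Numerical and design choices

* Closed date interval for the study window; boundary events are kept.
* Union dedup tie-break: earliest date, then smallest source id.
* Probability exactly at the RA cutoff ⇒ case.
* Medication precedence is `NA` unless both medication classes are
  present; paths requiring it treat `NA` as unsatisfied.
* Zero-denominator metrics are `NA` with a warning, never a crash.
* Half-up rounding only at report time.
* RA probabilities are reported for all benchmark cases under every view,
  including patients outside a source's inclusion cohort (scored from
  their possibly-empty feature vector), so probability trajectories across
  sources are comparable.
* RA control eligibility depends on exclusion codes that are not model
  features; error attribution therefore diffs both the feature vector and
  the factor-presence table.

The package's own test conditions (stated here as package choices): the
benchmark self-consistency and attribution properties are exercised on
1,500–2,000-patient cohorts; the fragmentation-monotonicity property uses
24 replicate seeds of 1,000 patients at `p_home` ∈ {1.0, 0.8, 0.6} in a
paired common-seed design, which removes between-cohort noise from the
level contrasts.

## What passing tests do and do not show

The simulator reproduces the structural mechanics of fragmentation, so
green tests certify the *pipeline*: parsing, view algebra, the algorithms'
logic, metric arithmetic, attribution completeness, determinism. They do
not certify clinical validity on real data: the synthetic vocabulary is a
placeholder; event dates are uniform within the window (no disease
trajectories, no ICD-9→ICD-10 era switch); NLP extraction is modelled as
already-structured events with no extraction error; event categories are
independent given latent status; and the two diseases are independent,
which understates comorbidity. Results on real linked data will differ in
level; the package's claim is about the direction and mechanism of
fragmentation effects and about correct, reproducible measurement.

## Known limitations

* No probabilistic record linkage: `linkage_key` is given.
* No OMOP/FHIR ingestion; CSV plus YAML configuration only.
* No statistical inference (confidence intervals) on the metrics.
* The RA weights are plausible configuration, not the unpublished fitted
  coefficients; absolute probabilities are therefore not comparable to the
  original model's, only the structure of the computation is.
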