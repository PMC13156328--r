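---
title: "Building and scoring operating-room QA benchmarks with orqa"
author: "orqa authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and scoring operating-room QA benchmarks with orqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orqa)
library(data.table)
```

## The problem

Operating-room (OR) scene understanding asks a system to answer clinically
relevant questions about an intraoperative scene: how many people are
present, what role each plays, where the drill is, whether the robot is
calibrated, whether a sterility breach is occurring. Benchmarks for this
ability are assembled from heterogeneous public OR datasets, each exposing
a different subset of annotation modalities (multi-view boxes, 3D
positions, scene graphs, clinical roles, surgical phases, gaze fixations,
robot state logs, audio transcripts, monitor text). `orqa` packages the
machinery around such a benchmark as reusable, testable components:

1. a **seeded scene simulator** whose annotation structure mirrors four
   source-dataset families, so every downstream stage can be exercised
   without any download;
2. a **QA engine** instantiating 23 task templates with canonical
   ground-truth answers derived from the scene records;
3. a **diversity-aware sampler** reducing a large QA pool to a benchmark
   using inverse question/answer frequency and per-source mixing weights;
4. the **ORQA Score** suite — all task-specific rules, three-level
   aggregation, and bootstrap confidence intervals;
5. a **most-frequent-answer statistical baseline** with a lenient
   free-text answer parser;
6. a **knowledge-distillation kernel** (temperature-scaled KL loss,
   top-left weight-crop initialization, progressive shrinking) exercised
   on toy networks.

## The scene simulator

`simulate_case()` generates one surgical case: an ordered timeline of
annotated timepoints in a room whose origin sits at the floor center
(meters; default extent 8 × 6 × 3 m). Entities — staff roles, the
patient, furniture, and four instruments — carry 3D positions following a
bounded random walk (≤ 0.12 m per axis per step, so projected boxes move
continuously), per-view 2D boxes from pinhole cameras (0-based pixels,
top-left inclusive, bottom-right exclusive, clipped to the 640 × 480
image), sterility flags, and color attributes. The operating table, the
patient and the instruments cluster in the central sterile field, as they
do in a real OR; staff drift in and out of the room.

Workflow state comes from two contiguous random partitions of the
timeline: six surgical phases (`preparation` … `closing`) and an
eight-step robot sequence traversed in fixed order with random dwell
times. Both token lists are configurable — the source families do not
publish a canonical phase taxonomy, so generic tokens are used. Phase
progress is linear within a phase, hence monotone, and the robot state
always satisfies `step_index == length(completed_steps) + 1`.

Scene-graph triplets tie present entities together (`(patient, lying_on,
operating_table)`, `(head_surgeon, holding, drill)`, …). A configurable
fraction of robot-OR cases (default 0.5) contains one sterility-breach
interval, during which the sterile head surgeon touches the non-sterile
tool cart; `detect_sterility_breach()` flags exactly the contact-class
predicates (`touching`, `holding`, `grasping`) linking a sterile team
member to a non-sterile entity. Gaze fixates the tool currently in use
(its box center plus 6 px Gaussian noise), which guarantees a resolvable
ground-truth target most of the time; `resolve_gaze_target()` breaks
overlapping-box ties by smallest area. Monitor text is a vitals summary
following a per-case random walk; the transcript tail carries the last
five sentences drawn from a small phrasebook.

Each of the four source profiles (`mvor_like`, `fourdor_like`,
`egosurgery_like`, `mmor_like`) enables only its modality subset
(`default_source_profiles()`); disabled fields are entirely absent from
that source's records, and the egocentric profile exposes a single
head-mounted view seeing only the instruments. Every case derives its own
RNG stream from `(seed, source_tag, case_index)`, so corpora are
reproducible case by case regardless of generation order. Splits are
assigned **per case** with largest-remainder rounding of the 0.8/0.1/0.1
ratios — no scene ever contributes to two splits.

What the simulator does **not** emulate: images, point clouds or audio
themselves (annotations only), detector/annotator noise, correlated
multi-person motion, realistic phase-duration distributions, or the label
taxonomies of the real datasets. Passing tests therefore demonstrate that
the machinery — generation, sampling, scoring, baselines — is correct and
reproducible, not that any model result on the real benchmark transfers.

## The QA engine

`orqa_tasks()` registers exactly 23 tasks, each with one answer tag, one
scoring rule, one question template, and the modality flags a source must
provide. The gating table is conservative where the source descriptions
give examples only: scene-graph tasks require scene graphs; robot-state,
sterility and monitor-text tasks require the fully instrumented robot-OR
profile; gaze tasks require gaze. `derive_answer()` is a pure function of
the stored record (plus its timeline for temporal context); unsupported
task/source pairings return a skip signal rather than an error.

Conventions fixed once: triplets serialize as `(subject,predicate,object)`
semicolon-separated; durations round to whole seconds, distances to
centimeters, progress to whole percent; left-to-right order for sorted
entity detection is defined by box-center x in the first (reference) view,
ties broken by class name; a phase that has already started is never asked
as "time until" — it becomes an "is completed" question instead. One
canonical template per task keeps generation deterministic; paraphrase
banks are an extension point, not a default.

## Diversity sampling

Raw pools over-represent trivial answers. `sample_benchmark()` draws a
benchmark in four nested strata: split (boundaries never crossed), source
(targets follow the mixing weights 0.40/0.30/0.20/0.10, chosen to balance
source families of very different sizes), task (equal quotas within a
source, remainders spread over task-name order), and finally a weighted
draw without replacement. The weight of a pair is
`1 / (question_count × answer_bin_count)` — the published description
names inverse question and answer frequency without a formula, and the
product is the simplest choice that reduces to each factor when the other
is constant. Continuous answers need bins for "answer frequency" to be
meaningful: scalars bin at 0.25 m / 10 s / 10 %, boxes and 2D points by
an 80 px image-grid cell, 3D points by a 0.25 m voxel grid.

The draw uses the exponential-key scheme (one `Exp(1)/w` key per pair,
smallest keys win), which is reproducible under a seed and independent of
pool row order. An exhausted stratum contributes everything it has and is
recorded as a shortfall — quotas are not silently redistributed.

## The ORQA Score

All rules return values in `[0, 1]` and are exercised against worked
examples and independent oracles in the test suite:

* **People counting** — 1.0 exact, 0.5 off by one, 0.0 otherwise.
* **Set tasks** (roles, tools, entities) — IoU of normalized token sets;
  two empty sets score 1.0.
* **Single-label tasks** (including the binary predicates) — exact match
  after normalization (case folding, punctuation stripping, whitespace →
  underscore).
* **Relative-error tasks** (3D distance, progress, time-until) — 1.0 for
  errors < 10 %, 0.5 for < 25 %, 0.0 beyond; the inequalities are strict
  as printed, and a zero truth scores 1.0 only for a zero prediction.
* **2D localization** — tiered box IoU with inclusive thresholds
  (≥ 0.75 → 1.0, ≥ 0.5 → 0.75, ≥ 0.25 → 0.5, ≥ 0.125 → 0.25).
* **Scene-graph generation** — macro F1 over predicate classes of
  exactly matching triplets, averaged over the classes observed in truth
  or prediction (averaging over a fixed vocabulary is the untaken
  alternative; observed classes penalize hallucinated predicates, which
  is the behavior a benchmark wants).
* **Sorted entity detection** — `1 − d/max(|pred|, |truth|)` with
  token-level Levenshtein distance `d`: the published rule names a
  distance, the score must be 0–1 with higher better.
* **Monitor text** — BLEU-1: clipped unigram precision times the brevity
  penalty `exp(min(0, 1 − r/c))`.
* **3D localization and gaze location** carry no published rule; the
  package reuses the only printed tier scheme on Euclidean error
  normalized by the room diagonal (3D) or image diagonal (gaze). These
  two rules are substitutes chosen for consistency, not published facts.

`score_benchmark()` parses prediction text leniently per task (a model
answering "Yes, there is." matches `yes`; "approximately 1.8 meters"
parses as 1.8); anything unparseable or missing scores 0.0 and is counted
in the parse-failure rate — conservative, and consistent with how
free-text model output is graded by hand. Aggregation reports per-task,
per-dataset and overall means; the overall mean is the micro average over
items, with the per-task macro mean reported alongside, since the
published weighting is unstated. Confidence intervals are percentile
bootstrap over items, 1,000 resamples at 95 % by default, seeded per
cell.

## The statistical baseline and its random reference

`fit_baseline()` predicts, per task, the most frequent training answer:
modal full answer for categorical/set/sequence/triplet/text tasks (ties
to the lexicographically smallest, so fits are deterministic), arithmetic
mean for scalars, coordinate-wise mean for boxes and points. Reading
"most frequent answer" as the modal *full* answer (not a per-element
assembly) is the simplest interpretation and keeps set answers valid.

The no-information reference it must beat, `predict_random()`, draws
uniformly from each task's answer **space** — yes/no at 50/50, scalars
uniform over the observed range, boxes uniformly placed in the image,
sets as uniform random subsets of the vocabulary — rather than from the
empirical answer distribution. Sampling actual benchmark answers would
hand the "random" guesser the distributional information and
partial-credit structure whose value the baseline is supposed to measure.

## The distillation kernel

`distillation_loss()` implements the temperature-scaled objective
`KL(softmax(z_t/T) ‖ softmax(z_s/T)) · T²`, reduced by the mean over
batch items (the reduction is unstated in the published formula; the mean
keeps the loss scale batch-size invariant). KL is in nats — the printed
summation leaves the base unspecified, and natural log matches every
property asserted in the tests. The loss is zero exactly when student
logits equal teacher logits up to a per-item constant, and at `T = 1` it
reduces exactly to plain KL of the softmaxes.

`crop_initialize()` takes the leading (top-left) submatrix of each
teacher weight matrix and the leading bias entries; it is the identity at
equal dimensions and composes (crop∘crop = crop to the smaller size).
`progressive_distill()` trains a non-increasing schedule of students,
each initialized by crop from its predecessor, with plain SGD and manual
backpropagation on toy tanh MLPs fed by a Gaussian-mixture input
generator. The teacher here is a fixed random network: the kernel's
correctness claims (loss identities, crop laws, argmax agreement above
90 % after 500 steps on a 2-class toy teacher) do not depend on the
teacher having been trained, and transformer-scale distillation is out of
scope. The optional hard-label mixing weight defaults to 0: only the
printed objective is implemented.

## Numerical choices and degenerate inputs

* Tier boundaries: relative-error tiers strict (`<`), IoU tiers inclusive
  (`≥`), both as printed.
* Degenerate boxes have zero area and IoU 0 unless both boxes are
  degenerate and equal.
* `bootstrap_ci()` with fewer than two items warns and returns the
  degenerate `(mean, mean)` interval.
* Probability vectors must sum to 1 within 1e−9; `KL` errors on support
  violations (`Q(i) = 0` where `P(i) > 0`) and applies `0·log 0 = 0`.
* All RNG consumers (`simulate_case`, `assign_splits`,
  `sample_benchmark`, `bootstrap_ci`, `predict_random`,
  `progressive_distill`) seed locally and restore the caller's RNG state.

## Problem sizes

The package's own reference computations run at desk scale, chosen to
keep every check fast while leaving no stratum starved: unit fixtures use
4 cases × 12 timepoints per source; the end-to-end pipeline check uses
16 cases × 30 timepoints (a pool of ≈ 86,000 pairs) sampled to a
2,000/200/200 benchmark; the mixing-weight check generates
65 cases × 70 timepoints per source (≥ 50,000 candidate pairs per
source) and draws 100,000 pairs. The million-pair scale of a production
benchmark is configuration, not code: `sampler_config()` target sizes
scale up without any change to the machinery.

## A worked pipeline

```{r pipeline, eval = FALSE}
cfg <- sim_config(n_cases_per_source = 16, timepoints_per_case = 30,
                  seed = 7)
corpus <- simulate_corpus(cfg)
pool <- generate_qa_pool(corpus)
bench <- sample_benchmark(pool, sampler_config(
  target_sizes = c(train = 2000, val = 200, test = 200), seed = 3))

model <- fit_baseline(bench$pairs[split == "train"])
test_set <- bench$pairs[split == "test"]
report <- score_benchmark(test_set, predict_baseline(model, test_set),
                          scoring_config(), seed = 1)
report
```

## Known limitations

* Synthetic scenes are far simpler than real OR recordings; absolute
  score levels on this corpus say nothing about scores on real data.
* The answer parser is lenient but rule-based; adversarial free text can
  still defeat it (and then scores 0, the conservative direction).
* Macro F1 over observed predicate classes means a prediction can lower
  its own score by inventing predicate classes; that is intended.
* The simulator's phase and robot-step taxonomies are generic tokens;
  ingestion adapters for the real dataset releases are an extension
  point, not part of the package.
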