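---
title: "The scoring model behind vpsmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The scoring model behind vpsmetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpsmetrics)
```

`vpsmetrics` scores what a medical student did during a virtual-patient
simulation against the case author's answer key. This vignette explains the
model, the choices that were genuinely open, and what the synthetic-data
tests do and do not establish about real student logs.

## Data model

A **case** is the answer key: per-section sets of relevant items (scenario
diagnostic factors, relevant questions, examinations, tests), a hypothesis
list in which the author marks the reasonable differential and the correct
final diagnosis, a binary-analysis reference assigning each
(diagnostic factor, hypothesis) pair one of three anchors — *increase*,
*neutral*, *decrease* — and a handful of critical diagnostic acts with
their desired execution order. A **log** is one student's ordered action
stream; only order and counts matter, never wall-clock time, so timestamps
are not part of the schema. Stored relevance flags are a cache: whenever a
case is supplied the flags are recomputed from it, keeping every metric a
pure function of (case, raw actions).

## Section scores

For each of the 7 sections (`s a p m h b r`):

* sensitivity = |distinct relevant items acted on| / |relevant items in
  the case|;
* precision = |distinct relevant items acted on| / |distinct items acted
  on|;
* F1 = harmonic mean, with F1 := 0 when both components are 0.

Two rules are deliberate design choices rather than forced by the metric
definitions:

* **Distinct-item counting.** Asking the same question three times counts
  once in numerator and denominator. "Identified" denotes coverage of the
  reference set; penalizing repetition is the job of the methodological
  score (p5), and double-penalizing it through precision would conflate
  content skill with process style.
* **Zero-action precision := 0.** An inactive section could leave precision
  undefined (0/0); defining it as 0 keeps every score total and bounded and
  maximally penalizes skipping a section, which is the pedagogically
  conservative choice.

The binary-analysis section scores **first attempts only**: the sensitivity
numerator counts pairs whose attempt-1 anchor equals the reference, over
all reference pairs; precision uses attempt-1 pairs executed as the
denominator. Later attempts stay in the log (they are useful for review)
but never reach a metric. A pair key that does not exist in the reference
matrix cannot be produced by the simulator interface, so such records are
ignored rather than penalized.

A section whose relevant set is empty has an undefined sensitivity
denominator; it is flagged *not assessable* and excluded from every
composite average rather than silently scored 0. Real cases populate all
seven sections.

## Composite scores

The overall score is the arithmetic mean of the assessable sections' F1
values; collection averages `s a p m`, analytical averages `h b r`. The
combination rule is not forced by anything in the metric definitions; the
unweighted mean is the simplest rule consistent with a 0–1 score range, and
a named-weights hook (`weights =`) is exposed for instructors who weight
sections differently. With all 7 sections assessable the algebraic identity
`7 * overall = 4 * collection + 3 * analytical` holds exactly, and the
tests assert it. Ranks are competition ranks ("1224"), rank 1 best.

## The methodological score

The action stream is encoded one character per action by section code and
collapsed (`sssaapp` → Φ = `sap`). Five bounded parameters are computed on
Φ: prefix similarity to `sap` (p1), suffix similarity to `br` (p2),
hypothesis-before-test indicator (p3), section coverage k/7 (p4) and the
revisit penalty 1/(1+R) (p5). The score is the Euclidean norm
√(Σ pᵢ²) ∈ [0, √5]; a normalized form score/√5 is carried alongside for
reporting, since the raw scale has no printed reference axis.

Open points resolved here, each implemented as a documented total rule:

* **Levenshtein similarity** is not a standard single object; we use
  1 − d(x, y)/max(|x|, |y|), clamped to [0, 1], with both-empty = 1. It is
  symmetric and bounded like the other four parameters. The edit distance
  is the classic unit-cost dynamic program, cross-checked in the tests
  against the independent C implementation in `utils::adist`.
* **Short Φ.** p1 compares whatever prefix exists (≤ 3 characters) and p2
  the ≤ 2-character suffix, so a truncated workflow is penalized
  proportionally instead of erroring; empty Φ gives p1 = p2 = 0.
* **p3 without tests.** Ordering a test before hypothesizing is the error
  being penalized; a student who orders no test commits no violation, so
  no-`m` logs score p3 = 1, while `m` without any `h` scores 0.
* **R (repetitions)** := |Φ| − |distinct(Φ)|. Contiguous repeats are gone
  after collapsing, so every remaining duplicate character is a genuine
  return to a previously visited section — exactly the back-and-forth
  behavior the parameter penalizes.
* **Which actions build Φ.** All logged actions, by default: the worked
  `sssaapp` example is built from ordinary scenario/anamnesis/examination
  actions. A `mode = "critical"` flag restricts Φ to actions bound to
  critical acts for users who read the construction the other way; path
  analysis proper is a separate module either way.

An empty log yields p = (0, 0, 1, 0, 1) and score √2 — a documented
degenerate output, not an error.

## Path analysis

Each critical act is bound to a concrete action (e.g. P = the "abdominal
palpation" examination item), so extraction is exact: the student's path is
the act ids ordered by first execution, acts never executed absent. The
cohort table aggregates identical paths with exact fractions, plus half-up
integer percents for human-readable output (3 of 36 prints as 8%).
`path_query()` generalizes questions of the form "reached the diagnosis
without a physical examination" as present/absent act predicates.

## Cohort report and validation

Class mean and **sample (n−1) SD** of the overall score (the usual
convention for a class summary treated as a sample); histogram over [0, 1]
in 20 right-open bins of width 0.05, the last bin closed so a perfect 1.0
is counted; per-section class-mean F1 as the radar baseline. Spearman
validation uses average ranks for ties and the two-sided t-approximation
p-value `t = ρ√((n−2)/(1−ρ²))`, adequate at class sizes of a few dozen
(an exact permutation test would only matter below n ≈ 10). Students
missing either value are dropped pairwise with the retained n reported;
a constant metric or exam vector makes ρ undefined and the result is
flagged rather than faked.

## The synthetic cohort

The generator exists so every code path is exercisable without real
student data. A student is four numbers:

* θ (thoroughness, default 0.6): probability each relevant item is acted
  on — drives sensitivity;
* λ (noise, default 2): expected irrelevant actions per section, Poisson
  from a per-section decoy pool — drives precision down;
* β (binary-analysis accuracy, default 0.6): probability a first-attempt
  anchor is correct; half of the wrong first attempts get a corrective
  second attempt, exercising the first-attempt-only rule;
* δ (discipline, default 0.6): probability of working through sections in
  the canonical clinical order `s a p h m b r` without revisits; otherwise
  section blocks are shuffled and a geometric (mean 2) number of extra
  revisits is injected, degrading p1, p2, p3 and p5 independently of
  content skill.

The defaults describe a mid-level student; a 25-student default cohort
lands in the mid-0.5s for the class-mean overall score with single-digit
SD — the range instructors report for real mid-course classes. At
θ = 1, λ = 0, β = 1, δ = 1 the generator attains the analytic maximum of
the entire stack (all F1 = 1, methodological score √5, desired path
followed), which the tests assert exactly.

Generated cases place one critical act per section in workflow order, so a
fully disciplined thorough student can reproduce the desired path. Real
cases may bind several acts within one section (e.g. palpation and a
specific sign, both physical examinations); the generator avoids that
because within-section action order is shuffled, which would make the
desired path unattainable by construction. Per-student seeds derive from
(cohort seed, student index), so a student's log is independent of cohort
size.

**What passing synthetic tests do not show:** the generator draws actions
independently per item, has no premature-closure cognition beyond the
ordering/revisit mechanics, no realistic question text or matching errors,
and no correlation between a student's content skill and discipline unless
you supply heterogeneous parameter vectors. Agreement of the pipeline with
its definitions on synthetic data says nothing about the validity of the
metrics as measures of clinical reasoning in real cohorts; that is an
empirical question requiring external criteria.

## Numerical choices and problem sizes

All scores are ratios of small integer counts; no optimization or
tolerance-bearing numerics are involved beyond the Euclidean norm
(asserted to 1e−12 in tests). The test suite's stochastic properties run
at fixed seeds: oracle equivalence of section metrics on 500 random small
fixtures (≤ 10 items per section), edit-distance oracle agreement
exhaustively on all string pairs up to length 2 plus all ≤ 3-character
strings against both reference patterns and 2,000 random longer pairs,
parameter recovery on 200 simulated students (3-standard-error band), and
a 100-per-arm sign test that disciplined cohorts outscore undisciplined
ones methodologically. These sizes keep the full suite around two minutes
on one core while leaving the statistical checks comfortably powered.
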