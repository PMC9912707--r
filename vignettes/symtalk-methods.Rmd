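---
title: "Detecting symptom talk with a keyword library: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting symptom talk with a keyword library: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symtalk)
```

## The problem

Patients with advanced cancer carry a heavy symptom burden, and much of it
is voiced — and then lost — in ordinary clinic conversation. A clinician
asks "how are your bowels", a patient mentions being "on edge all the
time", a caregiver asks about more Ativan; little of this reaches the
chart. Rule-based detection of *symptom talk* — any turn-level reference
to symptoms, side effects or their management — is the simplest
computational handle on this problem: a curated library of literal words
and phrases, grounded in the PRO-CTCAE framework (the patient-reported
version of the Common Terminology Criteria for Adverse Events, covering
roughly 80 clinically relevant cancer symptoms), matched against each
speaker turn of a transcribed encounter.

`symtalk` implements that detector together with everything its
development and honest evaluation requires: the lexicon data model and its
version-diff machinery, transcript I/O and tokenization, the turn-level
matcher with exclusion patterns, gold-standard construction from
multi-coder relevance scores, confusion-matrix evaluation with
stratification and review sampling, n-gram candidate mining for the
curation loop, and a synthetic-conversation generator that makes the whole
pipeline testable without access to any real (and necessarily
confidential) clinical transcript.

## The detection model

The unit of analysis is the **speaker turn**: an uninterrupted span of
speech by one participant. Detection is binary at the turn level.

Matching is deliberately austere:

* terms are **literal strings**, never regular expressions;
* a single-word term matches any equal token, a multi-word phrase matches
  an equal contiguous token sequence;
* matching is case-insensitive and at **token boundaries** only, so "red"
  can never fire inside "bothered";
* morphological variants are separate explicit entries ("deep breath" and
  "deep breaths"), never produced by stemming.

This keeps every detection auditable: any flagged turn can be explained by
pointing at a library entry and a span. The cost is equally explicit —
misspellings, inflections not in the library, and colloquial paraphrases
("things will just run through" for diarrhea) are missed by construction.
Those limits are inherent to rule-based methods and are the reason the
package pairs the matcher with an evaluation and curation harness rather
than presenting it as a finished clinical instrument.

**Exclusion patterns** handle the one contextual correction the approach
admits: a phrase (e.g. the physical-exam instruction "deep breaths") whose
occurrence suppresses any keyword match *fully contained* in its span.
Exclusions are contextual suppression, not term deletion: a library
containing "breaths" still matches it outside the excluded phrase.
Both views of exclusion exist in practice, so term-level removal is also
available (via `filter_library()` / `diff_libraries()`), but the shipped
semantics are span containment.

Two design points were genuinely open and were settled as follows:

* **No context beyond the turn.** Symptom talk spread over several turns
  ("how do you feel" — "seven and three quarters") is not recoverable by
  keywords in a single turn; the matcher makes no attempt to window across
  turns, and the evaluation framework treats such turns as expected false
  negatives rather than hiding them.
* **All speaker roles are searched by default.** Patients, caregivers and
  clinicians all produce symptom talk ("do you need any more ativan" is a
  clinician turn); role filtering is an analysis choice, not a matcher
  default.

## Tokenization

Turn text is normalized (lowercased; typographic apostrophes and quotes
mapped one-to-one onto ASCII so character positions are preserved) and
tokenized into maximal runs of letters and digits with internal
apostrophes and hyphens kept token-internal ("don't", "schedule-wise").
Token spans are **1-based inclusive** `[start, end]` character positions —
the native R string convention (`substr`, `stringr::str_locate`) — and
`substr(normalize_text(text), start, end)` reproduces each token exactly.
This span convention is asserted by property tests over randomized text.

## Gold standards

Coders score each turn for symptom relevance on a 0–3 scale. The **broad
gold standard** averages the available coders per turn and calls the turn
positive when the mean is **at least 2** — a closed bound, so a mean of
exactly 2.0 is positive (tested at the boundary). Single-coded turns are
allowed; the threshold applies to whatever coders scored the turn.

Because a PRO-CTCAE-grounded library targets a narrower construct than
"all symptom talk", a second, **PRO-CTCAE-focused gold standard** is
derived from the broad one by explicit manual overrides — downgrading
turns whose symptom content falls outside the framework, upgrading turns
where coders missed, say, a symptom-relevant medication. Overrides live in
a sidecar table (`conversation_id`, `turn_index`, `proctcae_positive`,
`note`), which keeps the focused standard reproducible, auditable and
idempotent under re-application.

Inter-rater reliability is chance-corrected agreement on binarized labels.
Both Fleiss' kappa (default; computed on the fully crossed turns) and the
mean of pairwise Cohen's kappas are exposed, because multi-rater designs
are reported with either and the underlying statistic behind any given
published coefficient is rarely recoverable; the package asserts the
arithmetic of both against independent closed-form oracles, not any
particular published value. Degenerate tables (chance agreement of 1)
return `NaN` with a warning rather than an arbitrary number.

## Evaluation

Detection crossed with a gold standard gives turn-level TP/FP/TN/FN and
the five standard metrics: sensitivity TP/(TP+FN), specificity
TN/(TN+FP), precision TP/(TP+FP), accuracy (TP+TN)/total, and
F1 = 2TP/(2TP+FP+FN). Numerical conventions:

* a zero-denominator metric is **undefined** (`NA`), never 0 and never an
  exception — small strata would otherwise silently bias summaries;
* display rounding is **half-up to two decimals** (`round_half_up()`),
  matching the convention of published performance tables; raw values are
  always retained;
* stratified reports assign the stratum at the conversation/patient level
  (a patient attribute such as self-reported race cannot vary by turn), so
  strata partition the turns and per-stratum counts must sum to the
  overall counts — asserted, not assumed.

`sample_for_review()` draws the seeded random sample of misclassified
(FP, FN) and properly classified (TP) turns used for qualitative error
analysis, balancing across dataset labels by water-filling (as even as
pool sizes allow) and enforcing an optional per-patient cap; infeasible
requests fail with the binding constraint named. The randomization
mechanism behind any given published sample is unknowable, so the
package's contract is reproducibility under a stated seed, not
reproduction of a specific historical sample.

## The curation loop

Libraries are grown iteratively: extract the positive turns under a gold
standard, enumerate candidate words and n-grams (default up to trigrams —
long enough for "stool softeners" and "fuzzy brain"-style phrases) with
keyword-in-context examples, and record human include/exclude decisions in
an append-only triage log with rationale. `apply_triage()` replays a log
into a new library version whose diff against the old one is exactly the
logged inclusions. A small function-word stoplist applies to single-word
candidates only; phrases are never stoplisted, since function words inside
phrases can carry the symptom sense ("don't have the appetite"). The
default minimum candidate frequency is 1, i.e. review everything — the
conservative reading of a manual triage workflow.

The shipped `seed_lexicon()` (41 terms, 2 exclusions) combines colloquial
terms heard in clinic talk, medication names used to treat relevant
symptoms, and a-priori anchor terms so every PRO-CTCAE system category
group (pain, GI, sleep/wake, neurological, cutaneous, mood/anxiety,
respiratory, oral, sexual, other) is represented. It is a starting point
for local curation and a fixture for the generator — not a validated
instrument. A curated library at realistic scale (a thousand terms or
more) is loaded from file; `synthetic_library(n)` builds a
clearly-labelled synthetic stand-in at any size for exercising the loader
and matcher at that scale.

## The synthetic-conversation generator

Real oncology transcripts cannot ship with a package, so the generator
produces corpora in which every turn's ground truth is planted and known.
Four mechanisms, drawn per turn:

* **lexical** positive — a lexicon term slotted into a template sentence
  (always detectable);
* **colloquial** positive — a paraphrase containing no lexicon term
  (never detectable; models "newly encountered language");
* **decoy** negative — a phrase superficially resembling symptom talk
  (exam instructions, idioms); the default decoy list is disjoint from the
  seed lexicon, so decoys plant no false positives unless the user passes
  overlapping ones;
* **filler** negative — ordinary clinic talk.

The generator validates its own inventory against the lexicon it is given
(templates and fillers must not leak lexicon terms; paraphrases must not
match) and errors otherwise, so the planted labels are guaranteed exact.
Coder scores are derived from truth (3 for positives, 1 for decoys, 0 for
filler) with optional ±1 perturbation at rate ε truncated to 0–3; at
ε = 0 the broad gold standard binarizes exactly back to truth.
A configurable share of colloquial positives is marked outside the
PRO-CTCAE framework and emitted as focused-standard overrides.

Default parameters describe the regime the package is built to study: 31
conversations of 350–600 turns (≈15k turns, two conversations per patient
on average), 12% turn-level symptom prevalence, colloquial rate 0.49 (a
keyword library catches about half of broad symptom talk),
PRO-CTCAE-irrelevant share 0.72 among colloquial turns (most of what the
library misses is outside its framework — which is what makes the focused
standard score visibly higher than the broad one), ambiguity rate 0.10,
and a patient-stratum mix mirroring a minority-enriched test sample. These
are fixed modelling choices, stated here once; tests use smaller explicit
sizes (stated below) purely as problem-size choices.

Because the model is fully specified, expected performance has a closed
form (`expected_performance()`): with prevalence *p*, colloquial rate *c*,
ambiguity *a* and decoy-overlap fraction *d*, broad-standard sensitivity
is 1 − *c*, focused-standard sensitivity (1 − *c*)/(1 − *cq*), expected
false-positive mass (1 − *p*)·*a*·*d* (zero, hence precision 1, for
disjoint decoys). End-to-end tests generate ≈5,200 turns and require the
realized sensitivity within three binomial standard errors of the closed
form and precision exactly 1.

What the generator does **not** emulate: dialogue coherence, lexical
diversity beyond its template inventory, transcription noise,
misspellings, cross-turn symptom discussion, and coder biases more
structured than symmetric score perturbation. Passing the synthetic
recovery tests therefore demonstrates that the pipeline's arithmetic and
matching semantics are correct under a known generative model — not that
any particular library generalizes to real conversations. Performance
claims on real data require real annotated transcripts.

## Problem sizes used in the shipped checks

* matcher–oracle equivalence: 1,000 randomized (library, sentence) pairs,
  plus 200 in the unit suite;
* gold-threshold agreement: 200 randomized coder matrices;
* kappa: 50 random fully-crossed Fleiss tables against an independent
  closed form; two independent raters at n = 10,000 for the
  drift-to-zero check;
* end-to-end recovery: ≈5,250 turns; two-gold-standard gap: ≈2,300
  turns; metric identities: 10,000 random count vectors.

## Known limitations

* Literal matching cannot see negation, hypotheticals, or who a symptom
  belongs to; an exclusion list is the only contextual lever.
* The turn is the context window; conversationally distributed symptom
  talk is out of reach by design.
* The kappa default (Fleiss on binarized labels) is one defensible choice
  among several; published coefficients computed otherwise will differ.
* The seed lexicon is a fixture-scale starting point whose coverage is
  intentionally thin; all performance statements in this package's tests
  are about synthetic corpora.
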