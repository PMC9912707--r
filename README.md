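# symtalk

Rule-based detection of **symptom talk** in transcribed clinical
conversations.

Seriously ill patients voice symptoms constantly in clinic — "the nausea
has been rough", "I don't have the appetite", "do you need any more
Ativan?" — and much of it never reaches documentation. `symtalk` detects
such talk at the level of the **speaker turn** (an uninterrupted span of
speech) using a curated keyword library grounded in the PRO-CTCAE symptom
framework (the patient-reported version of the Common Terminology
Criteria for Adverse Events, ~80 clinically relevant cancer symptoms).
It is aimed at researchers who build, audit and evaluate such lexicons:
palliative-care and health-communication groups, clinical NLP developers
who need a transparent rule-based baseline, and annotation teams
maintaining turn-level gold standards.

## The method

A keyword library is a versioned set of literal lowercase terms — single
words or multi-word phrases, each sorted into one or more (nonexclusive)
symptom categories with provenance flags — plus *exclusion patterns*:
phrases whose occurrence suppresses any keyword match fully contained in
their span (the exam instruction "deep breaths" must not count as a
respiratory symptom). A turn is flagged when at least one unsuppressed
term matches at token boundaries, case-insensitively; no regular
expressions, stemming or fuzzy matching.

Turn-level gold standards come from coders scoring relevance 0–3: the
**broad** standard calls a turn positive when the mean score is ≥ 2
(closed bound), and a **PRO-CTCAE-focused** standard refines it through
an auditable manual-override sidecar. Detection crossed with a gold
standard yields TP/FP/TN/FN and the five standard metrics

    sensitivity = TP/(TP+FN)        specificity = TN/(TN+FP)
    precision   = TP/(TP+FP)        accuracy    = (TP+TN)/total
    F1          = 2TP/(2TP+FP+FN)

with stratified reporting, chance-corrected inter-rater agreement (Cohen,
Fleiss), seeded misclassification sampling for qualitative review, n-gram
candidate mining for the curation loop, and a synthetic-conversation
generator with planted ground truth so the whole pipeline is testable
without confidential transcripts.

## Worked example

```r
library(symtalk)

lib <- seed_lexicon()
lib
#> <keyword_library 'seed-0.1'>: 41 terms, 2 exclusions, 10 categories in use
#>   medication terms: 5

detect_turn("The nausea has been rough, and I don’t have the appetite.", lib)
#> <detection>: symptom talk (2 match(es), 0 suppressed)
#>   nausea [gi]
#>   appetite [gi]

detect_turn("Take a few deep breaths for me.", lib)
#> <detection>: no symptom talk (0 match(es), 0 suppressed)
```

The first turn is flagged through two gastrointestinal terms. The second
contains "breaths" language but lies inside the exam-context exclusion,
so nothing fires — the distinction between symptom description and
physical-exam instruction that plain substring search gets wrong.

Published turn-level confusion counts for a full-scale (1320-term)
library ship with the package; feeding them through the metric formulas
reproduces the published table:

```r
rc <- reference_confusion_counts()          # validation/test × 2 standards
performance_metrics(confusion_counts(rc$tp[4], rc$fp[4], rc$tn[4], rc$fn[4]))
#> <metric_set> (2 dp display, raw values retained)
#>   sensitivity 0.79
#>   specificity 0.99
#>   precision   0.85
#>   accuracy    0.97
#>   f1          0.82
```

End to end on a synthetic corpus with planted truth:

```r
cfg <- generator_config(n_conversations = 8,
                        turns_per_conversation = c(80, 120), seed = 42)
syn  <- generate_corpus(cfg)
det  <- detect_corpus(syn$corpus, lib)
gold <- build_broad_gold(syn$scores)
stratified_report(det, gold, standard = "broad")
#> <evaluation_report> vs broad gold standard
#> <confusion_counts>: TP 50  FP 0  TN 714  FN 49  (total 813)
#> <metric_set> (2 dp display, raw values retained)
#>   sensitivity 0.51
#>   specificity 1.00
#>   precision   1.00
#>   accuracy    0.94
#>   f1          0.67
```

Half the planted positives are colloquial paraphrases absent from the
lexicon ("things will just run through"), so sensitivity sits near 0.51
by construction while precision is perfect (the default decoy list is
disjoint from the lexicon). Applying the generated PRO-CTCAE overrides
and re-scoring against the focused standard lifts F1 from 0.67 to 0.86 —
the characteristic gap between what a framework-specific library misses
in *all* symptom talk versus in the talk it was built to find.

## Scope

The matcher is deliberately a transparent baseline: it cannot see
negation, cross-turn context or novel phrasings, and the shipped seed
lexicon is a starting point for local curation, not a validated
instrument. See the methods vignette
(`vignettes/symtalk-methods.Rmd`) for the model, parameter rationale,
numerical conventions and limitations.
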