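---
title: "Auto-coding radiology Impressions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auto-coding radiology Impressions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radcoder)
```

## The problem

Radiology reports end in an *Impression*: the summary section holding the
actionable diagnoses. Mapping each Impression finding to an ICD-10-CM code
would let imaging findings be tracked like any other clinical diagnosis,
but radiologists rarely code their own reports, and physicians who do code
agree with each other only moderately. `radcoder` implements a
transparent, deterministic auto-coder for neuroimaging Impressions
together with the validation machinery needed to measure such an engine
against a panel of human reviewers.

## The pipeline

**Segmentation.** The Impression section is located by heading
(`IMPRESSION`, `CONCLUSIONS`, `OPINION`, ... -- section phraseology varies
across dictation styles), split into its bulleted or numbered *lines*, and
each line into atomic *phrases*. Phrases split unconditionally at
semicolons and sentence boundaries, and at commas and the conjunctions
"and"/"with"/"as well as" only when both sides carry a finding-bearing
noun. The gate is deliberately conservative: "mass with surrounding soft
tissue" is one finding, while "degenerative change with disc bulge" is
two. The finding-bearing nouns are the pathology class of an editable
word-class lexicon (`radcoder_lexicon()`), since no canonical list of
"context identifiers" exists for dictated English.

**Normalization.** Phrases are case-folded; characters outside
`[A-Za-z0-9]` and whitespace are deleted (so "1.2 cm" survives as tokens
`12`, `cm`); light inflection reduction maps plurals to singulars while
leaving Latin singulars ("stenosis", "calculus") alone; and an editable
clinical synonym table maps surface variants ("bleed", "narrowing") to the
canonical vocabulary used by the catalog descriptions.

**Polarity.** Each phrase is positive, a *pertinent negative* (PNF), or
non-codable. A negation trigger ("no", "without", "free", "resolved", ...)
preceding a finding-bearing token marks a PNF; the negation scope is the
whole phrase rather than a fixed token window, which is correct once
phrases are atomic findings. A phrase made solely of normality terms and
stopwords ("Unremarkable examination") is non-codable -- the engine-side
analog of a reviewer's "no applicable code" verdict -- and emits no
candidates. PNFs still receive ranked candidates, flagged negative: "no
intracranial hemorrhage" is a *negative* assertion of the hemorrhage code.
Hedged findings ("cannot exclude infarct") default to positive; a
dedicated uncertainty polarity is out of scope.

**Matching.** Every catalog entry is scored against the phrase with

$$s = \Big[\sum_{t \in \text{shared}} \mathrm{idf}(t)^{a}\, w_{\text{class}}(t)\Big]
      \cdot \text{coverage}^{c} \cdot \text{align} \cdot \text{region},$$

where $\mathrm{idf}(t) = \ln\frac{1+N}{1+\mathrm{df}(t)} + 1$ uses the
term's document frequency over the catalog descriptions, $w_\text{class}$
up-weights pathologic (default 2.0) and anatomic (1.25) terms,
$\text{coverage}$ is the matched fraction of the description's tokens
(exponent 0.5 by default), $\text{align}$ is a bonus (1.2) when shared
tokens appear in the same relative order in phrase and description, and
$\text{region}$ multiplies by 1.5 / 0.6 when the exam's body region
matches / contradicts the entry's tagged regions (region-neutral entries
multiply by 1). The score is zero exactly when no token is shared, grows
with match length, and is unbounded above -- an odds-ratio-like weight,
not a probability. Candidates are ranked by score with lexicographic
code order as the deterministic tie-break; `k` defaults to 100, the
largest evaluated rank cutoff.

The multiplicative form and the default weights are this package's own
concrete design: they satisfy the qualitative requirements (word overlap,
corpus word frequency, phrase/description alignment, clinical word-class
weighting, body-part conditioning) and were fixed against the bundled
fixture corpus only. The region conditioning is why a bare "aneurysm" on
a head CT prefers the cerebral-aneurysm entry while the same phrase on a
neck CTA prefers the vertebral-artery one.

## Validation framework

**Ground truth by unanimity.** With no gold standard available, a
phrase's reference code exists only when all reviewers independently
selected the identical code at the comparison length $L \in \{3, 4, 7\}$
(dot excluded; 3 is the category level). Phrases unanimously judged
uncodable form their own class; everything else is "not unanimous".

**Confusion rules.** For each cell $(L, k)$, $k \in \{1,5,20,100\}$: a
unanimous-code phrase is TP when its truncated code appears among the
truncated top-$k$ candidates, else FN -- pure rank membership. Phrases
without an agreed code cannot be scored that way, so the engine's
confidence is thresholded: the *threshold match score* is the mean score
of the TP matches in that cell, and a non-unanimous phrase is FP when any
top-$k$ candidate scores at or above it, TN when all fall below. "At or
above" versus "below" makes the two classes exhaustive and exclusive.
Unanimous-no-code phrases are routed through the FP/TN rule by default
(`nocode_mode = "negative-pool"`) because the unanimity definition of
ground truth does not apply to them; `"exclude"` drops them instead, and
both modes are reported by the CLI. Note the deliberate asymmetry: the
threshold is derived from TP scores yet only affects FP/TN cells, so
sensitivity depends on rank membership alone and is monotone
non-decreasing in $k$.

**Metrics.** Sensitivity, specificity, precision, and
$F_2 = 5PR/(4P + R)$, which weights recall over precision -- appropriate
when missing a codable finding is costlier than over-suggesting. Cells
with no TPs have no threshold and are marked unavailable rather than
imputed. Two cells are compared with a two-proportion chi-square test
(continuity-corrected) on pooled correct versus incorrect
classifications; the test is this package's choice, as the comparison
procedure has no canonical name in the validation literature.

**Reliability.** Reviewer agreement is measured two ways, mirroring the
two decisions a reviewer makes: Cohen's kappa (pairs) or Fleiss' kappa
(3+ raters) on the *binary* applicability verdict (is there any
applicable code?), and nominal Krippendorff's alpha on the *specific*
verdict, with no-code as its own category, at each comparison length.
The statistics are implemented from their defining formulas and are
tested against brute-force pair-enumeration oracles to 1e-12; alpha has
no missing-data handling because the study design has every reviewer
answering every phrase. Significance for alpha, when requested, comes
from a seeded phrase-level bootstrap (1,000 resamples by default) --
Krippendorff gives no closed-form test at these panel sizes. Percent
exact agreement is monotone non-increasing in $L$ by construction;
chance-corrected kappa/alpha are exempt from that guarantee because the
chance term also shifts with $L$.

## The synthetic corpus

Real neuroimaging reports cannot be redistributed, so the generator
(`generate_reports()`) emulates the *shape* of the reference corpus: exam
types and patient settings drawn from the bundled mix tables (200 reports,
heavily weighted to noncontrast head CT and brain MR), a phrase count per
report over 1..6 with mean 3.22 (matching the 645-phrase/200-report
corpus), a 4.8 % non-codable rate, and a 20 % pertinent-negative rate --
the last is not recorded in any reference table and was fixed once as a
realistic figure for neuroimaging Impressions. Phrase surfaces are
derived from catalog descriptions with filler words dropped, optional
severity modifiers and measurements, and occasional synonym swaps that
normalization must undo; entries whose description carries no pathology
noun (device-presence codes) are always planted positive, since "No
ventriculoperitoneal shunt" is not a pertinent negative a radiologist
would dictate. Reviewer panels (`simulate_reviewers()`) pick the planted
code with probability `p_correct`, a same-category distractor otherwise,
and a spurious no-code verdict with probability `p_nocode_error`; with the
error rate at zero, panel unanimity occurs at exactly `p_correct^m`,
which the tests recover within binomial confidence limits.

What the generator does *not* emulate: dictation disfluencies, findings
absent from the 74-entry catalog, the long-tail candidate lists of a full
ICD-10-CM database (tens of thousands of entries versus 74), or
inter-reviewer bias structure. Passing the end-to-end benchmark therefore
demonstrates internal consistency of the pipeline on solvable inputs, not
clinical-grade accuracy: the top-5 category-level sensitivity target of
at least 0.85 on the clean-template corpus (evaluated under an imperfect
panel with `p_correct = 0.9`, `p_nocode_error = 0.02`, so that FP/TN
cells are exercised) is an engineering bar, not a reproduction of any
published engine's performance.

## Numerical and design notes

* **Catalog fixture.** The bundled catalog carries the 74 full-length
  unanimity codes with hand-written, synthetic plain-English descriptions
  (flagged as such in the file header). The three bundled unanimity lists
  (60 / 74 / 74 codes at lengths 3 / 4 / 7) are *separate* sets: the
  full-length codes truncate into 67 distinct length-4 codes, a proper
  subset of the 74-item length-4 list, because unanimity can hold at a
  short length without holding at full length. The tests assert the
  subset relation and both cardinalities.
* **Code grammar** is permissive (letter + 2 alphanumerics + up to 4
  alphanumerics) rather than the full ICD-10-CM character-class rules, so
  placeholder codes like `S06.2X9A` validate; the typeset multiplication
  glyph sometimes found in such codes is normalized to the placeholder
  letter `X`.
* **Determinism.** Generators are pure functions of their seed;
  `code_corpus()` output is byte-identical across runs; ranking ties
  break lexicographically.
* **Degenerate inputs.** Punctuation-only lines become a single phrase
  with no tokens (non-codable); kappa/alpha return `NaN` with a warning
  when the chance denominator vanishes (single category ever used), but
  complete agreement returns exactly 1; metric ratios of 0/0 are reported
  as 0 with a warning; undefined thresholds mark their grid cell
  unavailable instead of aborting the run.
* **Problem sizes in the shipped checks.** The test suite evaluates the
  statistics oracles on 1,000 randomized panels of up to 10 phrases,
  matcher-oracle equivalence on 50 fixture phrases, grid invariants on
  100 simulated evaluations, parameter recovery at 500-600 phrases, and
  the end-to-end benchmark on a 200-report corpus -- the scale of the
  reference study.

## Limitations

The matcher is a bag-of-words ranker over a small curated catalog: it has
no learned embeddings, no terminology service, and no uncertainty
polarity. The lexicon, synonym, and region tables ship as small editable
defaults tuned to craniospinal imaging; other body parts need extended
tables. Agreement statistics assume complete annotation (no missing
verdicts). The evaluation inherits the unanimity definition's
conservatism: phrases with partial reviewer agreement contribute only to
the FP/TN pool, and the threshold's circularity (derived from TP scores)
is retained by design rather than resolved.
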