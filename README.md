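# radcoder

Automated ICD-10-CM coding of radiology report Impressions, with the
validation framework needed to measure an auto-coder against panels of
physician reviewers.

Radiology reports summarize their actionable diagnoses in the Impression
section, but those diagnoses almost never become ICD-10 codes: radiologists
rarely code their own reports, and physicians who do code agree with each
other only moderately. `radcoder` implements a transparent, deterministic
auto-coder for neuroimaging Impressions — section extraction, line and
phrase segmentation, normalization with clinical synonyms, pertinent-
negative (negation) polarity, and a contextual bag-of-words matcher — plus
the evaluation side: unanimity ground truth, threshold-based confusion
classification, sensitivity/specificity/F2 grids, and inter-rater
reliability statistics (Cohen and Fleiss kappa, Krippendorff alpha).

## The match score

Every catalog diagnosis *d* is scored against a phrase's normalized tokens:

    s(phrase, d) = [ Σ_{t ∈ shared} idf(t)^a · w_class(t) ]
                   · coverage^c · align · region

with `idf(t) = ln((1+N)/(1+df(t))) + 1` over the catalog descriptions,
class weights that up-weight pathologic and anatomic terms, `coverage` the
matched fraction of the description's tokens, an `align` bonus when shared
tokens keep their relative order, and a `region` multiplier conditioning on
the exam's body part (so a bare "aneurysm" on a head CT prefers the
cerebral-aneurysm code, on a neck CTA the vertebral-artery one). The score
is zero iff no token is shared, unbounded above, and odds-ratio-like rather
than probabilistic; candidates are ranked by score with deterministic
lexicographic tie-breaks.

Validation compares codes at lengths 3 (category), 4, and 7 characters
(dot removed) and rank cutoffs 1, 5, 20, 100. A phrase with a unanimous
reviewer code is a TP when that code appears among the top-k candidates;
phrases without unanimity are split into FP/TN by a threshold equal to the
mean TP match score of the cell.

## Worked example

```r
library(radcoder)
catalog <- radcoder_catalog()   # 74-entry bundled fixture catalog

report <- paste(
  "EXAM: CT Head w/o Contrast",
  "FINDINGS: Described below.",
  "",
  "IMPRESSION:",
  "1. Mass of left temporal lobe measuring 1.2 cm.",
  "2. Ischemic changes; no acute intracranial hemorrhage.",
  "3. Unremarkable examination otherwise.",
  sep = "\n")
corpus <- data.frame(report_id = "R0001", text = report, modality = "CT",
                     body_region = "head", contrast = "without",
                     setting = "emergency")
matches <- code_corpus(corpus, catalog, quiet = TRUE)
subset(matches, rank <= 2,
       select = c(phrase_id, rank, code, score, polarity, raw_text))
```

```
   phrase_id rank   code score polarity                                    raw_text
 R0001-L1-P1    1   R220 33.13 positive Mass of left temporal lobe measuring 1.2 cm
 R0001-L1-P1    2 I63512  4.43 positive Mass of left temporal lobe measuring 1.2 cm
 R0001-L2-P1    1   G931  6.80 positive                            Ischemic changes
 R0001-L2-P2    1   I629 15.69 negative            no acute intracranial hemorrhage
 R0001-L2-P2    2   I609  7.33 negative            no acute intracranial hemorrhage
```

Line 1 becomes one positive phrase whose best match is R22.0 ("localized
mass of head, temporal lobe") with a score far above the runner-up. Line 2
splits at the semicolon into a positive phrase and a pertinent negative:
"no acute intracranial hemorrhage" is *negatively* asserted hemorrhage
(I62.9), ranked but flagged `negative`. Line 3 is a bare normality
statement — non-codable, so it emits no candidates and would map to a
reviewer's "no applicable code" verdict.

The validation side runs off reviewer annotations:

```r
syn <- generate_reports(corpus_config(seed = 1))          # 200 synthetic reports
matches <- code_corpus(syn$corpus, catalog)
ann <- simulate_reviewers(syn$truth, reviewer_panel_config(seed = 2))
evaluate_grid(matches, ann)      # 3 lengths x 4 rank cutoffs
agreement_report(ann)            # kappa + alpha per reviewer subset
```

A command-line entry point wrapping the same functions is installed at
`system.file("cli", "radcoder", package = "radcoder")` with subcommands
`code`, `agreement`, `evaluate`, and `gen-fixtures`.

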