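# aeval

Evaluation and retrieval toolkit for automated analysis of medical-device
adverse-event reports, with infant incubators (a class III neonatal
device) as the worked domain.

When a language model extracts structure from an adverse-event narrative
— when the event happened, what the device did wrong, what staff did
about it — standard text-generation metrics say little about whether the
clinically load-bearing content survived. `aeval` implements the
specialised scoring stack used for this problem, the statistics that
calibrate it against blinded expert raters, and desk-scale harnesses for
the two model-adaptation mechanisms such pipelines rely on
(parameter-efficient dual-adapter fine-tuning and supervised contrastive
retrieval fine-tuning), together with a clause-aware
retrieval-augmented-generation scaffold that audits answers for citation
discipline. Because real monitoring-system data are confidential, seeded
synthetic generators produce every input with exact ground truth
attached, so the whole stack is testable offline.

It is aimed at people building or reviewing report-analysis pipelines in
pharmacovigilance: the metrics are reusable for any report schema with
core/secondary fields, and every component is plain R with no model
weights or services required.

## The scoring model

A report is described by three **core** fields (occurrence date,
abnormal condition, follow-up measures; weight 1.0), two **secondary**
fields (failure cause, triggered risk; weight 0.8), and one
supplementary field. Matching of a reference element against a
prediction is hierarchical: an **exact** match if the normalized
reference text is contained in the prediction, otherwise a **fuzzy**
match iff the edit-distance similarity ratio

    sim(a, b) = 1 − Levenshtein(a, b) / max(|a|, |b|)

strictly exceeds 0.8.

**Element recall rate (ERR)** is the mean over reports of the fraction
of the three core elements recovered:

    ERR = (1/|K|) Σ_{k∈K} I( match(E_k_ref, E_k_pred) ),  |K| = 3

**IDIAE** (Information Density Index of Adverse Events) scores a whole
answer: weighted coverage of the five required fields divided by a
denominator inflated by the correction factor

    β = 1 + α·(N_red / 10) + γ·M_error,   α = 0.1, γ = 0.2

where `N_red` counts irrelevant characters and `M_error` near-miss
terminology errors. With the default weight-sum normalization a complete,
clean answer scores exactly 1. The α/γ defaults are the pair recovered by
the package's own grid-search calibration against simulated expert
scores (`grid_search_weights()`, validated with a two-way random-effects
absolute-agreement ICC, Pearson r, and Cohen's κ). **Risk recall**
counts coverage of a six-item core safety list, so a mean of 5.52
identified items corresponds to a recall of 0.92.

The adapter harness exercises, on a micro-transformer, low-rank
adaptation `W → W + B·A` on attention query/value projections plus an
activation-scaling vector `l` on feed-forward activations, trained in
two stages (LoRA first, then frozen-LoRA + (IA)³) under a 3:1
domain:general weighted objective. The retrieval embedder is fine-tuned
with the InfoNCE objective

    L = −(1/N) Σ_i log[ e^{sim(q_i,p_i⁺)/τ} / (e^{sim(q_i,p_i⁺)/τ} + Σ_k e^{sim(q_i,p_ik⁻)/τ}) ],  τ = 0.15

## Worked example

```r
library(aeval)

gen <- gen_reports(report_gen_spec(n_reports = 6,
  dropout = setNames(rep(0.3, 5), element_schema()$required),
  redundancy_rate = 12, term_error_rate = 0.5, seed = 7))
score_reports(gen$references, gen$predictions,
              ground_truth = gen$ground_truth)
#>  report_id   err idiae beta n_red m_error
#>      R0001 0.333 0.332 1.18    18   0.000
#>      R0002 1.000 0.631 1.31    11   1.000
#>      R0003 0.667 0.607 1.29     9   1.000
#>      R0004 0.667 0.580 1.35    15   1.000
#>      R0005 1.000 0.763 1.31    11   1.000
#>      R0006 0.667 0.476 1.28     8   1.000
#>    summary 0.722 0.565 1.29    12   0.833
```

Each row is one report: `err` is the fraction of the three core
elements the prediction recovered (report R0001 lost two of them to the
30% field dropout), `idiae` the density index after the β penalty for
the injected junk characters and terminology typos, and the `summary`
row holds the corpus means. Per-report detail is available directly:

```r
idiae(gen$references[[2]], gen$predictions[[2]],
      n_red = gen$ground_truth$n_red[2],
      m_error = gen$ground_truth$m_error[2])
#> <idiae_breakdown R0002> score 0.6306 (coverage 4/5, beta 1.310, N_red 11, M_error 1)

split_dataset(as.character(1:4095), seed = 1)
#> <ae_split> 4095 items over 4095 reports: train=2457, test=1229, validation=409
```

A command-line wrapper ships in `inst/cli/aeval`
(`simulate`, `score`, `split`, `calibrate`, `chunk`, `ask`, `audit`,
`train-adapters`, `train-embedder`, `report`); see `aeval --help`.

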