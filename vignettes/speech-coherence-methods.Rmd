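---
title: "Methods: referential structure, arrival dynamics and semantic coherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: referential structure, arrival dynamics and semantic coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Speech coherence in psychosis-spectrum research is quantified along three
largely separate dimensions: (i) the *referential* structure of noun
phrases (NPs) — how determiners, case marking, anaphora and pro-drop null
subjects establish and track referents; (ii) *distributional-semantic*
structure — cosine similarity between embeddings of adjacent words, and
the alignment between a picture and the text describing it; and (iii)
*predictability* — the pseudo-perplexity of the token stream under a
masked language model. `refcoh` implements a joint pipeline for all three
on picture-elicited narrations, together with the inference layer needed
to relate them, for corpora of Turkish-style pro-drop speech annotated
with morphosyntactic features. Because clinical transcripts are not
freely redistributable, the package ships a synthetic-corpus generator
with the same statistical structure, so every stage is exercised end to
end by code alone.

# The referential taxonomy

Tokens carry explicit features (`determiner`, `case`, `plural`, `lemma`,
verb `agreement_subject`), so classification is deterministic and
language-neutral at the data level. `classify_np()` applies a fixed
cascade to each NP span:

1. **null subject** — empty token range anchored at a verb bearing
   subject agreement (pro-drop);
2. **lexical pronoun**;
3. determiner phrases: **indefinite DP** (indefiniteness markers such as
   *bir* "a/one") and **definite DP** (demonstratives such as *bu*
   "this");
4. bare NPs, in order: **anaphoric** (head lemma already mentioned in the
   same narration, or an explicit annotator flag — the flag overrides the
   lemma match in both directions), **specific** (accusative or other
   specificity-inducing case), **indefinite** (plural morphology:
   quantification over a set), **generic** (annotator flag), and the
   total fallback **bare-residual**.

Design choices that were genuinely open:

* *Anaphoricity proxy.* Real annotation judges anaphora semantically; the
  testable automatic surrogate is head-lemma identity within the
  narration. An optional manual flag overrides it, and the registry of
  mentioned lemmas resets at every picture boundary, since narrations are
  independent one-minute descriptions.
* *Genericity and referential anomalies are inputs, not inferences.* Both
  require context or world knowledge (a generic NP can even carry case
  morphology), so they enter as annotator-supplied flags and are passed
  through and counted, never detected.
* *Definiteness aggregates.* "All definite" defaults to definite DP +
  bare anaphoric + bare specific; "all indefinite" to indefinite DP +
  bare indefinite. Null subjects and lexical pronouns are modelled
  separately, and the rare generic class is excluded; both compositions
  are arguments of `aggregate_definiteness()`.

Inter-rater reliability is summarised by Cohen's kappa,
`(po - pe) / (1 - pe)` with chance agreement from the raters' marginals.

# Arrival dynamics over narrative time

For the four macro-types frequent enough to test (definite DP, indefinite
DP, bare indefinite, bare-residual), the package treats occurrences as a
point process over token indices. The inter-occurrence *gap* is the
difference of successive head-token indices within one narration — the
convention under which gaps telescope to the span between first and last
occurrence; gaps never cross narration boundaries. A narrative that
introduces referents with indefinites and picks them up later with
definites should *not* be memoryless, so the null hypothesis of interest
is exponential gaps (a Poisson arrival process).

`exponentiality_test()` estimates the rate as `1/mean(gap)` and offers
two Monte-Carlo procedures:

* **two-sample fraction** — the empirical gaps are compared by two-sample
  Kolmogorov–Smirnov tests against each of `n_sim` simulated exponential
  samples matched in size and rate; the fraction of comparisons
  significant at `alpha` is reported. Near `alpha` under the null,
  towards 1 for clearly non-exponential data; the decision rule rejects
  above a configurable majority threshold (0.5 by default).
* **lilliefors_mc** (primary) — the one-sample KS statistic against the
  fitted exponential is referred to its simulated null distribution with
  the rate re-estimated inside every replicate, which properly accounts
  for the estimated parameter; `mc_p` is the fraction of simulated
  statistics at least as large as the observed one.

Both are computed by default; the `method` argument selects which one
decides `rejected`. `n_sim` defaults to 100,000, the full-scale setting;
the packaged tests and pipeline default run at 500–2,000 replicates, with
Monte-Carlo tolerances chosen accordingly. Tests with fewer than
`min_gaps` (default 8) gaps return an explicit "insufficient occurrences"
result rather than a p-value. Ties from integer gaps use the standard
tied KS statistic; a seeded uniform jitter on (-0.5, 0.5) is available
and off by default.

Calibration, verified in the test suite: under i.i.d. exponential gaps
(n = 200, 2,000 replicate tests at 1,000 null draws each) the
lilliefors_mc rejection rate at the 5% level stays within [0.035,
0.065]; under a gamma(shape 3) renewal of equal mean, power exceeds the
level and grows from n = 50 to n = 200.

**A representation limitation worth knowing.** Corpus-derived gaps are
whole token indices observed in finite narration windows. At large pooled
sample sizes the KS test resolves the discretization and the
finite-window deficit of long gaps themselves, so the corpus-level
rejection rate under a true exponential renewal sits slightly above the
nominal level (we measured roughly 0.08–0.12 across generator settings),
even though the i.i.d.-gap calibration is exact. Conclusions from
corpus-level non-rejections are conservative; conclusions from
rejections at very large pooled n should be checked against the jittered
variant and sparser aggregation.

# Semantic metrics

All embedding-based metrics sit behind a provider contract: a function
set mapping token surfaces to embeddings, token probabilities, and image
ids to vectors, deterministic given the input and model identity. The
shipped `stub_provider()` is a hash-based deterministic double used by
tests and pipeline runs; adapters for real masked-LM and image-text
models plug in behind the same contract without touching any metric code.

* **Consecutive-cosine similarity** `(1/(n-1)) * sum cos(e_i, e_{i+1})`,
  computed after removing punctuation and stop words — this
  preprocessing applies *only* to the similarity path; the referential
  and perplexity analyses always see the full stream. A
  `with_stopwords = TRUE` variant reproduces the robustness check with
  function words retained. The metric operates on whitespace tokens by
  default; subword granularity is a provider concern. A small default
  Turkish stop-word list ships as a plain-text fixture; it is a
  convenience, not a canonical list.
* **Pseudo-perplexity** `exp(mean(-log p_i))` with natural logarithms
  (fixed, documented), equivalently the inverse geometric mean of the
  token probabilities; lower is more predictable.
* **Image-to-text similarity** — mean cosine between one image embedding
  and the text-unit embeddings of its description, aggregated per
  participant downstream.

Zero-norm vectors are rejected rather than coerced; a single-token
similarity input returns `NA` ("undefined"), not an error.

# The inference layer

* **Poisson rate regression with offset** (`poisson_glm_offset()`):
  counts per narration with `log(words)` as a fixed offset, so
  coefficients are log incidence-rate differences relative to the
  reference group (NC). Fitting is iteratively reweighted least squares
  with convergence at a maximum coefficient update below 1e-10 (at most
  100 iterations); the score equations `X'(y - mu) = 0` are verified to
  1e-8 in the tests, and the fit agrees with `stats::glm` to the same
  order. Quasi-separation (an all-zero category in a group) is flagged
  at |B| > 10 and reported with a warning and a diverged estimate rather
  than silently penalised, since that is what the rate tables of this
  literature print. Covariates (age, education) are centered on the
  analysis sample; model comparison is by likelihood ratio and AIC.
* **GEE, Gaussian family, identity link, exchangeable working
  correlation** (`gee_gaussian_exchangeable()`): moment estimate of the
  working correlation from Pearson residual cross-products, dispersion
  by the Pearson estimator, robust sandwich covariance, tolerance 1e-8,
  at most 50 iterations. With all clusters of size one it reduces to
  ordinary least squares exactly. The Gaussian deviance GOF is reported
  against a supplied or known noise scale; against the fit's own
  dispersion the ratio is 1 by construction, so the default call is a
  scale report, not a test.
* **Spearman partial correlation**: ranks, residualisation on ranked
  covariates, t-approximate p with `n - 2 - k` degrees of freedom.
* **FDR**: Benjamini–Hochberg step-up q-values via `stats::p.adjust`,
  validated against a brute-force implementation in the tests. Within
  each fitted outcome the correction family is the non-intercept
  coefficients; the family partition is configurable because reasonable
  analysts draw it differently.

# The synthetic generator

`generator_config()` defaults encode the study conditions the analysis
assumes: four groups of 34/53/64/39 participants (NC/FEP/UHR/FHP), four
narrations each, negative-binomial word counts (mean 250, sd ≈ 90,
floor 40), per-word NP base rates equal to the exponentiated
neurotypical intercepts of the rate models (e.g. ≈ 0.077 for indefinite
DPs, ≈ 0.049 for definite DPs), and group multipliers reproducing the
reported contrasts: definite DPs in FEP at ≈ 0.7 of the control rate,
more bare-residuals in FEP, fewer lexical pronouns in UHR, and raised
referential-anomaly rates in all clinical groups (×3.5/×2.4/×1.9).
Arrival processes are i.i.d.-gap renewals because the scientific
null/alternative is exactly exponential vs non-exponential
inter-arrivals: definite and indefinite DPs default to gamma(shape 3)
gaps (regular, memory-bearing), except FEP indefinite DPs, which revert
to exponential — the memoryless pattern the pipeline is built to detect.
Positions are floored to integer token indices with collision re-draw to
the next free slot. Embedding streams use a spherical autoregression
whose expected consecutive cosine equals the mixing parameter; group
means (0.45–0.55) put the clinical groups above controls. Probability
streams draw token surprisal from a positive-truncated normal with equal
group means, matching the absence of group differences in predictability.

What the generator does *not* emulate: real lexical content and topical
structure, utterance segmentation, annotator disagreement, punctuation
and disfluency noise (punctuation-bearing fixtures are hand-built in the
tests), correlations between word count and NP rates, and any
symptom-scale structure. Passing tests therefore demonstrate that the
machinery measures what it claims on data with the assumed statistical
structure — not that the clinical effects themselves are recoverable
from any particular real corpus.

Worked scales used by the packaged checks (chosen to keep a full run in
minutes on one core): level calibration at 2,000 replicate tests ×
1,000 null draws; rate-ratio recovery over 200 corpora of 200
participants; GEE recovery over 40 replicates of 200 clusters × 4. The
rate-ratio recovery experiment generates the tested category from the
exponential renewal, because Wald-interval coverage is a Poisson-count
property: under the gamma-renewal default the counts are under-dispersed
and intervals over-cover by construction.

# Pipeline and reproducibility

`run_pipeline()` executes simulate → annotate → dynamics → semantics →
fit → report, each stage writing plain CSV/JSONL files so any stage can
be re-run or replaced independently, plus a JSON manifest with the
config hash, per-file checksums and record counts. All randomness flows
from named seeds in the run config (per-stage seeds are derived
deterministically), so identical configs give identical checksums, and
two pipelines in one process cannot interfere. A failed stage leaves
completed outputs in place and records the failure in the manifest.

# Known limitations

* Anaphora-by-lemma misses pronoun-mediated and bridging reference;
  coreference resolution is out of scope.
* The corpus-level memorylessness test inherits the integer-position and
  finite-window effects described above.
* GEE small-sample corrections are not implemented; with few clusters,
  sandwich standard errors are anti-conservative.
* The deviance GOF for Gaussian GEE is only informative against an
  external noise scale.
* The stub provider carries no linguistic knowledge; metric values on
  real language require real model adapters behind the provider
  contract.
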