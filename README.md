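# refcoh

Referential structure and semantic coherence metrics for narrative speech.

## What this is for

Discourse coherence in psychosis-spectrum research is measured along
three dimensions that are rarely analysed together: the **referential
structure** of noun phrases (how determiners, case marking, anaphora and
pro-drop null subjects introduce and track referents), **embedding-based
semantics** (cosine similarity between adjacent word embeddings, and the
alignment between a picture and the speech describing it), and
**predictability** (masked-language-model pseudo-perplexity). `refcoh`
implements a joint, fully testable pipeline for all three on
picture-elicited narrations annotated with morphosyntactic features,
aimed at computational psycholinguists and clinical-language researchers
working with pro-drop languages such as Turkish.

The core quantities:

* NP taxonomy over feature-annotated spans — indefinite/definite DPs,
  bare anaphoric/specific/indefinite/generic/residual NPs, null
  subjects, lexical pronouns — plus annotator-flagged referential
  anomalies and Cohen's κ for inter-rater reliability.
* Arrival dynamics of the four frequent macro-types over narrative time:
  inter-occurrence gaps g_i between successive head-token indices, their
  mean distance, and a Monte-Carlo Kolmogorov–Smirnov test of the
  memorylessness null g ~ Exp(λ̂), λ̂ = 1/mean(g), with the rate
  re-estimated inside every null replicate (Lilliefors construction) or,
  alternatively, the fraction of significant two-sample KS comparisons
  against simulated exponential samples matched in size and λ.
* Semantic similarity (1/(n−1)) Σ cos(e_i, e_{i+1}) on the
  punctuation/stop-word-filtered token stream; pseudo-perplexity
  exp((1/n) Σ −log P(w_i | context)); image-to-text mean cosine — all
  behind a deterministic provider contract with a shipped stub.
* Inference: Poisson rate regression with a log word-count offset
  (IRLS, quasi-separation flagging), Gaussian GEE with exchangeable
  working correlation and sandwich errors, Spearman partial correlation,
  and Benjamini–Hochberg FDR.
* A synthetic-corpus generator reproducing the group structure, renewal
  arrival processes, word-count dispersion, covariates and embedding
  streams that the analysis assumes, so the whole pipeline runs without
  access to clinical transcripts.

## Worked example

```r
library(refcoh)

cfg    <- generator_config(groups = c(NC = 20L, FEP = 20L,
                                      UHR = 20L, FHP = 20L))
corpus <- simulate_corpus(cfg, seed = 42)
counts <- corpus_counts(corpus)

X   <- design_matrix(counts, covariates = c("age", "education"))
fit <- poisson_glm_offset(counts$definite_dp, log(counts$words), X)
fit
#> <poisson_fit> log-rate model with offset, 6 coefficients, 320 observations
#>                   B     Se        z      p      q
#> (Intercept) -3.0234 0.0375 -80.5579 0.0000     NA
#> groupFEP    -0.4172 0.0575  -7.2613 0.0000 0.0000
#> groupUHR    -0.0217 0.0551  -0.3947 0.6930 0.8663
#> groupFHP    -0.1231 0.0509  -2.4162 0.0157 0.0392
#> age_c        0.0027 0.0039   0.7023 0.4825 0.8041
#> education_c -0.0012 0.0076  -0.1617 0.8715 0.8715
```

The intercept is the log incidence rate of definite DPs per word in the
reference group (exp(−3.02) ≈ 0.049 per word); `groupFEP` says the FEP
group's rate is exp(−0.42) ≈ 0.66 of that, a reliable reduction after
FDR correction (q column), while age and education contribute nothing —
exactly the structure the generator was configured with.

```r
nc   <- corpus$annotations[vapply(corpus$annotations, `[[`, "", "group") == "NC"]
gaps <- inter_occurrence_gaps(lapply(nc, occurrence_positions,
                                     macro = "indefinite_dp"))
mean_distance(gaps)
#> [1] 13.07496
exponentiality_test(gaps, n_sim = 2000, seed = 7,
                    methods = "lilliefors_mc")
#> <arrival_test> lilliefors_mc, n_gaps = 1374, lambda_hat = 0.0765
#>   lilliefors_mc:       mc_p = 0.0000
#>   rejected: TRUE
```

Control-group indefinite DPs recur every ~13 tokens on average, and the
memorylessness null is firmly rejected: their arrivals are generated by
a regular (gamma) renewal, as expected when narratives introduce
referents and later pick them up.

```r
E <- simulate_embedding_stream(n = 1000, dim = 32, rho = 0.5, seed = 3)
consecutive_cosine_similarity(E)
#> [1] 0.4876087
pseudo_perplexity(simulate_probability_stream(1000, log(10), 0.5, seed = 4))
#> [1] 9.829333
```

The measured consecutive cosine tracks the stream's mixing parameter
(0.49 for ρ = 0.5), and a surprisal stream centered at log 10 yields a
pseudo-perplexity near 10.

End-to-end runs with per-stage CSV outputs and a checksum manifest:

```r
rc <- run_config(simulation = cfg, seed = 1, n_sim = 2000)
run_pipeline(rc, "run1")
report_run("run1")   # group means/SDs, coefficient tables, arrival tests
```

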