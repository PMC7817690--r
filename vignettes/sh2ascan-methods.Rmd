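---
title: "sh2ascan: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sh2ascan: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sh2ascan)
```

# Scope and model

`sh2ascan` analyzes aberrant expression of the short histone H2A
variants (sH2As) in tumor cohorts. The package consumes gene-level TPM
matrices, Psi tables, MAF-like mutation calls, and gapped protein
alignments; it does not estimate expression or Psi from reads, and it
does not retrieve data from any portal.

The core quantities:

* **Reactivation status.** For each (sample, paralogue) pair, status is
  *positive* iff TPM > τ⁺, *negative* iff TPM < τ⁻, otherwise
  *intermediate*. Both inequalities are strict, so a sample at exactly
  τ⁺ = 1.5 TPM is intermediate. Intermediates are excluded from
  differential comparisons (their group membership is genuinely
  ambiguous) but kept in frequency denominators, since a reported
  "percentage of tumors" refers to all tumors of a type. The positive
  set depends only on τ⁺, a property the tests assert.
* **Mann–Whitney U.** All group comparisons use the rank-sum test. For
  tie-free data with `choose(n1+n2, n1) < 1e5` the exact permutation
  null of U is computed by the Gaussian-binomial counting recursion;
  otherwise a normal approximation with mid-ranks, tie-corrected
  variance, and a continuity correction is used (matching
  `wilcox.test(exact = FALSE, correct = TRUE)`). Under complete ties the
  variance is zero and p is defined as 1: identical data carry no
  evidence. Exact p-values are bounded below by 1/C(n, n1), so p ∈ (0, 1].
* **Differential expression.** Fold change is computed on group mean
  TPM with a pseudocount ε: FC = (mean⁺ + ε)/(mean⁻ + ε), ε = 0.1 TPM
  by default. The direction call is composite: *up* iff FC > 1.19 and
  p < α (symmetric for *down*). No multiple-testing correction is
  applied by default — the downstream summaries (concordance, common
  gene sets) consume raw p-values — but `adjust = "BH"` is available.
* **CTA score.** Within each cancer type, over tumor samples only:
  log2(TPM + 1) per CTA gene; rank genes by the sample variance
  (ddof = 1) of log expression; keep the top k = 40 with positive
  variance (zero-variance genes are excluded rather than dividing by
  zero); Z-normalize each kept gene; score each sample by the sum of
  its Z-scores. Scores therefore sum to exactly zero within a type, and
  are invariant to per-gene multiplicative TPM rescaling. Groups are
  compared with a one-sided (positive-greater) Mann–Whitney test.
* **Differential splicing.** ΔPsi is the difference of group means of
  non-missing Psi (medians via a flag; the choice is not dictated by
  any convention we know of, and means match how the per-event summary
  is usually plotted). The one-sided test direction follows the sign
  of ΔPsi, and an event is called only if p < 0.05 *and* |ΔPsi| > 0.1.
  The conjunction makes the procedure conservative on null data, which
  the acceptance suite verifies. Events with fewer than 5 non-missing
  values in either group are reported untested, not silently dropped.
  For TandemUTR (APA) events Psi is the proximal-site usage fraction,
  so reduced proximal usage appears as negative ΔPsi.
* **TMM normalization.** Scaling factors come from the trimmed mean of
  per-gene log2 ratios (M) of library-size-normalized values,
  restricted to coding genes, after trimming 30% from each end by M
  and 5% by average log-abundance (A); genes zero in either sample are
  excluded; factors are rescaled to geometric mean 1. Precision
  weighting (as in count-based TMM) is available but **off by
  default**: binomial precision weights assume count sampling noise
  that TPM values do not carry, and they break the desirable
  invariance of factors to uniform per-sample rescaling. The test
  suite cross-checks the weighted path against edgeR on a fixed-scale
  matrix.
* **Oncohistone mapping.** Protein positions are 1-based on the
  ungapped canonical sequence (standard histone numbering: R29, E121).
  A canonical position maps through the gapped↔ungapped coordinate
  maps (mutual inverses, property-tested) to an alignment column; the
  variant's residue there either matches the oncomutation's alternate
  residue, differs, is an internal gap, or — when the variant has only
  gaps from that column through the alignment's C-terminal end — is
  reported `TRUNCATED`. Requiring gaps to the end distinguishes a
  truncation from an internal deletion. The canonical record must
  carry the stated reference residue at each queried position; a
  mismatch errors immediately, which catches mis-numbered mutation
  catalogues.
* **Recurrence rule.** A protein change is recurrent iff it occurs at
  least 5 times pooled across all genes of a histone class and across
  all cancer types (so ten E121Q events spread over different
  canonical H2A genes count as one recurrent change with count 10).

# The synthetic cohort generator

The source study analyzes real cohorts and specifies no generative
model, so every distributional choice here is ours, made once and
documented:

* **Background expression** is log-normal per gene: meanlog ~
  N(log 10, 1.2) (median gene ≈ 10 TPM, heavy-tailed across genes),
  sdlog ~ U(0.25, 0.5) (25–55% biological CV across tumors of a type,
  typical for expressed genes). Per-gene scale is drawn once per
  cohort so variance ranking for CTA top-k selection is meaningful.
* **Reactivation** is Bernoulli per tumor (default fraction 0.1).
  A reactivated tumor expresses H2AFB1 alone (50%), H2AFB2+H2AFB3
  (40%), or all three (10%) — mirroring the observation that H2AFB1
  reactivates independently while the near-identical H2AFB2/3 pair
  co-occurs. Expressed paralogues draw TPM log-normally around a
  median of 3 (sdlog 0.5), truncated below at 1.6 TPM; silent
  paralogues get sparse dropout noise strictly below 0.5 TPM. The
  truncation and the dropout ceiling keep the planted world cleanly
  classifiable (recall and precision exactly 1), so the intermediate
  band is populated only if a user configures it — by design, the
  generator states a world rather than tuning one.
* **Psi** is Beta(μκ, (1−μ)κ) with κ = 20 (SD ≤ 0.11, matching
  MISO-style posterior spread at moderate coverage). Baselines are
  uniform on [0.05, 0.95] for alternative classes and [0.90, 0.99]
  for constitutive events. Planted events shift μ by ΔPsi in
  reactivated samples; planted baselines are drawn so μ + ΔPsi stays
  inside [0.05, 0.95], making the realized mean shift equal the
  planted one. Cells go missing independently at rate 0.05.
  Constitutive events are never planted unless explicitly listed.
* **CTA effect**: affected CTA genes (default half of them) shift
  their log expression by `cta_effect_sd` gene-SD units in reactivated
  samples. **DE genes** shift multiplicatively by `de_fold_change`.
* **Mutations** are sprinkled per sample × pool-gene at rate 0.01 with
  random substitutions, plus a configurable recurrent hotspot
  (default: ten E121Q events across canonical H2A genes).

What the generator does **not** emulate: gene–gene correlation beyond
the planted effects, batch structure, purity variation, read-mapping
ambiguity between H2AFB2 and H2AFB3, and realistic per-event coverage
differences in Psi. A green test therefore establishes that the
statistics behave correctly in a known world — not that any biological
conclusion from real cohorts is reproduced. In particular the study's
headline frequencies (e.g. half of DLBCLs) and common-gene counts
depend on controlled-access data and are out of reach by design.

# Numerical and policy choices

* log2(TPM + 1) wherever "log expression" is needed; the base and
  pseudocount are conventions, stated rather than inherited.
* Sample statistics use ddof = 1 throughout.
* Exact Mann–Whitney two-sided p = min(1, 2·min(P(U ≤ u), P(U ≥ u))).
* The expressed-gene universe for expression percentiles defaults to
  median TPM > 0 across the chosen samples ("expressed" is otherwise
  undefined); the rule is a function argument. Percentile rank uses
  mid-ranks scaled to [0, 100] with the extremes at 0 and 100.
* Cross-cancer common genes: *up* requires an *up* call in at least
  `min_types` types (default: half, rounded up) and *down* in none.
  The policy is parameterized because no canonical rule exists; the
  output is monotone non-increasing in `min_types`.
* Frequencies report positives over all tumors of a type, including
  intermediates; a flag-free alternative denominator is a one-line
  filter upstream.
* Gene identity is keyed on `gene_id`; symbols are display-only.
  Coordinates are 1-based inclusive and never converted implicitly.
* Missing Psi is an empty TSV field and NA in memory — never zero,
  which is a valid biological value.
* The shipped gene-class catalogue seeds the canonical H2A/H2B
  replication-coupled gene sets; the lymphoma-subtype panels in it are
  editable placeholders (the authoritative panel memberships are not
  enumerated in our sources) and are data, not code.
* The packaged alignment fixture is synthetic (names suffixed
  `_synthetic`): a canonical core-H2A record with R29/E56/E92/E121 at
  their standard mature-protein positions, and an H2A.B-like record
  carrying R29Q, an internal deletion, and a C-terminal truncation
  that removes E121.

# Reproducibility

`simulate_cohort` seeds R's RNG from its config and restores the
caller's RNG state afterwards; identical seeds give byte-identical
cohorts, which the CLI's checksummed outputs verify. Every CLI stage
writes a provenance JSON (config, seed, package and R versions, input
checksums) sufficient to re-run it.

# Known limitations

* The Mann–Whitney exact path refuses ties rather than computing the
  (expensive) exact conditional distribution; tied data use the
  tie-corrected approximation even at small n.
* TMM assumes most genes are not differentially expressed between
  samples; cohorts violating that (global amplification) need external
  spike-in anchoring, which is out of scope.
* `differential_splicing` treats events independently; no event-level
  FDR is applied by default, consistent with the composite-threshold
  convention it implements.
* The CLI's `diffexp` groups pool across cancer types; per-type runs
  are available through the R API (`differential_expression` over
  per-type sample sets) and are what `cross_cancer_common_genes`
  expects.
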