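---
title: "Sparse genotype storage and per-variant regression: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse genotype storage and per-variant regression: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spgwas)
```

# The problem

In population-scale sequencing panels nearly all discovered variants are
rare. Two costs scale badly with cohort size n as a consequence: storing a
genotype matrix at fixed width wastes its bytes on hom-ref calls, and
running one regression per variant rebuilds and refactorizes an n × p
design millions of times to estimate a single new coefficient each time.
`spgwas` attacks both: genotypes live in a container whose rare-variant
records cost O(k) bytes for k carriers, and the regression engines do O(k)
or O(p(k+p)) work per variant on top of quantities computed once per scan.

# The storage model

Genotypes are additive alt-allele counts with a missing sentinel: 0
hom-ref, 1 het, 2 hom-alt, 3 missing — 2-bit packable, and arithmetic-
friendly (the code *is* the dosage for nonmissing calls). Each variant is
stored in one of two record types:

* **dense (type 0)**: `ceiling(n/4)` bytes, 2 bits per sample in sample
  order, little-endian within each byte;
* **sparse difflist (type 1)**: `varint(k)`, then k LEB128 varints of
  0-based sample indices (first absolute, the rest as gaps from the
  previous index), then `ceiling(k/4)` bytes of 2-bit codes in entry
  order.

`choose_encoding()` computes both sizes from closed forms and takes the
smaller, ties going to the branch-free dense decoder. Delta-encoding keeps
index varints short even deep into the cohort: a lone het at sample
399 999 of 400 000 costs 1 (count) + 3 (index) + 1 (codes) = 5 bytes.

Three choices here deserve justification:

* **Missing calls are difflist entries.** The residualized engine needs the
  positions of missing genotypes to downdate its sums; storing codes 1, 2
  *and* 3 in the difflist lets it do so in O(k) without densifying.
  The cost — monomorphic-but-partially-missing variants carry entries — is
  negligible at realistic missingness (~0.2%).
* **No minor-allele flipping.** When ALT happens to be the major allele the
  difflist is large and the encoder simply falls back to dense. Flipping
  would complicate effect-sign bookkeeping for a size win that a
  rare-variant panel rarely needs.
* **1-based indices in memory, 0-based on disk.** R-side records use R's
  native indexing; the serialized format uses 0-based indices. Conversion
  happens only inside the codec.

The container (`.spg`) is little-endian throughout: a 12-byte header
(magic `SPG1`, n_samples, n_variants as uint32), a 4-byte index entry per
variant (1 byte record type + 24-bit body length), then the bodies at
offsets given by the cumulative lengths. Variant metadata (CHROM POS ID
REF ALT, biallelic only) and sample IDs live in `.pvar`/`.psam`-style TSV
sidecars. Reads validate the magic and the index/body length arithmetic;
any mismatch is a classed `spgwas_corrupt_store` error. VCF import takes
hard GT calls only; half-calls and haploid GTs become missing, multiallelic
records are skipped with a warning (splitting them is upstream work for
`bcftools norm`).

# The regression kernel

With the design written as the block matrix `X = (Xc x_g)`,

$$X^TX = \begin{pmatrix} A & B \\ B^T & D \end{pmatrix},
\quad A = X_c^TX_c,\; B = X_c^Tx_g,\; D = x_g^Tx_g,$$

the kernel precomputes `A`, `A^{-1}`, `X_c^Ty` and `y^Ty` before the
variant loop (`precompute_covariates()`; multiple phenotypes sharing a
sample set are handled columnwise in one pass). Per variant,
`sparse_cross_products()` accumulates `B`, `D` and `x_g^Ty` over the k
difflist entries, and `block_complete_inverse()` finishes
$(X^TX)^{-1}$ with the Schur complement $F = D - B^TA^{-1}B$ via the 2×2
block-inverse identity. `RSS = y^Ty - (X^Ty)^T\hat\beta$, and the genotype
SE/t/p are the usual Wald quantities with a Student-t reference on
`n − p` degrees of freedom (at biobank n the t vs normal distinction is
negligible; t is exact under Gaussian errors at any n, so the simulator's
null scans calibrate exactly).

Numerical guards:

* **Collinearity of covariates** is detected at precompute time by QR rank
  and a condition-number estimate (bound 1e12), reporting the offending
  columns by name.
* **Degenerate genotypes** (constant, or in the covariate span) surface as
  `F ≤ f_tol` with the *relative* tolerance `f_tol = 1e-10 × D`, which is
  scale-free; the engines catch the classed condition and emit a
  `DEGENERATE` row rather than aborting a scan.
* **Perfect fits** (RSS = 0) report p = 0 with a flag; p-values are floored
  at `5e-324` (the smallest positive double) rather than rounded to 0.

The sparse path requires a record with no missing calls; the standard
engine routes variants that carry missing genotypes (or are dense-encoded,
or have k > n/8, where the O(kp) path loses its advantage — the format
itself does not fix a cutover, so one had to be chosen) to a dense
complete-case QR fit. `dense_ols_fit()` doubles as the brute-force oracle
in the tests; the suite asserts sparse ≡ dense to 1e-8 relative on β̂, SE
and p across thousands of simulated rare variants.

# The residualized mode

Refitting 18 covariates per variant is wasted work when the covariates are
the same for every variant. `qt_residualize` fits each phenotype on the
covariates once, then tests every variant against the residuals with an
intercept + genotype model (p = 2). At p = 2 missing genotypes stop being
expensive: with whole-sample sums `n`, `Σe`, `Σe²` precomputed, each
missing call *subtracts* its sample's contribution (downdating), and
carrier terms accumulate `Σg`, `Σg²`, `Σge`; the 2×2 normal equations are
then solved in closed form. All O(k), straight off the difflist.

The price is a mild model misspecification: the per-variant model has
`n − 2` residual degrees of freedom and does not re-orthogonalize the
genotype against the covariates among the complete cases. With covariates
independent of genotype the two modes agree essentially perfectly (the
acceptance suite demands R² > 0.999 and slope within 1% on −log₁₀ p at
n = 2000, m = 5000 — observed R² ≈ 0.999996); under genotype–covariate
confounding the residualized estimate is biased toward the marginal
effect, which is inherent to the construction, not an implementation
artifact. Each phenotype is residualized over its own complete cases; in
the standard mode, phenotypes are instead grouped by identical missingness
pattern so each group shares one precompute, which keeps joint
multi-phenotype runs row-for-row identical to single-phenotype runs.

# Case-control scans

`logistic_newton()` is a plain Newton–Raphson maximizer of the logistic
log-likelihood with a fixed per-sample offset and step-halving; it stops
when the largest score component falls below 1e-8 (max 25 iterations) and
declares divergence when any coefficient passes 40 on the logit scale.
`firth_fit()` maximizes the Jeffreys-penalized likelihood — the score is
corrected by the hat-value term $h_i(1/2-\mu_i)$ — which keeps estimates
finite under the separation that rare variants produce constantly (max 50
iterations; step-halving on the penalized likelihood).

`firth_fallback_assoc()` fits the full model per variant and refits with
Firth when the ordinary fit fails to converge *or* lands beyond |β| = 40.
One caveat the tests make explicit: under *one-sided* separation (all
carriers are cases but controls are mixed) the likelihood is monotone in
β_g yet the score can fall below tolerance at a finite, large β̂ with an
enormous SE — a quasi-converged boundary fit that any score-based stopping
rule accepts. Such rows carry noise-level p ≈ 1 in every implementation;
comparisons between modes are therefore evaluated where the MLE exists.

`cc_residualize_assoc()` is the case-control analog of residualization:
the covariate-only model is fit **once** (with the Firth penalty — robust
to quasi-separation in the covariates), its linear predictor is frozen as
a per-sample offset, and each variant gets a 2-parameter intercept +
genotype fit on top of it. The per-variant cost is a 2-column Newton
iteration: the intercept update shifts every sample's weight, so the
whole-sample sums must be refreshed each iteration — O(n) vectorized work
with a tiny constant rather than O(k); an exactly-O(k) update does not
exist for this model. With an all-zero offset the mode reduces exactly to
the no-covariate full fit, which the tests assert to 1e-6. Where a variant
is strongly confounded with a covariate the frozen offset misses the
genotype's effect on the covariate adjustment and the two modes disagree
detectably — the test suite constructs such a variant and asserts the
disagreement, because it is a property of the method a user should know,
not a defect. Concordance between the modes is asserted at rank
correlation > 0.95 over variants with MAC ≥ 10; below that the Wald
p-values being compared are boundary-fit noise in both modes (see above),
and their rank order is meaningless.

# Multi-phenotype SVD

Deep phenotype panels are heavily correlated. `pheno_svd()` restricts to
complete rows (component scores cannot be defined for rows with missing
entries without imputation, which is out of scope), centers columns,
takes the thin SVD and keeps the smallest rank r whose cumulative squared
singular values reach the variance-explained threshold. Scores are
`U_r S_r`; since association t-statistics are invariant to phenotype
scaling, the `U_r` vs `U_r S_r` choice affects only reported effect sizes,
and `U_r S_r` keeps scores on the phenotypes' scale. Columns are *not*
variance-standardized by default — centering is the minimal SVD
prerequisite and standardization is a modeling decision the caller can
opt into (`standardize = TRUE`); with phenotypes on wildly different
scales the unstandardized SVD is dominated by the largest-variance column,
which is sometimes exactly what is wanted and sometimes not.

The degenerate panel of 50 identical columns collapses to r = 1 at any
threshold and its component scan reproduces the single-trait t-statistics
to 1e-8 — the suite asserts this 50-fold shortcut end to end. Component
associations are only interpretable jointly with the loadings table, which
`run_glm_components()` therefore always returns alongside.

# The synthetic panel generator

The generator emulates the marginal structure of a biobank exome panel,
with every draw seeded:

* **MAF spectrum**: Beta(0.08, 1), truncated to `[1/(2n), 0.5]` — a heavy
  rare tail under which ~69% of variants fall below 1% MAF
  (`0.01^0.08 ≈ 0.692`) and, at n = 2000, over 80% of records land in the
  sparse encoding, so the storage and compute paths under test are the
  ones that dominate real panels.
* **Genotypes**: Hardy–Weinberg `Binomial(2, MAF)`, i.i.d. across samples
  and variants. No LD, relatedness or population structure — per-variant
  regression correctness is LD-agnostic, so passing tests speak to the
  estimator, not to multi-variant phenomena (fine-mapping, clumping,
  genomic control) which this package does not do.
* **Missingness**: completely at random at rate 0.002. The downdate path
  is pattern-agnostic and is tested against arbitrary patterns; MCAR is
  only the generator's default, not an engine assumption.
* **Covariates**: one binary sex, one age ~ N(55, 8), the rest standard
  normal PC-like columns (18 by default, the covariate count typical of
  large-cohort GWAS).
* **Phenotypes**: `y = Xcγ + Σ βⱼ gⱼ + ε` with γ ~ N(0, 0.05²),
  β ~ N(0, 0.5²) on a default 1% of variants, ε ~ N(0, 1); missing
  genotypes contribute their expectation 2·MAF so the recorded truth stays
  well defined. Binary traits use the same linear predictor through a
  logistic link with the intercept solved by root-finding so realized
  prevalence hits the target within ±1% at n ≥ 4000.

Truth tables (per-variant MAF and effects, covariate effects, solved
intercept) are returned and written as JSON by the CLI, sufficient to
score bias and coverage without re-deriving anything.

# Problem sizes in the test suite

The suite exercises the engines at n = 2000, m = 5000 for the linear-mode
concordance and null-calibration checks, n = 2000 with 18 covariates and
1200+ variants for sparse-vs-dense oracle equivalence, n = 4000, m = 2000
for the case-control mode comparison, and 200 seeded replicates
(n = 800, m = 40) for planted-effect recovery at the 3-SE level. These
sizes make every statistical property measurable with comfortable margins
while keeping a full run at a few minutes on one CPU; the estimators'
costs are linear in n and m, so nothing about the implementation is
specific to these scales.

# Known limitations

* Hard calls only: no dosages, no phase, no multiallelics (conversion
  upstream), and no exact binary compatibility with other containers.
* Wald inference only for binary traits; no likelihood-ratio or
  saddlepoint p-values, so ultra-rare case-control variants keep Wald's
  known conservatism — filter by MAC or read the METHOD column.
* The residualized modes trade exactness under confounding for speed, as
  quantified above; use the standard/full modes when covariate–genotype
  correlation is plausible.
* Single-threaded: `--threads` is accepted for pipeline compatibility and
  validated, but execution order (hence output) never depends on it.
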