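---
title: "Pan-genome kernels, REML and genomic prediction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-genome kernels, REML and genomic prediction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panblup)
```

## The problem

In panels of sequenced microbial isolates, SNPs are not the only — and often
not the best — genome-wide description of heritable variation. The
pan-genome adds two further layers: which ORFs an isolate carries at all
(presence/absence), and in how many copies. Because ORF variation is itself
gene-level variation, a relationship kernel built from it can tag causal
variation that common SNPs miss when linkage disequilibrium between markers
and causal sites is weak — the "still missing heritability" problem.
`panblup` makes the three layers interchangeable inputs to one estimation
and prediction machinery so that their contributions can be compared on
equal footing.

## Models and estimation

Every BLUP-family model here is `y = 1*mu + g (+ h) + e` with one or two
genetic random effects whose covariances are relationship kernels:

* SNP kernel `G = ZZ'/(2*sum(p*(1-p)))`, dosages centered at `2p`. The
  0/1/2 code is oriented to count the **minor** allele before centering;
  without this orientation, centering at twice the minor allele frequency
  is inconsistent for markers where the stored dosage counts the major
  allele. The `counted_allele` attribute kept by `read_vcf()` lets users
  recover the original orientation.
* ORF kernel `O = WW'/sum(q*(1-q))`, presence centered at the frequency
  `q`. Core ORFs (`q = 1`) contribute zero to numerator and denominator, so
  keeping or dropping them changes nothing downstream; the frequency filter
  therefore removes only rare ORFs.
* CNO kernel `C = SS'/f`, copy numbers centered at the column mean, `f` the
  median diagonal of `SS'` — which forces `median(diag(C)) = 1` exactly and
  makes the variance component scale comparable across traits.

Monomorphic columns are silently zero-weight rather than rejected; an error
is raised only when *every* column is weightless (zero denominator).

REML uses average-information updates with two safeguards: step halving
whenever a proposed update would lower the restricted log-likelihood, and an
EM step (guaranteed monotone) when the AI system is singular or halving
fails. The accepted log-likelihood trace is stored on the fit, and the
non-decreasing property is asserted in the test suite. Negative component
proposals are projected onto the boundary (set to zero) so heritability
always lands in [0, 1]; the residual component keeps a floor of `1e-8 *
var(y)` so the covariance stays invertible — if it is estimated at that
boundary, heritability is reported as ~1 with a degenerate-fit warning.
Convergence requires both a relative log-likelihood change below `tol`
(default 1e-8) and component stability below 1e-6 relative change. Standard
errors come from the inverse AI matrix; heritability SEs by the delta
method on that matrix. A kernel numerically proportional to the identity is
flagged: its component cannot be separated from the residual.

Single-kernel fits are solved in the kernel's eigenbasis, where every
functional reduces to sums over eigenvalues (O(n) per iteration after one
decomposition); `kernel_eigen()` attaches a reusable decomposition for
workflows that refit many phenotypes on one isolate panel. Two-kernel fits
use the dense representation. If the covariance fails to factorize, a
one-time diagonal boost of `1e-6 * mean(diag)` is applied and logged.

Kernel frequencies (`p`, `q`, column means) are computed on the full
analysis set, not per cross-validation fold: fold-wise frequencies would
change the kernel under every replicate and conflate kernel estimation
noise with prediction error.

## Prediction and evaluation

Out-of-sample genetic values use the standard BLUP predictor
`g_test = Gamma[test, train] V_train^-1 (y_train - mu)` with
`Gamma = sum_j sigma_j^2 K_j`. On the SNP layer this is algebraically
identical to ridge regression on centered dosages with
`lambda = sigma_e^2 / sigma_u^2`, `sigma_u^2 = sigma_g^2 / (2*sum(p*(1-p)))`
— asserted to 1e-6 in the tests as a standing regression check.

Predictive ability is the Pearson correlation between predicted genetic
values and observed phenotypes in held-out folds of a replicated k-fold
cross-validation (default 20 replicates of 5-fold, i.e. a mean over 100
fold estimates; correlations are averaged per fold, not pooled). Variance
components are re-estimated inside every training fold — the statistically
clean choice, though analyses that reuse whole-data variance components
would report slightly different values. Fold assignment is drawn over
isolates in sorted-id order, which makes the result invariant to the input
order of the data. Two conventions matter in degenerate folds: a fold whose
*phenotypes* are constant carries no information and is skipped with a
warning; a fold whose *predictions* are constant (the genetic component was
estimated at the zero boundary, so every prediction equals the mean) is
scored r = 0, since a constant predictor has no predictive ability —
leaving such folds out would discard exactly the folds that demonstrate a
null signal.

The training-size response is summarized by the deterministic accuracy
curve `r(n) = w * sqrt(n h2 / (n h2 + Me))`, fitted by maximum likelihood
under i.i.d. Gaussian residuals with a free variance — equivalent to
nonlinear least squares. `Me` is optimized on the log scale and the
optimizer is multistarted from a coarse grid (`w` in 0.2–1.4, `Me` in
{50, 200, 1000, 3000}) because the objective has a flat ridge when the
observed range of `n` constrains the asymptote weakly; exactly that
pathology produces fits with `w > 1` on real data, which are flagged
(`outlier_flag`) rather than rejected, since the flagged value is itself
informative.

## Bayes A/B

The whole-genome regression `y = 1*mu + X a + e` gives every centered
predictor column its own effect variance with a scaled-inverse-chi-square
prior (`nu = 5`, `S = 0.002`). Bayes B adds a point mass at zero; we take
`pi = 0.05` to be the prior probability of a **nonzero** effect — the
sparse-architecture reading — and expose it as `pi_nonzero` so the
complementary convention is one argument away. The indicator is sampled
jointly with its effect by integrating the effect out of the two-state
comparison, which avoids the stuck-chain behavior of naive Gibbs on a point
mass; at `pi_nonzero = 1` the sampler reduces exactly to Bayes A (same RNG
stream, identical draws). The residual variance gets a weakly informative
scaled-inverse-chi-square prior (`nu_e = 4`, scale `var(y)/2`). Default
chain settings are 50,000 iterations with 45,000 burn-in; the validation
suite runs 800–3,000-iteration chains with correspondingly widened
tolerances, which is sufficient because the checks there are structural
(determinism, model collapse, prior recovery) rather than
posterior-precision claims. The inner loop is compiled (Rcpp) and draws all
randomness from R's RNG, so every fit is reproducible under a seed.

One direction worth recording: a *larger* prior scale `nu*S` means larger
prior effect variances and therefore *less* shrinkage of the posterior
effects; the test suite asserts that effects shrink toward zero as the
scale decreases.

## QC filters

SNP markers pass three sequential criteria — missing rate ≤ 0.05, minor
allele frequency ≥ 0.01, Hardy–Weinberg equilibrium at p ≥ 1e-6 by a 1-df
chi-square test against expected counts `n*(p^2, 2pq, q^2)` — each applied
to the survivors of the previous one; this order is fixed for
reproducibility. ORFs are filtered only on the rare side (presence
frequency < 0.05), keeping core ORFs. Copy-number columns have no standard
frequency notion, so we define it as the fraction of isolates whose copy
number differs from the column's modal value, which captures "how variable
is this column" with a single number. Remaining missing SNP calls are
imputed by sampling from each marker's observed genotype-frequency
distribution under a fixed seed — deliberately LD-free, adequate for the
low missing rates left after filtering, and a documented divergence from
haplotype-aware imputers.

## The simulator

`simulate_population()` generates the three layers with the features that
matter for validating this machinery: a rare-skewed site-frequency spectrum
(allele frequencies from Beta(0.15, 4), putting roughly 88% of minor allele
frequencies below 0.1, emulating deep population panels where the vast
majority of SNPs are rare); a pan-genome of core ORFs plus variable ORFs
with presence frequencies uniform on (0.05, 0.95); and copy numbers that
are zero exactly where an ORF is absent, mostly 1–2 where present, with
rare amplifications bounded at 296. Layers are generated independently by
default — the conservative choice when no generative model for their
dependence is established — and an optional `linkage` parameter couples ORF
presence to a local SNP score (logistic model) for experiments that need
cross-layer LD. `simulate_phenotype()` places N(0,1) effects on a chosen
layer and scales the residuals so the realized in-sample heritability
equals the target *exactly*, which makes parameter-recovery tests sharp
rather than hostage to sampling error in the generative step.

What passing tests on these simulations do **not** show: real pan-genomes
have population structure, LD blocks, correlated layers (copy number
amplifications sit on specific haplotypes), and non-Gaussian phenotypes.
Results on simulated data validate the estimation machinery, not the
biological claims one would make from a real panel.

## Problem sizes and numerical choices

The validation suite runs at deliberately chosen desk-scale sizes:
heritability recovery on an n = 500 panel with 100 phenotype replicates per
true h2 in {0.2, 0.5, 0.8} (mean recovered within ±0.05); two-kernel
attribution at n = 500 over 15 replicates; cross-validation properties at
n = 150–300; Bayes chains of 800–3,000 iterations (plus a 100,000-iteration
thinned chain for the prior-conformance check, where the residual variance
is pinned so the sampler's stationary distribution is the prior itself);
kernel oracles on ≤ 12 × 30 matrices against brute-force double loops at
1e-12. The acceptance script uses a 400-isolate population with an
ORF-borne trait at heritability 0.6, 20×5-fold CV for kernel models and 5
replicates for the Gibbs models.

Other numerical conventions: kernels are not bent to strict positive
semi-definiteness (eigenvalues down to −1e-8 of the largest are accepted);
NJ trees delegate to the standard Saitou–Nei implementation in `ape`
(negative branch lengths clamped to zero with the deficit logged); PCA is
the SVD of the centered matrix; the two gene-distance metrics (locus
count-difference, the pairwise convention of `ape::dist.gene`, and plain
Euclidean) are both provided because the two are used interchangeably in
practice even though they differ on dosage data — count-difference is the
default.

## Known limitations

Single fixed effect only (the overall mean): covariates must be
pre-regressed out. No multi-trait models, no dominance or epistasis
kernels, no stratified cross-validation. The Bayes sampler reports posterior
means and inclusion probabilities but no convergence diagnostics beyond the
seed-determinism guarantee. The imputer ignores LD by design. Aneuploid
isolates should be removed upstream; the copy-number reader warns on values
≥ 297 (outside the range this toolkit was designed around) but does not
clip them.
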