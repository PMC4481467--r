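---
title: "Functional linear mixed models for region-based association in families"
author: "regflm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional linear mixed models for region-based association in families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Single-variant association tests are underpowered for rare variants, so
rare-variant studies test all variants of a genomic region jointly.
Burden tests collapse the region into one score and lose power when
effects point in different directions; kernel (SKAT-type) tests use only
pairwise genotype similarity.  Functional data analysis (FDA) treats the
genotypes of a region, ordered by physical position, as discrete
observations of a continuous *genetic variant function* (GVF), and the
per-variant effects as a continuous *beta-smoothing function* (BSF).
This uses the positions, the order and the linkage disequilibrium (LD)
of the variants, not just their identities.  `regflm` implements this
regional test for samples of *related* individuals — pedigrees, isolated
populations, biobanks with cryptic relatedness — by embedding the
functional design in a linear mixed model with a polygenic random
effect.

## The model

For $n$ individuals with trait $y$, covariates $X$ ($n \times c$,
including the intercept) and regional dosages $G$ ($n \times m$, minor
allele counts at positions scaled to $[0,1]$), the baseline mixed model
is

$$y = X\alpha + G\beta + h + e, \qquad
h \sim N(0, \sigma_h^2 R), \quad e \sim N(0, \sigma_e^2 I),$$

where $R$ is the relationship matrix (twice the kinship matrix, so
founders give $R = I$) and $\Omega = \sigma_h^2 R + \sigma_e^2 I$.  The
functional model replaces $G\beta$ by a smoothed design:

* genotype smoothing: $\tilde G(t) = G\,\Phi(\Phi^\top\Phi)^{-1}\varphi(t)$,
  with $\Phi$ the $m \times K_G$ evaluation matrix of the GVF basis at
  the scaled positions;
* effect smoothing: $\tilde\beta(t) = \psi^\top(t)\beta_F$ with $K_\beta$
  coefficients.

Substituting both gives $y = X\alpha + GW\beta_F + h + e$ with
$W = \Phi(\Phi^\top\Phi)^{-1} W_2$ and
$W_2 = \int_0^1 \varphi(t)\psi^\top(t)\,dt$; using the BSF only gives
$W = \Psi$, the direct evaluation matrix of the BSF basis.  Six model
labels name the basis combinations: `B-B`, `0-B`, `F-B`, `B-F`, `0-F`,
`F-F`, where the first letter is the GVF basis (B-spline, Fourier, or
`0` for none) and the second the BSF basis.

Two basis families are provided: cubic B-splines on equally spaced knots
($K$ functions imply $K-4$ interior knots) and the orthonormal Fourier
system $\{1, \sqrt2\sin 2\pi kt, \sqrt2\cos 2\pi kt\}$ ($K$ odd).  $W_2$
is computed by composite Gauss–Legendre quadrature (20 nodes per knot
interval), which is exact for the polynomial factors and resolves the
trigonometric factors far below $10^{-10}$ for $K \le 25$.

## Testing

The null hypothesis is $\beta_F = 0$.  $\alpha$ and $\Omega$ are
estimated once per phenotype by maximum likelihood under the null
(`flmm_null()`), via the eigendecomposition $R = UDU^\top$: after
rotating by $U^\top$, the likelihood is profiled analytically over
$\alpha$ and the total variance, and the heritability
$h^2 = \sigma_h^2/(\sigma_h^2+\sigma_e^2)$ is found by bounded
one-dimensional search on $[0, 1-10^{-6}]$ (tolerance $10^{-8}$;
boundary solutions accepted; REML available via `reml = TRUE` for
sensitivity checks).  The same eigendecomposition then makes every
regional test cheap: whitening by $D_\Omega^{-1/2}U^\top$ turns
$\Omega^{-1}$-weighted sums of squares into ordinary ones.

With $\Omega$ fixed at its null estimate, the regional statistics are

$$F = \frac{(RSS_0 - RSS_1)/r}{RSS_1/(n - r - 1)}, \qquad
LRT = n\log(RSS_0/RSS_1), \qquad
\text{score} = U^\top V^{-1} U = RSS_0 - RSS_1,$$

where $RSS_0$ is the weighted null residual sum of squares, $RSS_1$ the
weighted residual sum after fitting $\beta_F$ by generalised least
squares, and $r$ the effective rank of the whitened regional design
(pivoted QR, relative tolerance $10^{-8}$; duplicated or collinear
genotype patterns reduce $r$, never crash or inflate the degrees of
freedom).  $F$ is referred to $F(r, n-r-1)$, the other two to
$\chi^2_r$.

**Joint estimation of $\alpha$ under the alternative.**  The package
orthogonalises the smoothed design against $X$ in the whitened metric
before fitting $\beta_F$, which is algebraically identical to
re-estimating $\alpha$ jointly with $\beta_F$ (with $\Omega$ still held
at the null fit).  The alternative — holding $\alpha$ completely fixed —
makes the $F$ numerator $\lVert P_Z(I-P_X)\varepsilon\rVert^2$ with
expectation $r - \mathrm{tr}(P_Z P_X) < r$, i.e. a measurably
conservative test (empirically ≈0.040 at $\alpha=0.05$ on our
calibration sample even with $\Omega$ known), because the leading,
burden-like column of $GW$ overlaps the intercept.  With the joint form
and intercept-only covariates the null $F$ statistic is *exactly*
$F(r, n-r-1)$ when $\Omega$ is known, which the test suite verifies by a
Kolmogorov–Smirnov test on $10^4$ simulated draws.  The score-test
variance uses the projection that accounts for $\alpha$-estimation; in
the whitened, orthogonalised coordinates it collapses to
$RSS_0 - RSS_1$.

**Degrees of freedom.**  The denominator df is $n - r - 1$, without
subtracting the covariate count; `df_conservative = TRUE` switches to
$n - r - c - 1$.  With an intercept only the two coincide.

## Automatic basis reduction

Estimating $\beta_F$ requires $m \ge K_G \ge K_\beta$.  Requested basis
counts (defaults: 15 B-spline, 25 Fourier) are reduced per region:

* each $K$ is capped at $m$; a Fourier $K$ is rounded down to odd;
* a B-spline basis cannot drop below $K = 4$, so for $m < 4$ any model
  involving a B-spline basis falls back to the *saturated* design — the
  ordinary multiple-regression LMM on the raw dosages; $m = 1$ always
  falls back to the single-variant Wald test;
* when a GVF basis is present, $K_\beta \le K_G$ is enforced.

Two degeneracies of evaluation matrices are handled explicitly:

1. *Fourier endpoint congruence.*  The Fourier system is 1-periodic and
   the scaled positions always contain both 0 and 1, which are congruent
   points: a Fourier evaluation matrix at $m$ positions has at most
   $m-1$ independent rows.  `eval_basis()` evaluates $t=1$ exactly as
   $t=0$, so at $K = m$ the rank drop is deterministic: a `0-F` design
   carries $m-1$ df, and a Fourier GVF is reduced below $m$ until
   $\Phi^\top\Phi$ is well conditioned.  Consequently the classical
   "$K = m$ reduces to the saturated LMM" identity holds exactly for
   `B-B`, `0-B` and `B-F` (whose Fourier side enters only through the
   nonsingular cross-integral $W_2$), and is unattainable for `F-B`,
   `0-F` and `F-F` under the $[0,1]$ scaling convention.  The test suite
   asserts both facts.
2. *Schoenberg–Whitney violations.*  A B-spline collocation matrix can
   be singular at unfavourable position layouts even for $K_G \le m$.
   The regional test then lowers $K_G$ until $\Phi^\top\Phi$ is well
   conditioned (saturated fallback at the floor) and records the
   reduction in the result's `note` column; `build_basis_matrices()`
   retains the hard error for callers that want it.

Positions are scaled affinely to $[0,1]$; a single variant maps to 0.5;
runs of duplicated coordinates are spread evenly between their
neighbours' scaled values (order-preserving) because evaluation matrices
need distinct points and silently dropping variants would change $m$.

## The simulator

`sim_scenario()` fixes the study conditions; its defaults emulate the
family sample of a mini-exome study:

* **Pedigrees** — 8 three-generation families of 86 (founder couple,
  7 children with married-in spouses, 10 grandchildren per couple),
  688 individuals in total, emulating a 697-member, 8-family sample.
* **Genotypes** — per region, $H = 600$ founder haplotypes are drawn
  from a site-frequency spectrum and assigned to pedigree founders;
  whole haplotypes are gene-dropped without recombination (regions are
  gene-sized), which creates within-region LD through shared founder
  haplotypes and identity-by-descent.  Monomorphic sites are redrawn, so
  the realized spectrum is conditioned on polymorphism.  The spectrum is
  a calibrated mixture — 90% rare Beta(0.08, 150) truncated to
  $[3\times10^{-4}, 0.35]$, 10% common Uniform(0.02, 0.35) — chosen so
  the *sample* MAF spectrum matches the study's printed one: median
  ≈ 1% (test band 0.5–2%), about two thirds of variants below 3%, range
  reaching ≈ 35%.  A single Beta (for instance Beta(0.2, 2)) cannot
  achieve this: conditioning on sample polymorphism shifts its realized
  median to ≈ 6%.
* **Trait** — $y = G_c\beta_c + h + e$ with $\sigma_h^2 = h^2 = 0.29$
  and $\sigma_e^2 = 0.71$ (non-genetic variance scaled to 1).  Causal
  variants ($\lceil$ `causal_fraction` $\cdot m\rceil$ of them,
  optionally restricted to MAF ≤ 0.03) get
  $|\beta_j| = \log(c)\,|\log_{10} \mathrm{MAF}_j|/2$, positive with
  probability `unidirectional_fraction`.

`type1_experiment()` builds a mini-exome (region sizes
$2 + \mathrm{NB}(1, \mu = 5.4)$ truncated at 60, matching a mean of
about 7.4 variants per region), simulates replicate null traits, and
pools the $F$-test P values; `power_experiment()` estimates power on a
fixed 50-variant region over a grid of effect-size constants $c$ and
direction fractions.  Replicates are paired across the grid and across
models (same causal sets, signs scaled by $\log c$, same noise), which
removes between-cell Monte Carlo noise from ordering comparisons.  Both
experiments precompute the rotated regional designs once, so a
region-model test costs one thin QR per replicate; all randomness flows
from a single seed.

**Problem sizes.**  The packaged calibration runs use 1,702 regions × 12
replicates (≈ 2×10^4 pooled tests per model) at $\alpha = 0.05$, 59
replicates (≈ 10^5 tests) at $\alpha = 0.01$, 200 replicates for
heritability recovery, and 200 replicates per power point — sizes chosen
so the whole acceptance analysis completes in minutes on one CPU while
keeping the binomial standard errors a small fraction of the quantities
tested.

## What the simulator does and does not emulate

It reproduces the sample structure (large three-generation pedigrees),
the rare-shifted MAF spectrum, within-region LD of the
founder-haplotype/IBD kind, and the polygenic trait model.  It does not
reproduce real exome geometry: position clustering (exons), fine-scale
population LD among founder haplotypes, allele-frequency/position
correlation, or covariates such as age, sex and smoking
(intercept-only by default; covariate support is in the API).  Passing
calibration here shows the statistics are correct under the model's own
assumptions, not that real data meet them.

One visible consequence: with synthetic LD the power of the B-spline
BSF-only model is measurably sensitive to the direction of causal
effects (the paired direction comparison in the acceptance suite detects
it), while the Fourier models are not.  On real exome genotypes the
direction insensitivity of all smoothed models may well be better, but
our generator cannot certify it, and we deliberately do not reshape the
LD just to make that comparison pass.

## Numerical choices

* eigendecomposition once per relationship matrix, shared across
  replicates and regions;
* rank by pivoted QR with relative tolerance $10^{-8}$ on the whitened,
  covariate-orthogonalised design;
* quadrature: 20-node Gauss–Legendre per piece on the union of the two
  systems' knot partitions (and a 12-interval partition for pure Fourier
  pairs);
* heritability search: `optimize()` on $[0, 1-10^{-6}]$, tolerance
  $10^{-8}$, explicit comparison against the boundary values; when $R
  \propto I$ only the total variance is identifiable and $h^2$ is pinned
  to 0;
* missing dosages are mean-imputed per variant; dosage columns are
  oriented to the minor allele; monomorphic variants are dropped by the
  readers (regions reduced to one variant use the Wald fallback);
* per-region failures in a scan are recorded as `NA` rows with the error
  message and never abort an exome run.

## Known limitations

Quantitative traits only (no GLMM for binary traits); one polygenic
random effect (no household or dominance variance components); no
kernel-based variance-component test; fixed (user-chosen) numbers of
basis functions rather than data-driven selection; simulator LD is
haplotype-pool/IBD LD, not coalescent LD.
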