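---
title: "Allele-count scaling and the shrinkage of allele substitution effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-count scaling and the shrinkage of allele substitution effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Genomic evaluation predicts direct genomic values (DGV) from dense SNP
genotypes and, as a by-product, estimates per-locus allele substitution
effects (ASE): the expected change in phenotype per extra copy of the counted
allele. Before fitting, the 0/1/2 allele counts are always centered; whether
they are *also scaled* by the locus standard deviation is a modelling choice
that is often treated as cosmetic. It is not: scaling changes the implicit
prior on how effect size relates to allele frequency, and therefore changes
how strongly rare-variant effects are shrunk toward zero. DGV are almost
unaffected; ASE of low-MAF variants can change several-fold.

`aseshrink` implements the machinery needed to study this quantitatively:

* a weighted SNP-BLUP / GBLUP solver with a continuous scaling parameter,
* ASE back-solving from DGV,
* the closed-form single-locus shrinkage-ratio theory under uniform and
  U-shaped allele-frequency spectra,
* per-MAF comparison statistics between two fits,
* a scan of the scaling parameter by restricted likelihood and by weighted
  prediction error, and
* a synthetic-data generator reproducing the statistical structure the
  theory assumes.

## Model

The phenotypes are deviation-style records (e.g. daughter yield deviations)
with an effective record count $wt_i$ per individual. For a scaling
parameter $\gamma \in [-1, 0]$ the coded design matrix $\mathbf V$ has
entries

$$v_{ij} = (x_{ij} - 2p_j)\,\bigl(2p_j(1-p_j)\bigr)^{\gamma/2},$$

where $x_{ij} \in \{0,1,2\}$ and $p_j$ is the sample frequency of the
counted allele. $\gamma = 0$ is centered-only coding (RRc), $\gamma = -1$ is
centered-and-scaled coding (RRcs). The model is

$$\mathbf y = \mathbf 1\mu + \mathbf V \mathbf b + \mathbf e,\qquad
  \mathbf b \sim N(0, \mathbf I\,\sigma_a^2/s_\gamma),\qquad
  \mathbf e \sim N(0, \mathbf D\,\sigma_e^2),$$

with $\mathbf D = \mathrm{diag}(1/wt_i)$ and
$s_\gamma = \sum_j (2p_j(1-p_j))^{\gamma+1}$. The divisor $s_\gamma$ is the
unique choice that makes this SNP-BLUP equivalent to GBLUP with
$\mathbf G = \mathbf V\mathbf V'/s_\gamma$ at *every* $\gamma$, and that
reduces to the two standard genomic relationship matrices at the endpoints
(centered GRM at $\gamma=0$; centered-and-scaled GRM at $\gamma=-1$). The
coded-scale estimates are mapped to ASE by
$\hat\alpha_j = \hat b_j (2p_j(1-p_j))^{\gamma/2}$, the identity at
$\gamma=0$.

`solve_snp_blup()` solves the marker-level equations when loci are few and
the equivalent $n \times n$ individual-level system when loci outnumber
individuals; the two routes agree to numerical precision and are tested
against each other. `backsolve_ase()` recovers
$\hat{\mathbf b} = s_\gamma^{-1}\mathbf V' \mathbf G^{-}\hat{\mathbf g}$
from a GBLUP solution (pseudo-inverse, relative tolerance $10^{-10}$, so
singular relationship matrices from small samples are handled
deterministically).

## REML

Variance components are estimated by restricted maximum likelihood for the
weighted single-GRM model. The implementation folds the weights in by
pre-multiplying with $\mathrm{diag}(\sqrt{wt_i})$, projects out the
intercept with an explicit orthonormal contrast basis (QR of the weighted
intercept column, exact also for rank-deficient $\mathbf G$), and profiles
the restricted likelihood down to one dimension: a deterministic Brent
search over $\log(\sigma_e^2/\sigma_a^2)$ on $[-10, 10]$ with tolerance
$10^{-8}$. There is no random initialization, so results are reproducible to
the last bit. The reported log-likelihood is always evaluated on the
original data scale
($\ell_R = -\tfrac12[(n-1)\log 2\pi + \log|\mathbf V_y| +
\log(\mathbf 1'\mathbf V_y^{-1}\mathbf 1) + \mathbf y'\mathbf P\mathbf y]$),
and the eigendecomposition path is tested against a dense-determinant
evaluation. Fits whose optimum lands on the edge of the search interval are
flagged (`boundary`); this happens legitimately when the likelihood prefers
$h^2 \approx 0$, e.g. on permuted phenotypes.

## Shrinkage-ratio theory

For a single locus in linkage equilibrium with Hardy–Weinberg genotypes and
record weights independent of genotype, the ratio of the ASE estimated under
the two codings has the closed form

$$\frac{\hat\alpha_{RRcs,j}}{\hat\alpha_{RRc,j}}
  = \frac{c\,n + S/(2p_j(1-p_j))}{c\,n + N},
  \qquad c = \frac{h^2}{1-h^2},$$

with $S = \sum_k 2p_k(1-p_k)$. Under a uniform frequency spectrum
$S = N/3$; under the U-shaped mutation–drift spectrum
$\phi(p) \propto p^{4N_ev-1}(1-p)^{4N_ev-1}$ (selection coefficient fixed at
0), $S = N \cdot 2C^*(2n-1)$ where

$$C^* = \frac{1}{4n}\Bigl(\ln(2n-1) + \tfrac{1}{4n-2} +
  \gamma_{EM}\Bigr)^{-1}$$

approximates the normalizing constant via the Euler–Mascheroni constant
$\gamma_{EM}$ (hard-coded to 20 digits, and named distinctly from the
scaling parameter throughout the package because the field reuses the symbol
$\gamma$ for both). The approximation assumes $4N_ev \approx 0$; the package
switches to the exact grid summation, with a warning, when
$4N_ev \ge 10^{-3}$, and the two paths are tested to agree to $10^{-3}$
relative for $n$ from $10^2$ to $10^6$. The ratio crosses 1 exactly where
$2p(1-p)$ equals the spectrum's expected heterozygosity, at
$p = (1-\sqrt{1-2E})/2$ — about 0.21 for the uniform spectrum, independent
of $h^2$, $n$ and $N$.

```{r}
library(aseshrink)
ratio_uniform(h2 = 0.2, n_individuals = 1000, n_snps = 15e6, p = 0.5)
crossing_maf(freq_ushaped(Ne = 65, v = 1e-8), 1000)
autoplot(ratio_curve(0.2, 1000, 8e5, freq_ushaped()))
```

All of the two-decimal scenario values reported by `scripts/acceptance.R`
come from these closed forms; the ridge-pair property test verifies the
formula against explicit per-locus scalar ridge estimates on simulated
linkage-equilibrium data (median relative error below 5% at $n = 2000$,
$N = 500$).

## What the synthetic data emulate — and what they do not

The generator reproduces exactly the structure the derivations assume:
loci in linkage equilibrium, Hardy–Weinberg genotypes, frequencies drawn
from the discrete grid $1/2n, \dots, (2n-1)/2n$ (the support of the theory's
summations), an additive polygenic architecture, and weighted residuals
$e_i \sim N(0, \sigma_e^2/wt_i)$. Choices made where the study data leave
gaps, each fixed once:

* **Effect architecture.** True effect variances follow
  $(2p_j(1-p_j))^{\gamma_{true}}$ with $\gamma_{true}$ configurable, then a
  deterministic rescaling sets $\sum_j 2p_j(1-p_j)\mathrm{Var}(\alpha_j)$ to
  the requested total additive variance. The two codings' priors are the
  endpoints $\gamma_{true} = 0$ and $-1$, which is what makes recovery of
  the architecture by the $\gamma$-scan testable.
* **Weights.** Only the mean effective record count is specified by the
  study design (549 daughters on average); the generator offers a constant
  model and a shifted-Poisson model ($1 + \mathrm{Pois}(m-1)$), the simplest
  families consistent with that single moment. No attempt is made to match
  higher moments of a real daughter-count distribution.
* **Intercept** defaults to 0 and is configurable; it is a free fixed
  effect in the model either way.

Not emulated: linkage disequilibrium (the theory explicitly ignores
off-diagonal crossproducts; LD genotypes would test a different claim),
pedigree structure, selection, imputation error, multiple traits. Passing
tests therefore demonstrate internal correctness and theory–simulation
consistency under the stated assumptions, not performance on real LD-rich
cattle data — on real data the overall DGV/ASE contrast persists, but
per-locus ratios are modulated by LD.

A practical consequence visible in the demo pipeline: with a U-shaped
spectrum and $\gamma_{true} = -1$, a large share of the additive variance
sits in rare loci that the five-copy variant filter removes, so the
marker-captured heritability estimated by REML is well below the simulated
$h^2$. That is the expected behaviour of the model, not an estimation
failure.

## The scaling-parameter scan

`scan_loglik()` re-estimates variance components by REML at every grid
point and records the restricted log-likelihood; profiles are comparable
across $\gamma$ because the fixed-effect design never changes. Whether the
study re-estimated components at each $\gamma$ is not documented; per-grid
re-estimation is the defensible default here and the estimates are reported
alongside the profile. `scan_msep()` fits on a training block only,
predicts validation individuals through the train–validation relationship
block (algebraically identical to projecting training DGV with the
train-block inverse), adds the training intercept, and evaluates the
weighted mean squared error of prediction
$\sum wt_i(\hat y_i - y_i)^2 / \sum wt_i$. Coding frequencies default to
the full dataset with a `freq_from = "train"` alternative, since the study
is silent on that point; the convention used is recorded on the result.
Ties on the grid are broken toward the more negative $\gamma$, with a
message. The default grid is $-1$ to $0$ in steps of $0.1$.

Ordered splits use input order as the age proxy (older animals first),
mirroring an older-bulls/young-bulls validation design; explicit id lists
are supported for real cohorts.

## Numerical choices and degenerate inputs

* Coding requires all frequencies strictly inside (0, 1); monomorphic loci
  must be removed first (`apply_variant_filters()`, which also enforces the
  five-minor-copies and all-genotype-classes rules and is idempotent).
* Centering is exact: column means of every coded matrix are zero to
  $10^{-10}$ by construction, enforced in tests.
* Pseudo-inversion of singular relationship matrices uses an eigenvalue
  cutoff of $10^{-10}$ relative to the largest eigenvalue.
* REML: search interval $[-10, 10]$ on the log variance ratio (heritability
  $\approx [5\times10^{-5}, 1-5\times10^{-5}]$), tolerance $10^{-8}$,
  boundary optima flagged rather than hidden.
* Missing genotypes are rejected with the locus and sample named; there is
  no imputation path.
* Per-MAF ratio summaries exclude loci whose reference ASE is exactly zero
  (reporting the excluded count) and publish a median ratio alongside the
  mean as a robust companion; groups below the minimum size are flagged,
  never silently dropped. MAF bins are right-closed so MAF = 0.5 stays in
  the top bin.

## Problem sizes used by the test suite

The property suites run at the sizes stated with each claim: model
equivalences on 50 × 200 simulated sets; the ridge-pair oracle at
$n = 2000$, $N = 500$; REML heritability recovery as the mean over 20
replicates at $n = 500$, $N = 1000$ (within 0.05 of the simulated 0.5); and
scaling-parameter recovery over 10 replicates per architecture endpoint at
$n = 500$, $N = 2000$ with the 11-point grid, requiring a majority of
replicates to land on the correct side ($\hat\gamma \le -0.7$ for
$\gamma_{true} = -1$; $\hat\gamma \ge -0.3$ for $\gamma_{true} = 0$). These
sizes give stable verdicts while keeping the whole suite around a minute on
one core.

## Known limitations

* No LD simulation, so the package cannot quantify how far LD moves
  empirical per-locus ratios away from the single-locus theory.
* The U-shaped density drops the selection term; spectra under selection
  are out of scope.
* The weighted generalization of the ratio formula (replacing $n$ by an
  effective record sum) is exposed but the printed scenario values all use
  the one-record-per-individual form.
* `fit_greml()` estimates two components (additive, residual); multi-GRM
  partitions and dominance are out of scope.
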