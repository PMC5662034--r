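# aseshrink

Scaling of allele counts and the shrinkage of allele substitution effects
in genomic evaluation.

## What this package is for

SNP-BLUP / GBLUP genomic evaluation centers the 0/1/2 allele counts before
fitting; whether the counts are *also scaled* by the locus standard
deviation $\sqrt{2p_j(1-p_j)}$ looks cosmetic but changes the implicit
prior on rare variants. Direct genomic values (DGV) are nearly invariant to
the choice, while allele substitution effects (ASE) of low-MAF variants can
differ several-fold, because scaled coding shrinks rare-variant effects
much less. `aseshrink` is for quantitative geneticists who want to study
that trade-off: it fits the weighted SNP-BLUP model

$$\mathbf y = \mathbf 1\mu + \mathbf V\mathbf b + \mathbf e,\qquad
v_{ij} = (x_{ij}-2p_j)\bigl(2p_j(1-p_j)\bigr)^{\gamma/2},\qquad
\mathbf e \sim N(0, \mathbf D\sigma_e^2),$$

for any scaling parameter $\gamma \in [-1,0]$ ($\gamma=0$: centered-only,
"RRc"; $\gamma=-1$: centered-and-scaled, "RRcs"), with per-individual
weights (effective record counts, e.g. daughter numbers) in
$\mathbf D = \mathrm{diag}(1/wt_i)$, and provides:

* deterministic REML for the weighted single-GRM model, and back-solving of
  ASE from DGV;
* the closed-form single-locus theory for the ratio
  ASE(scaled)/ASE(unscaled),
  $\bigl(cn + S/(2p(1-p))\bigr)/\bigl(cn + N\bigr)$ with $c=h^2/(1-h^2)$,
  specialized to uniform ($S=N/3$) and U-shaped
  ($S = 2NC^*(2n-1)$, Euler–Mascheroni approximation of the normalizing
  constant) allele-frequency spectra;
* per-MAF comparison statistics (correlation, mean ratio, regression slope)
  between two fits, with the theoretical overlay;
* a $\gamma$-scan selecting the scaling by restricted log-likelihood and by
  weighted mean squared error of prediction on a train/validation split;
* a Hardy–Weinberg synthetic-data generator with a configurable
  MAF-dependence of true effect variance, so every claim is testable
  without external data.

Genotypes come in as VCF (diploid GT, counted allele = ALT) or dosage TSV;
phenotypes as TSV (`id`, `phenotype`, `weight`). Results come back as
tibbles (`tidy()`, `glance()`, `augment()`) with `autoplot()` methods.

## Worked example

```r
library(aseshrink)

sim <- simulate_dataset(
  n_individuals = 500, n_snps = 2000, h2 = 0.5, gamma_true = -1,
  freq_model = freq_ushaped(Ne = 65, v = 1e-8), seed = 2024
)
geno <- apply_variant_filters(sim$genotypes)
#> Removed 1122 of 2000 loci by variant filters.

fit_rrc  <- fit_ase(sim$phenotypes, geno, gamma = 0)   # centered
fit_rrcs <- fit_ase(sim$phenotypes, geno, gamma = -1)  # centered + scaled

compare_fits(fit_rrc, fit_rrcs, bin_width = 0.05)
#> <ase_comparison> gamma 0 vs -1
#>   DGV: cor = 0.9610, slope = 1.2212; ASE: cor = 0.7010; 10 MAF groups
```

The two codings give almost the same ranking of animals (DGV correlation
0.96) but visibly different marker effects (ASE correlation 0.70), and the
per-MAF table shows where: the lowest-MAF bin has a mean ASE ratio of 7.1
(scaled coding shrinks those effects far less), falling to 1.3 by MAF 0.175
and below 1 for common variants:

```r
head(tidy(compare_fits(fit_rrc, fit_rrcs, bin_width = 0.05)), 4)
#>     maf n_snps correlation mean_ratio median_ratio regression_slope
#> 1 0.025    132       0.853       7.08         5.88             6.67
#> 2 0.075    161       0.982       2.56         2.47             2.47
#> 3 0.125    111       0.994       1.62         1.63             1.65
#> 4 0.175     86       0.997       1.30         1.27             1.27
```

Note the variant filter removed 56% of the loci: a U-shaped spectrum puts
most mass on rare alleles, and with `gamma_true = -1` those loci carry much
of the additive variance, which is why the REML heritability captured by
the retained markers (≈ 0.13 below) sits far below the simulated 0.5.

Scanning the scaling parameter on this dataset:

```r
split <- split_phenotypes(sim$phenotypes, "by_order", train_fraction = 0.6)
scan  <- scan_gamma(sim$phenotypes, geno, criterion = "both", split = split)
best_gamma(scan, "loglik")  # -1
best_gamma(scan, "msep")    # -0.5
```

The restricted log-likelihood is maximized at $\gamma = -1$, matching the
simulated architecture; the MSEP profile is shallow (range < 0.005) with
its minimum mid-grid, which is typical — prediction error discriminates
between codings much more weakly than the likelihood does.

The theoretical ratio curves behind Figures of the scenario grid:

```r
ratio_uniform(h2 = 0.2, n_individuals = 1000, n_snps = 15e6, p = 0.5)
#> 0.6666889  (prints as 0.67)
crossing_maf(freq_uniform(), 1000)
#> 0.2113249  (ratio = 1 near MAF 0.21, for every uniform scenario)
autoplot(ratio_curve(0.2, 1000, 8e5, freq_ushaped()))
```

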