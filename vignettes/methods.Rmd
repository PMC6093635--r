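---
title: "Methods: summary-level CCA for cross-trait pleiotropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-level CCA for cross-trait pleiotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Metabolic disorders travel together: fasting glucose (FG), fasting insulin
(FI), body-mass index (BMI), waist-hip ratio (WHR), HDL cholesterol and
triglycerides (TG) are phenotypically and genetically correlated, and many
genes are believed to act on several of them at once (pleiotropy). Testing
each trait separately wastes that shared signal. `pleiocca` implements a
gene-centric multivariate screen that works entirely from published GWAS
summary statistics — per-SNP effect size `beta`, standard error `se` and
sample size `n` per trait — plus a reference genotype panel for linkage
disequilibrium (LD) and a phenotypic trait-correlation matrix.

## The model

### Stage 1: harmonization, annotation, pruning

SNPs are intersected across all traits and the panel; effect alleles are
aligned to the first trait (a swapped allele pair flips the sign of `beta`;
strand-ambiguous A/T and C/G SNPs and allele mismatches are dropped). SNPs
are assigned to genes by position (1-based inclusive ranges, optional
flank, default 0 bp — strict transcript boundaries). Within each gene, SNPs
are greedily pruned in position order so that every kept pair satisfies
r² ≤ 0.01, where r is the Pearson correlation of panel dosages. Pruning is
per-gene, so a SNP may survive in one overlapping gene and not another;
keep-first scanning in ascending position is the common convention and
makes the result deterministic.

### Stage 2: summary-level canonical correlation analysis

For a gene with m pruned SNPs and K traits, three correlation blocks are
assembled:

* `Sigma_XX` (m×m): SNP–SNP correlations from the reference panel;
* `Sigma_XY` (m×K): normalized effect sizes
  `beta / (sqrt(n) * se)`, each trait using its own per-record `n`
  (for a standardized trait this is approximately the SNP–trait Pearson
  correlation), clamped to |0.999| so entries stay inside the correlation
  domain when `se` is tiny;
* `Sigma_YY` (K×K): the phenotypic trait correlations, supplied as data
  (the packaged `engage_trait_cor()` holds the published six-trait values).

`Sigma_XX` and `Sigma_YY` are made numerically positive definite by
iteratively multiplying off-diagonals by 0.999 until the smallest
eigenvalue reaches 1e-8 — the smallest perturbation toward the identity
that guarantees invertibility. The canonical correlations are the singular
values of `Sigma_XX^(-1/2) Sigma_XY Sigma_YY^(-1/2)`, clipped to [0, 1].

Significance uses all canonical correlations jointly via Bartlett's
Wilks-lambda approximation: `-(n - 1 - (m + K + 1)/2) * sum(log(1 - r_i^2))`
referred to chi-square with `m*K` degrees of freedom. The leading canonical
correlation is also reported as the gene's effect summary. Because the
traits have unequal sample sizes (24,245–87,048 in the published data), the
test uses `n_effective = min` per-trait n over the gene's records — the
conservative choice; the original analysis does not state its policy.
Bonferroni control divides `alpha` by the number of genes tested.

### Stage 3: per-trait gene-based refinement

Genes passing the CCA screen are re-tested one trait at a time with the
classical all-SNP sum-of-chi-squares statistic `sum((beta/se)^2)`. Its null
distribution accounts for LD by Monte Carlo: draws from N(0, LD) are
squared and summed, and `p = (#exceeding + 1)/(sims + 1)`, which is a valid
p-value and never zero. Simulation escalates through stages (default 10³,
10⁴, 10⁶) while `p < 10/sims`, resolving small p-values down to the
~1e-6 floor at reasonable cost. Each (gene, trait) cell draws from its own
RNG stream derived from the master seed by a stable hash, so results are
independent of execution order. By default the test uses **all** SNPs in
the gene (that is how the classical gene-based test is defined, and a
causal variant removed by pruning would otherwise lose most of its signal);
`genetest_pruned = TRUE` switches to the pruned set. A gene significant at
the Bonferroni threshold (`alpha` / genes tested) for **more than one**
trait is called potentially pleiotropic.

### Stage 4: enrichment

Pleiotropy calls are tested for over-representation in GMT gene-set
libraries with the hypergeometric upper tail (identical to one-sided
Fisher), BH-corrected across the library. The default background universe
is the set of genes that entered the CCA stage — only genes that could have
been discovered — rather than the whole annotation file; this is
configurable because web enrichment tools differ on this point and their
choice is rarely reported.

## The synthetic world

`make_scenario()` generates a complete input bundle with known truth. Its
defaults state the emulated conditions once:

* 6 traits with the published phenotypic correlation matrix and the
  published per-trait sample sizes scaled down 10× (FG 4,669 … BMI 8,705),
  so the full pipeline runs in minutes;
* a cohort of 10,000 individuals; each trait subsamples its own cohort,
  emulating distinct, partially overlapping consortium cohorts;
* 100 genes, each with a truncated-Poisson(13) number of SNPs in 1–40
  (echoing the published 1–280 range with mean 13; the cap keeps desk-scale
  runtime), AR(1) within-gene LD at rho = 0.5, MAF uniform on (0.05, 0.5),
  genes mutually LD-independent; dosages arise from two latent Gaussian
  haplotypes thresholded at the MAF quantile;
* 5 pleiotropic genes with effects on HDL and TG (the trait pair on which
  most reported pleiotropic genes act) and 5 single-trait genes, each
  planted effect explaining 1% of trait variance.

**Effect architecture.** By default a planted gene's effect is the
standardized equal-weight sum of *all* its standardized dosages
(`causal_snps_per_gene = Inf`), scaled to explain exactly `h2_per_gene` of
the trait variance. This models allelic heterogeneity and — importantly —
makes the signal robust to LD pruning: with a single causal SNP, pruning at
r² ≤ 0.01 over AR(0.5) LD keeps roughly every fourth SNP and therefore
deletes the causal SNP itself for most genes, leaving a world structurally
unlike the one being emulated (where the pruned multivariate screen
retained thousands of strong signals). The point architecture remains
available (`causal_snps_per_gene = 1`) and is what the single-SNP
heritability checks use.

**What a green test does not establish.** The generator has no real LD
maps, no population stratification, no imputation error, no allele-
frequency/effect-size coupling, and cohort overlap arises implicitly from
subsampling one cohort rather than being controlled. Calibration of the
CCA p-value is checked under the model-consistent null (fully overlapping
cohorts, where the cross-trait covariance of the normalized betas equals
the phenotypic correlation); with partially overlapping cohorts that
covariance shrinks toward zero and the Bartlett test becomes conservative
in most directions — the same approximation the real analysis makes.

## Numerical choices

* PD shrinkage constants: factor 0.999, floor 1e-8 (above).
* Normalized betas clamped at |0.999|; `1 - r_i^2` floored at 1e-12 before
  the log in the Bartlett statistic.
* The Monte-Carlo p uses the +1/+1 estimator; the per-cell seed is a
  31-bit polynomial hash of (master seed, "genetest", gene, trait).
* Missing dosages are mean-imputed only inside LD computation, never
  written back.
* Monomorphic panel SNPs are dropped at load with a count.
* Degenerate inputs: empty gene-range files and empty enrichment queries
  return empty results with warnings; a failed gene is recorded and skipped
  rather than aborting the run; an empty SNP intersection is an error.

## Observed operating characteristics

These are measured by the test suite and `scripts/acceptance.R`, not
asserted from theory: summary-level CCA tracks individual-level CCA within
0.02; null CCA p-values pass a KS uniformity check at the 1% level with
nominal 5% type-I error; the Monte-Carlo gene test matches chi-square
closed forms within 3 Monte-Carlo SEs; and the default planted world is
recovered end-to-end (≥4 of 5 pleiotropic genes, no null calls) in about
18 of 20 seeds — the recovery criterion sits near its boundary, reflecting
the genuine difficulty of the scaled-down world (for large genes the
Bartlett degrees of freedom grow with m while the planted signal does
not), and was not tuned.

## Known limitations

* `Sigma_YY` is an input; it is never estimated from the summary
  statistics.
* No liftover, rsID resolution, MAF filtering (beyond monomorphic
  removal), or frequency-based resolution of strand-ambiguous SNPs —
  ambiguous SNPs are simply dropped.
* Gene-based testing implements only the all-SNP statistic, not top-k or
  best-SNP variants.
* The enrichment stage ignores gene-ontology term hierarchy; GO and
  pathway libraries are treated identically.
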