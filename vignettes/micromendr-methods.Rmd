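---
title: "Methods: host genetics, the gut microbiome, and bidirectional Mendelian randomization"
author: "micromendr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host genetics, the gut microbiome, and bidirectional Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What the package computes

micromendr implements a complete host-genetics-by-gut-microbiome analysis:

1. **SNP-based heritability** of taxon abundances by single-component GREML.
2. **Microbiome GWAS**: covariate-adjusted association scans with a
   log-normal model for common taxa and a logistic model for rare
   (presence/absence) taxa and enterotypes, with genomic-inflation control.
3. **Polygenic-score instruments**: LD clumping of suggestive signals and
   weighted scores validated in a replication design.
4. **Bidirectional two-sample Mendelian randomization (MR)** between taxa
   and complex traits/diseases, with four estimators (IVW, weighted median,
   MR-Egger, an MR-PRESSO-style test) and a two-tier significance
   classification.
5. **Disease-microbiome feature analysis**: Spearman screening of predicted
   disease-pathway abundances against taxa, PAM clustering with
   silhouette-based model selection, Jaccard comparison of clusterings, and
   a microbiome risk score (MRS).

Because the motivating cohort data are access-restricted, the package ships
a synthetic-cohort generator with known ground truth; every stage is
validated against it.

# The synthetic cohort generator

`sim_config()` + `simulate_cohort()` produce a full dataset bundle. The
generator's components, and the real-data features they do and do not
emulate:

**Genotypes.** A latent Gaussian with AR(1) correlation (parameter
`ld_rho`) inside blocks of `ld_block_size` variants is thresholded at the
MAF quantile to produce one haplotype; dosages are sums of two independent
haplotypes. This gives tunable LD with almost no machinery, but
thresholding attenuates correlation (the classic tetrachoric-to-Pearson
gap): at `ld_rho = 0.9` adjacent dosage r² is roughly 0.35–0.55 depending
on MAF, and the test suite checks the realized correlation against a
bivariate-normal orthant-probability oracle rather than against `ld_rho`
itself. The genetic map is a constant 1 cM/Mb (configurable), which is all
the 0.1 cM clumping window requires.

**Common taxa.** Each common taxon's latent log-abundance is a genetic
value plus Gaussian noise, empirically rescaled so the in-sample genetic
variance fraction equals `taxon_h2` exactly. Causal effects have **equal
magnitude and random sign** (`h2/m` variance each). We chose this over
Gaussian effect sizes deliberately: with heavy-tailed effects a single
dominant variant carries most of the association signal, and downstream
instrument-screening rules (below) cap the usable signal of any one
instrument, so only designs with several comparable instruments exercise
the IVW aggregation the analysis relies on. Counts are produced by
multinomial sampling of `depth` reads/sample (default 10,000, a standard
16S rarefaction depth), which adds realistic compositional and sampling
noise on top of the latent model.

**Rare taxa.** Presence follows a probit liability threshold at a
per-taxon target prevalence drawn from `rare_prevalence_range`; abundance
conditional on presence is log-normal and independent of the liability.
This matches the analysis-side treatment of rare taxa as binary variables.

**External disease GWAS.** Instruments carry true liability effects drawn
from `instrument_beta_range` with standard errors implied by a GWAS of
`gwas_n` samples (default 5,000, the scale of the East Asian disease GWASs
that typically supply reverse-direction instruments). A fraction
`pleiotropy_fraction` of instruments also receive a direct effect on
downstream taxa, violating the exclusion restriction; these are recorded in
the ground truth so pleiotropy diagnostics can be scored.

**Cohort bundle.** `simulate_cohort()` adds covariates (age, sex, dietary
energy, alcohol, BMI, batch), a binary disease generated from a logistic
model on the first `n_disease_taxa` common taxa (intercept solved
numerically for the target prevalence), a reverse-causal channel (genetic
disease liability scaled by `causal_effect` added to four target taxa), an
external quantitative-trait GWAS mediated purely through the last common
taxon, a PICRUSt-style predicted-disease feature, and a pathway table whose
features are noisy non-negative combinations of disjoint taxon subsets
(ground-truth clusters). The disease taxa additionally share a latent
community factor (loading 0.8); this mirrors co-occurring taxon groups in
real communities and is what lets a single predicted-disease feature
correlate above 0.2 with many taxa at once, as a 16-taxon risk score
requires.

**Not emulated:** read-level sequencing error, chimeras and OTU-picking
artifacts; phylogenetic structure among taxa; population stratification and
cryptic relatedness (the cohort is unstructured by default, which is also
why fixed-effect PC adjustment suffices downstream); vertical microbiome
transmission. Passing tests therefore validate the statistical machinery,
not robustness to those real-data complications.

# Taxon-table processing

* **Rarefaction** draws without replacement (multivariate hypergeometric),
  one seeded draw per sample; samples below the target depth are dropped
  and reported.
* **Alpha diversity**: Shannon in base 2 (bits, the QIIME 1 convention),
  observed richness, and Chao1 with the bias-corrected form
  `S + F1(F1-1)/2` when no doubletons exist.
* **Prevalence partition** at 90% with an inclusive boundary ("not fewer
  than 90%"): a taxon present in exactly 90% of samples is common.
* **Z-scored log abundance**: zeros are replaced per taxon by half its
  smallest nonzero relative abundance before the natural-log transform
  (configurable); the pseudocount choice matters little after Z-scoring
  but keeps the transform defined.
* **Effective number of independent taxa**: `(Σλ)²/Σλ²` over eigenvalues of
  the taxa-by-taxa covariance matrix. The abundance scaling that the
  covariance should be computed on is not well defined in general, so the
  default standardizes columns first (equivalently, uses the correlation
  matrix), making the statistic scale-free; `scale = "raw"` is available.
* **Enterotyping**: root Jensen–Shannon divergence distances (natural log;
  the square root is a metric), PAM clustering, and the
  Calinski–Harabasz pseudo-F (computed from pairwise distances via the
  standard sum-of-squares identity) to choose k.

# Heritability and association

**GREML.** The model is `y = Xb + g + e`, `g ~ N(0, σg² K)` with K the
standard GCTA-style GRM. We rotate once into the GRM eigenbasis, making
every REML iteration O(n·p²). Optimisation: one EM step, then
average-information updates with the proposal clamped at the lower bound
and step-halved if it overshoots the likelihood; EM fallback otherwise.
Convergence at relative log-likelihood change < 1e-6, at most 100
iterations; components are truncated at 1e-8 of the phenotypic variance
with a boundary flag; h² standard errors come from the inverse AI matrix by
the delta method. An identity-like GRM triggers a non-identifiability
warning. `reml_loglik()` exposes the restricted likelihood so it can be
checked against direct dense-matrix evaluation (the test suite does this to
1e-8 at n = 50).

**Association scans.** Exact per-variant OLS via residualization
(Frisch–Waugh) for continuous outcomes — equal to the joint fit, verified
against a normal-equations oracle — and per-variant IRLS logistic fits for
binary outcomes, with separation reported per variant rather than aborting
the scan. A mixed-model association was deliberately replaced by
fixed-effect regression with the top five GRM principal components as
covariates: the synthetic cohort has no cryptic relatedness, and PC
adjustment is the standard fixed-effect approximation.

**Genomic inflation** is the median-χ² lambda (LD-score regression needs
external LD-score references and is out of scope).

**Clumping and polygenic scores.** Greedy clumping (smallest p first,
claim r² ≥ 0.1 within 0.1 cM, ties broken by smaller genomic coordinate —
deterministic), discovery threshold p < 5e-5 for score construction.
Scores are Σ beta × dosage after allele harmonization (label flips use the
complementary dosage, so scores are invariant to allele-label orientation).
Score-taxon association uses a Gaussian linear model on the Z-scored log
abundance as the primary analysis; a negative-binomial-on-counts mode
exists because the source analysis describes an NB model, but an NB
distribution applied to Z-scores is internally inconsistent, so it is not
the default.

# Mendelian randomization

* **Instrument selection.** Forward: clumped leads, minus any instrument
  whose outcome association has p < 0.05/k (k = number of instruments) —
  the pre-filter against direct outcome effects. Reverse: replicated
  disease variants thinned to pairwise r² < 0.1 in the cohort LD
  reference. Missing variants may be replaced by the best proxy with
  r² > 0.9, or dropped.
* **Harmonization.** Outcome effects are aligned to the exposure's effect
  allele (sign flip + EAF complement when swapped); palindromic variants
  are resolved by allele frequency only when both EAFs are outside
  [0.42, 0.58], else dropped; incompatible allele pairs are dropped with
  reasons.
* **IVW** with multiplicative random effects by default (SE inflated by
  √(Q/(k−1)) when above 1); fixed-effect via flag; single instrument
  degrades to the Wald ratio, flagged.
* **Weighted median**: delta-method ratio SEs as weights, linear
  interpolation where the cumulative normalized weight crosses 0.5,
  parametric-bootstrap SE. With equal weights and odd k it equals the
  ordinary median (tested).
* **MR-Egger**: WLS with intercept after orienting exposure effects
  non-negative; multiplicative overdispersion floored at 1; t-tests with
  k−2 df. Constrained through the origin it reduces to fixed-effect IVW
  (tested to 1e-10).
* **MR-PRESSO-style test**: observed leave-one-out IVW residual sum of
  squares against a parametric null (default 1000 seeded simulations;
  empirical p with add-one smoothing, so min p = 1/(n_sim+1));
  per-instrument outliers at a Bonferroni-corrected level; corrected
  estimate = IVW after outlier removal.
* **Classification.** `significant` when IVW p is below the
  direction-appropriate Bonferroni bound — 0.05/62 forward (62 outcome
  traits in the reference design), 0.05/n_eff reverse, with n_eff the
  effective number of independent taxa at the taxonomic level;
  `potential_causal` when Bonferroni fails but all four methods have
  p < 0.05; otherwise `null`. Binary-taxon reverse results are reported as
  odds ratios of presence per log-odds of disease; continuous-taxon results
  as 1-SD changes in log abundance per log-odds.

# Disease-microbiome features

Disease features (predicted pathway abundances) are clustered as objects:
Euclidean distance on Z-score-normalized per-sample profiles (the
transposed table; cohort-average profiles are the documented alternative).
PAM is the classic BUILD + SWAP algorithm — best improving
(medoid, non-medoid) exchange per pass, lowest-index tie-break — whose SWAP
objective is validated against exhaustive search on small instances and
against the reference `cluster::pam` implementation. Silhouette widths use
the `(M−N)/max(M,N)` form with singleton clusters given width 0; k is the
argmax of the average width. Clusterings are compared by the pairwise
co-membership Jaccard coefficient a/(a+b+c) (all-singleton pairs define 1,
with a warning).

The MRS selects taxa with training |Spearman rho| strictly above 0.2
against the target feature, freezes each taxon's empirical 5% quantile
(type-7) as a low-abundance cutoff, and scores each sample as the sum of
±1 direction contributions (0 below the cutoff). Cutoffs are learned on
the training table and stored in the model so the score is reusable on new
samples — the source procedure does not separate train/apply; we do.
Logistic regression of disease on the score (covariates: age, sex, energy,
alcohol, BMI) yields the odds ratio per score unit.

# Validation scenarios and problem sizes

The test suite and `scripts/acceptance.R` exercise the pipeline at desk
scale, chosen so the full suite runs in minutes on one core:

* GREML recovery: n = 1000 samples, 1200 variants, 20 causal variants,
  h² ∈ {0, 0.25, 0.5}, 20 replicates per setting.
* MR calibration: 25–30 instruments, 100 replicates, effects {0, 0.3};
  pleiotropy scenarios plant directional direct effects aligned with the
  exposure direction (sign-symmetric pleiotropy largely cancels in both
  IVW and the Egger intercept and would test nothing).
* End-to-end runs: n = 500, 2000 variants, 50 taxa (40 common + 10 rare),
  20 pathway features in 5 ground-truth clusters, focal taxon h² = 0.5,
  mediated trait effect 0.13, 10 causal variants, `ld_rho = 0.3`,
  `n_disease_taxa = 0` (the disease/MRS channel is validated separately at
  n = 1800, matching a cohort with ~217 cases).

The forward-MR scenario deserves its design note. The instrument-exclusion
rule (drop instruments with outcome p < 0.05/k) bounds the outcome signal
any retained instrument can carry at roughly |z| ≤ 2.6–2.8, so the IVW
z-statistic is capped near 1.6·√k regardless of the causal effect size —
stronger effects simply get their best instruments excluded. Detection
against the forward Bonferroni bound (0.05/62, z ≈ 3.35) therefore requires
several instruments of comparable strength, which drove both the
equal-magnitude effect design and the scenario's mediated effect size: at
n = 500 with h² = 0.5 split over 10 causal variants the expected detection
rate is about 0.75, and that ceiling is a property of the decision rules at
this sample size, not of the implementation.

# Known limitations

* The generator's LD is block-local; there is no long-range LD, so proxy
  search and clumping operate in an easier regime than real imputed data.
* Compositionality induces small negative correlations among taxa and
  attenuates observed-scale heritability relative to the latent target by
  roughly 5–15% depending on taxon count; the variance-accounting tests
  work on the latent scale for this reason.
* One cohort serves as both discovery and LD reference (as in the source
  design); winner's curse on instrument effects biases MR estimates toward
  zero by ~10–20% in the end-to-end scenario.
* MR-Egger under equal-strength instruments is nearly collinear and has
  essentially no power; the all-four-methods tier is accordingly
  conservative.
* The logistic association scan refits every variant; it is intended for
  thousands, not millions, of variants.
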