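---
title: "Methods: integrated metataxonomic and metabonomic analysis of mucosal biopsies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated metataxonomic and metabonomic analysis of mucosal biopsies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucometab)
```

## The analysis this package implements

`mucometab` implements a combined analysis of two molecular views of
colorectal mucosa, sampled on tumour and at 5 cm and 10 cm off tumour in
the same patients: genus-level 16S rRNA community profiles (OTU count
tables) and 1H magic-angle-spinning NMR spectra of intact tissue. The
pipeline has six stages:

1. **Cohort input or simulation** — paired OTU counts, spectra,
   metadata and qPCR Ct values (18 patients x 3 sites by default).
2. **NMR preprocessing** — calibration to the alanine methyl doublet at
   1.47 ppm, binning of the -1 to 10 ppm region at 0.00055 ppm (20000
   bins), removal of the water (4.50-5.19 ppm), ethanol (1.10-1.20,
   3.60-3.90 ppm) and polyethylene-glycol (3.70-3.75 ppm) windows,
   probabilistic quotient normalization (PQN) and unit-variance
   scaling. STOCSY correlation of a driver bin against the whole
   matrix supports peak assignment.
3. **Supervised modelling** — PCA with Hotelling T2 outlier screening;
   PLS-DA of community profiles against histology features with
   leave-one-sample-out cross-validation; OPLS-DA and maximum margin
   criterion (MMC) projections of the spectral matrix for the
   tumour/off-tumour contrast with leave-one-patient-out
   cross-validation; Q2, ROC/AUC, and an FDR-coloured pseudo-loadings
   ANOVA.
4. **Mucosal ecology** — rarefaction to the minimum depth, Shannon and
   Tau indices normalized to each patient's on-tumour value,
   Bray-Curtis distances with Ward clustering and patient-concordance
   detection, NMDS ordination, and univariate genus-histology tests.
5. **qPCR quantification** — Fusobacterium nucleatum relative
   abundance as `2^-(Ct_fn - Ct_pan)` with a paired, one-sided
   Wilcoxon comparison of tumour against the 10 cm site.
6. **Network integration** — Spearman correlation of per-metabolite
   bucket intensities against genus relative abundances, thresholded
   at p < 0.05 into signed tumour and off-tumour networks, per-stage
   subnetworks with a sign-consistent intersection, and
   Fruchterman-Reingold spring layouts.

## Models, conventions and numerical choices

**Binning.** Bins are contiguous half-open intervals
`[lo + k*res, lo + (k+1)*res)`; the bin value is the *mean* intensity
of raw points in the bin (zero when empty) so binning conserves mean
intensity over covered regions. Whether the original matrices used
mean or sum aggregation is not decidable from the description; mean
was chosen because it makes bin values resolution-independent.
Exclusion membership is decided by the bin centre.

**PQN.** Each row is first total-area normalized; the reference is the
column-wise median spectrum; each row's quotient is the median of
row/reference over reference-positive columns; the row is divided by
its quotient. The *stored* dilution factor is the product of the area
factor and the quotient (rescaled to median 1), which is the quantity
proportional to the physical dilution of the sample — the quotient
alone only corrects the residual compositional bias left by area
normalization. PQN applied twice returns unit factors (a fixed
point). Zero-variance bins after scaling are retained, centred, and
flagged, so bin indexing stays stable.

**OPLS-DA.** The orthogonal-projections construction with a single
predictive component: per orthogonal component, the orthogonal weight
is the X-loading minus its projection onto the predictive weight, its
variation is deflated from X, and the predictive component is
extracted last. With zero orthogonal components the predictive scores
coincide with one-component NIPALS PLS-DA. The number of orthogonal
components in the pipeline is chosen by maximizing the
leave-one-patient-out Q2 over 0..2 (component counts are otherwise
arbitrary at n = 54). Multi-class targets are handled one-vs-rest.

**MMC.** Concretized as the eigen-decomposition of the difference
between between-class and within-class scatter, `S_b - S_w`, with
orthonormal directions. When variables greatly outnumber samples the
scatter matrices are formed in a PCA subspace retaining 95% of the
variance, which stabilizes the decomposition; loadings are mapped back
to the original bins. Classes with a single member are rejected unless
regularization is explicitly enabled.

**Cross-validation.** Column centring/scaling is re-estimated on the
training rows of each fold and applied to the held-out rows, so no
scaling information leaks. Q2 = 1 - PRESS/TSS on the dummy-coded
class matrix, with fold-training means as the TSS baseline; class
assignment is nearest class mean in predicted-score space. The PQN
reference is computed once on the full matrix: it is a row-wise
(per-sample) operation, and refitting the median reference per fold
changes factors by well under the noise level at n = 54.

**Outlier screening.** Hotelling T2 from the first k = 3 component
scores with the F-distribution limit
`k(n-1)(n+1)/(n(n-k)) * F(conf, k, n-k)` at 95% confidence, the
conventional choice when the criterion used originally is not stated.

**ROC.** Threshold sweep over unique scores with trapezoidal area,
which averages ties; an all-tied score vector gives AUC 0.5.

**Pseudo-loadings ANOVA.** Per-bin one-way ANOVA (vectorized F
statistic) with Benjamini-Hochberg correction ("FDR p values" was
interpreted as BH, the standard step-up procedure). Constant bins get
p = 1 by convention. Direction is the sign of the
class-of-interest-minus-reference mean difference; magnitude is the
covariance of the bin with the model's predictive score.

**Tau index.** The "Tau similarity index" has no citable definition in
the source description; it is concretized as the mean Kendall tau-b
rank correlation between a sample's genus-abundance vector and every
other sample's vector — a per-sample community-similarity score. The
implementation sits behind a single exported function so an
alternative definition can be swapped without touching callers.
Constant abundance vectors yield `NA`.

**Clustering and concordance.** Ward linkage (Lance-Williams on
squared dissimilarities, `hclust` method `ward.D2`) on Bray-Curtis
distances of rarefied counts. A patient is *concordant* when the
smallest subtree containing all of that patient's samples contains no
other patient's samples — a private-clade criterion chosen over
same-cluster-at-fixed-k because it matches the notion of samples
"clustering together" independent of where the tree is cut, and it is
invariant to leaf-order permutations.

**Univariate genus tests.** Mann-Whitney U (binary features) or
Kruskal-Wallis (3+ levels) on relative abundances after rarefaction,
BH-corrected. Tests may be restricted to a site subset (`samples=`)
since it is ambiguous whether the original univariate screen used
tumour samples only or all sites; the default uses all supplied
samples. Patient-level features are broadcast to the patient's three
samples.

**Networks.** Metabolite features enter as integrated bucket
intensities over each metabolite's multiplet regions (+/- 0.03 ppm)
on the normalized, unscaled matrix — one value per named metabolite —
rather than all 20000 bins, because the network nodes are named
metabolites. Spearman rho uses midranks; p-values use the
t-approximation, with an exact permutation null available at n <= 10.
Stage subnetworks use all samples of patients in each stage group
(early = T0/T1/T2, T3, T4 by default; configurable), and stage
consistency requires the same signed edge in every group. The
one-sided qPCR alternative (tumour greater) matches the directional
claim being tested; a two-sided option exists.

## The synthetic cohort generator

The generator is first-class, tested code. It emulates:

- **Design**: 18 patients x 3 sites; histology prevalences matching a
  right-sided resection series (T stage 3/1/1/5/8 over T0..T4, N stage
  11/4/3, 15 adenocarcinomas/3 dysplasias, differentiation 1/11/6,
  EMVI 5/18, LVI 6/18, PNVI 1/18, KRAS 2/18), with a mild
  T4-poor-differentiation association toggle.
- **Counts**: a Dirichlet-multinomial composition — per-sample genus
  log-abundance = smooth base gradient + patient-level random effect
  (log-sd 0.6) + planted covariate effects; depths uniform on
  5000-50000 reads over 60 genera. Planted defaults mirror the
  reported enrichment structure (Fusobacterium and Campylobacter up on
  tumour; Bacteroides with EMVI, Roseburia down with LVI,
  Aggregatibacter with KRAS, Streptococcus/Solobacterium/Clostridium
  XI up and Subdoligranulum down with poor differentiation). Read
  depths and genus counts are not reported for the original data, so
  these defaults are explicit config values.
- **Spectra**: sums of 17 metabolite multiplet templates at their
  literature chemical shifts (e.g. lactate doublet 1.33/quartet 4.15,
  taurine 3.26/3.42, alanine doublet 1.47) with Lorentzian lines,
  Pascal's-triangle multiplet ratios, lognormal per-sample dilution
  (log-sd 0.4), lognormal concentration noise (log-sd 0.15), tumour
  log fold-changes signed by the reported direction of each
  metabolite, and additive Gaussian noise. Lineshape, linewidths and
  effect magnitudes are simulator choices; only shifts, multiplicities
  and directions are sourced.
- **qPCR**: `Ct_fn = Ct_pan - log2(ratio) + noise`, with tumour copy
  ratios 4x the 10 cm site by default and perfect per-cycle
  efficiency (an efficiency parameter is exposed; no standard curve
  is modelled).

What the generator does *not* emulate: phasing/baseline artefacts,
water suppression residues, chemical-shift drift with pH, rare-taxon
inflation, chimeras or sequencing error profiles, and replicate
inserts per tissue sample (supported as separate rows but off by
default). Passing tests therefore demonstrate algorithmic
correctness and statistical calibration under a faithful but idealized
data-generating process, not robustness to every artefact of real
tissue data.

## Problem sizes and runtime choices

The test-suite and acceptance computations use the study-scale design
throughout (54 samples, 20000 bins, 60-200 genera), with Monte-Carlo
components sized for stable estimates at interactive runtimes: 100
repetitions for outlier recovery, 200 for network calibration, 500 for
the paired-test type-I rate, 20 seeds for null Q2. All randomness is
derived from explicit seeds; a run seed deterministically derives
stage seeds, and `run_full()` reruns bit-identically for a fixed
config and seed.

## Known limitations

- The headline numbers of the original tissue analysis (AUCs
  0.95-1.0, specific Table p-values, 8/18 concordance) depend on the
  deposited reads and undeposited spectra; this package reproduces the
  *procedures* and validates them by parameter recovery and
  calibration on synthetic cohorts with known truth.
- OPLS-DA is implemented for binary contrasts (one-vs-rest for
  multi-class); ordinal trend models are out of scope.
- Spearman p-values at moderate n rely on the t-approximation; heavy
  ties (many zero counts) make them conservative.
- The Tau index definition is an explicit assumption (see above).
- No partial-correlation or conditional-independence network
  inference: edges are marginal associations.

## A short worked example

```{r example, eval = FALSE}
cfg <- run_config(outdir = "mucometab_demo", seed = 1)
man <- run_full(cfg)
man$results$models$nmr$opls_q2_cv     # cross-validated Q2, tumour vs off
man$results$ecology$concordant_patients
man$results$qpcr$p                    # Fn enrichment on tumour vs 10 cm
```
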