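# mucometab

Integrated metataxonomic + metabonomic analysis of colorectal mucosal
biopsies, as an end-to-end, testable R pipeline.

## What problem this addresses

Colorectal tumours reshape both the mucosal microbiome and the tissue
metabolome. A design that samples each patient on tumour and at 5 cm
and 10 cm off tumour, and profiles the same biopsies by genus-level
16S rRNA sequencing and by 1H magic-angle-spinning (MAS) NMR, lets one
ask three linked questions: how mucosal ecology varies with tumour
site and histology; how well tissue metabolic profiles discriminate
tumour from adjacent mucosa; and which taxa co-vary with which
metabolites on and off the tumour. `mucometab` implements the full
statistical pipeline for that design — for microbiome/metabonomics
researchers who want each stage as a documented, unit-tested function,
and a synthetic cohort generator with known ground truth so every
stage can be validated without access to tissue data.

## The methods at its core

- **Spectral preprocessing**: calibration to the alanine CH3 doublet
  (δ 1.47), binning of δ −1..10 into 20000 bins of 0.00055 ppm,
  exclusion of water/ethanol/PEG windows, probabilistic quotient
  normalization (row area-normalization, median-spectrum reference,
  per-row median quotient), unit-variance scaling, and STOCSY
  (per-bin r and covariance against a driver bin).
- **Supervised projections**: NIPALS PLS-DA on dummy-coded classes;
  OPLS-DA separating class-predictive from orthogonal variation
  (`w_o ∝ p − (wᵀp)w`, orthogonal deflation before the predictive
  component); maximum-margin-criterion projection onto the top
  eigenvectors of `S_b − S_w`; Hotelling T² outlier screening with an
  F-based 95% limit; grouped cross-validation with
  `Q² = 1 − PRESS/TSS`, ROC/AUC by trapezoid, and a BH-corrected
  per-bin ANOVA of pseudo-loadings.
- **Ecology**: rarefaction, Shannon `H = −Σ p ln p`, a Tau similarity
  index (mean pairwise Kendall τ-b), on-tumour normalization per
  patient, Bray-Curtis `Σ|u−v| / Σ(u+v)` with Ward linkage and a
  private-clade patient-concordance criterion, NMDS (Kruskal
  stress-1), Mann-Whitney/Kruskal-Wallis genus-histology tests.
- **qPCR**: ΔCt = Ct_fn − Ct_pan, relative quantity `2^−ΔCt`, paired
  one-sided Wilcoxon for tumour vs 10 cm.
- **Integration**: Spearman correlation of metabolite bucket
  intensities against genus relative abundances, p < 0.05 (or BH)
  edge thresholding into signed tumour/off-tumour networks, stage-wise
  sign-consistent edge intersection, Fruchterman-Reingold layouts.

The methods vignette (`vignettes/mucometab-methods.Rmd`) documents
every convention and numerical choice.

## Worked example

```r
library(mucometab)
man <- run_full(run_config(outdir = "demo_run", seed = 11))
man
#> run_manifest: 6 stages (simulate, nmr, chemometrics, ecology, qpcr, network), seed 11
str(man$results$models$nmr[c("n_retained", "opls_q2_cv", "roc_auc")])
#> List of 3
#>  $ n_retained: int 51
#>  $ opls_q2_cv: num 0.913
#>  $ roc_auc   : num 1
man$results$ecology$concordant_patients
#> [1] 7
signif(man$results$qpcr$p, 3)
#> [1] 7.63e-06
```

Reading: of the 54 simulated biopsies, 3 exceeded the 95% Hotelling T²
limit and were removed (51 retained). The OPLS-DA model of the
spectral matrix separates tumour from off-tumour samples with a
leave-one-patient-out Q² of 0.91 and a cross-validated ROC AUC of 1.0
— the spectral contrast is planted in the simulator, so a strong model
is expected. Seven of 18 patients have all three biopsies forming a
private clade in the Bray-Curtis/Ward dendrogram, and the paired
Wilcoxon test detects the planted 4-fold Fusobacterium nucleatum
enrichment on tumour relative to 10 cm (p ≈ 8 × 10⁻⁶). All artifacts
(OTU TSV, spectra CSV, spectral matrix, dendrogram Newick, NMDS
coordinates, edge tables, manifest with md5 hashes) are written under
`demo_run/`.

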