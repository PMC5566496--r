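#' Metabolite multiplet template
#'
#' A template describes one metabolite as a set of multiplets: each peak
#' has a centre chemical shift, a multiplicity (1 = singlet, 2 =
#' doublet, 3 = triplet, 4 = quartet), a J coupling expressed as line
#' spacing in ppm, and a relative intensity. Lines within a multiplet
#' follow Pascal's-triangle intensity ratios (1; 1:1; 1:2:1; 1:3:3:1)
#' and Lorentzian lineshapes of common half-width.
#'
#' @param name metabolite name.
#' @param peaks data.frame with columns `centre_ppm`, `multiplicity`,
#'   `j_spacing_ppm`, `rel_intensity`.
#' @param linewidth_ppm Lorentzian half-width at half-maximum, ppm.
#' @param tumour_log_fc log fold-change of concentration on tumour
#'   relative to off-tumour samples.
#' @return object of class `metabolite_template`.
#' @export
metabolite_template <- function(name, peaks, linewidth_ppm = 0.004,
                                tumour_log_fc = 0) {
  stopifnot(is.data.frame(peaks),
            all(c("centre_ppm", "multiplicity", "j_spacing_ppm",
                  "rel_intensity") %in% names(peaks)))
  if (any(peaks$centre_ppm < -1 | peaks$centre_ppm > 10))
    stopf("template '%s': peak centres must lie within -1..10 ppm", name)
  if (any(peaks$rel_intensity <= 0))
    stopf("template '%s': relative intensities must be positive", name)
  structure(list(name = name, peaks = peaks, linewidth_ppm = linewidth_ppm,
                 tumour_log_fc = tumour_log_fc),
            class = "metabolite_template")
}

peak_row <- function(centre, mult = 1L, j = 0.0175, rel = 1) {
  data.frame(centre_ppm = centre, multiplicity = mult,
             j_spacing_ppm = j, rel_intensity = rel)
}

#' Default metabolite template panel
#'
#' Seventeen mucosal metabolites with their 1H chemical shift
#' assignments and multiplicities (singlet/doublet/triplet/quartet),
#' e.g. lactate with a doublet at 1.33 ppm and a quartet at 4.15 ppm,
#' taurine at 3.26/3.42 ppm, alanine doublet at 1.47 ppm (the
#' calibration reference). Tumour log fold-changes follow the reported
#' direction of each metabolite in cancer mucosa (taurine, lactate,
#' glycine, choline species up; lipid/triglyceride signals down;
#' creatine, leucine, valine unchanged); magnitudes are simulator
#' choices scaled with reported significance.
#' @export
default_metabolite_templates <- function() {
  list(
    metabolite_template("acetate", peak_row(1.92, 1L), tumour_log_fc = -0.10),
    metabolite_template("alanine", peak_row(1.47, 2L), tumour_log_fc = 0.50),
    metabolite_template("creatine",
      rbind(peak_row(3.02, 1L, rel = 3), peak_row(3.93, 1L, rel = 2)),
      tumour_log_fc = 0),
    metabolite_template("formate", peak_row(8.45, 1L), tumour_log_fc = 0.40),
    metabolite_template("glycerophosphorylcholine", peak_row(3.22, 1L, rel = 9),
      tumour_log_fc = 0.30),
    metabolite_template("glycine", peak_row(3.56, 1L), tumour_log_fc = 0.55),
    metabolite_template("isobutyrate", peak_row(1.00, 2L, rel = 6),
      tumour_log_fc = -0.10),
    metabolite_template("isoglutamine", peak_row(2.34, 3L), tumour_log_fc = 0.40),
    metabolite_template("lactate",
      rbind(peak_row(1.33, 2L, rel = 3), peak_row(4.15, 4L, rel = 1)),
      tumour_log_fc = 0.70),
    metabolite_template("leucine", peak_row(1.72, 3L), tumour_log_fc = 0),
    metabolite_template("lipid_unsaturated", peak_row(2.02, 1L, rel = 4),
      linewidth_ppm = 0.012, tumour_log_fc = -0.45),
    metabolite_template("lipid_ch2", peak_row(1.29, 1L, rel = 12),
      linewidth_ppm = 0.015, tumour_log_fc = -0.60),
    metabolite_template("lipid_ch3", peak_row(0.90, 1L, rel = 6),
      linewidth_ppm = 0.012, tumour_log_fc = -0.55),
    metabolite_template("phosphocholine",
      rbind(peak_row(3.22, 1L, rel = 9), peak_row(4.19, 3L, rel = 2)),
      tumour_log_fc = 0.45),
    metabolite_template("scylloinositol", peak_row(3.34, 1L, rel = 6),
      tumour_log_fc = 0.10),
    metabolite_template("taurine",
      rbind(peak_row(3.26, 3L, rel = 2), peak_row(3.42, 3L, rel = 2)),
      tumour_log_fc = 0.70),
    metabolite_template("valine",
      rbind(peak_row(1.02, 2L, rel = 3), peak_row(0.98, 2L, rel = 3)),
      tumour_log_fc = 0)
  )
}

# Evaluate one template at unit concentration on a ppm axis.
evaluate_template <- function(tpl, ppm) {
  y <- numeric(length(ppm))
  hw <- tpl$linewidth_ppm
  for (r in seq_len(nrow(tpl$peaks))) {
    pk <- tpl$peaks[r, ]
    m <- pk$multiplicity
    w <- choose(m - 1, 0:(m - 1))
    w <- w / sum(w)
    offs <- (0:(m - 1) - (m - 1) / 2) * pk$j_spacing_ppm
    for (l in seq_len(m)) {
      c0 <- pk$centre_ppm + offs[l]
      # Lorentzian normalized to unit height at centre
      y <- y + pk$rel_intensity * w[l] * hw^2 / ((ppm - c0)^2 + hw^2)
    }
  }
  y
}

#' Simulate a set of 1H spectra from metabolite templates
#'
#' Each spectrum is `dilution_i * sum_m conc_im * multiplet(template_m)
#' + Gaussian noise`, with multiplets rendered as Lorentzian line sums.
#' Concentrations are `base * exp(tumour_log_fc)` on tumour samples,
#' perturbed per sample by lognormal noise of log-sd `conc_log_sd`;
#' dilution factors are lognormal with log-sd `dilution_log_sd`. All
#' ground truth (concentrations, dilutions) is returned.
#'
#' @param meta metadata (needs `sample_id` and `site`; samples at the
#'   first site are treated as tumour unless `tumour_site` says otherwise).
#' @param templates list of [metabolite_template()]s.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param dilution_log_sd log-sd of the per-sample dilution factor.
#' @param conc_log_sd per-sample lognormal concentration noise.
#' @param base_conc named or unnamed vector of baseline concentrations
#'   (recycled over templates).
#' @param ppm_range,ppm_step raw acquisition axis.
#' @param tumour_site site label counted as tumour.
#' @param calibration_shift_sd sd of a per-sample random ppm axis shift
#'   (simulates miscalibration; 0 disables).
#' @param seed integer seed.
#' @return list with `spectra` (a `spectrum_set`) and `truth`
#'   (dilution factors, concentration matrix, class labels, axis shifts).
#' @export
simulate_spectra <- function(meta, templates = default_metabolite_templates(),
                             noise_sd = 0.02, dilution_log_sd = 0.4,
                             conc_log_sd = 0.15, base_conc = 1,
                             ppm_range = c(-1, 10), ppm_step = 0.0005,
                             tumour_site = "tumour",
                             calibration_shift_sd = 0, seed = 1L) {
  if (length(templates) == 0) stopf("templates must be non-empty")
  set.seed(seed)
  n <- nrow(meta)
  m <- length(templates)
  ppm <- seq(ppm_range[1], ppm_range[2], by = ppm_step)
  basis <- vapply(templates, evaluate_template, numeric(length(ppm)), ppm = ppm)
  base <- rep_len(base_conc, m)
  is_tum <- as.character(meta$site) == tumour_site
  lfc <- vapply(templates, function(t) t$tumour_log_fc, numeric(1))
  conc <- matrix(rep(base, each = n), n, m)
  conc <- conc * exp(outer(is_tum, lfc)) *
    matrix(exp(stats::rnorm(n * m, 0, conc_log_sd)), n, m)
  dil <- exp(stats::rnorm(n, 0, dilution_log_sd))
  shifts <- if (calibration_shift_sd > 0)
    stats::rnorm(n, 0, calibration_shift_sd) else numeric(n)
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    y <- dil[i] * as.numeric(basis %*% conc[i, ])
    if (noise_sd > 0) y <- y + stats::rnorm(length(ppm), 0, noise_sd)
    spectra[[i]] <- spectrum(ppm + shifts[i], y, meta$sample_id[i])
  }
  names(spectra) <- meta$sample_id
  truth <- list(
    dilution_factors = stats::setNames(dil, meta$sample_id),
    concentrations = structure(conc, dimnames = list(
      meta$sample_id, vapply(templates, `[[`, "", "name"))),
    class_labels = stats::setNames(ifelse(is_tum, "tumour", "off"), meta$sample_id),
    axis_shifts = stats::setNames(shifts, meta$sample_id)
  )
  list(spectra = spectrum_set(spectra), truth = truth)
}
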