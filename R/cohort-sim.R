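#' Configuration for a synthetic mucosal biopsy cohort
#'
#' Describes the sampling design emulated by the simulator: a number of
#' patients each biopsied at an ordered set of mucosal sites (on tumour,
#' 5 cm and 10 cm off tumour by default), with patient-level histology
#' features drawn from configurable prevalences.
#'
#' The default prevalences reproduce the structure of a typical
#' right-sided colorectal cancer resection series of 18 patients:
#' mostly T3/T4 tumours, a minority with nodal disease, EMVI, LVI,
#' perineural invasion or KRAS mutation.
#'
#' @param n_patients number of patients (>= 2).
#' @param sites character vector of unique site labels, first label is
#'   the tumour site used for on-tumour normalization downstream.
#' @param seed integer seed for metadata generation.
#' @param histology_prevalences named list of per-feature probabilities:
#'   `emvi`, `lvi`, `pnvi`, `kras` are Bernoulli probabilities;
#'   `t_stage`, `n_stage`, `differentiation`, `subtype` are named
#'   probability vectors over their levels.
#' @param stage_diff_association logical; when TRUE, poorly
#'   differentiated histology is made more likely for T4 tumours (a mild
#'   positive dependence mirroring the co-occurrence of advanced stage
#'   and poor differentiation in resection series).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 18L,
                          sites = c("tumour", "5cm", "10cm"),
                          seed = 1L,
                          histology_prevalences = default_histology_prevalences(),
                          stage_diff_association = TRUE) {
  if (n_patients < 2) stopf("n_patients must be >= 2, got %d", n_patients)
  if (anyDuplicated(sites)) stopf("site labels must be unique")
  pr <- histology_prevalences
  flat <- unlist(pr)
  if (any(flat < 0 | flat > 1)) stopf("all prevalences must lie in [0, 1]")
  for (nm in c("t_stage", "n_stage", "differentiation", "subtype")) {
    if (abs(sum(pr[[nm]]) - 1) > 1e-8)
      stopf("prevalences for '%s' must sum to 1", nm)
  }
  structure(list(n_patients = as.integer(n_patients), sites = sites,
                 seed = as.integer(seed), histology_prevalences = pr,
                 stage_diff_association = isTRUE(stage_diff_association)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_histology_prevalences <- function() {
  list(
    t_stage = c(T0 = 3, T1 = 1, T2 = 1, T3 = 5, T4 = 8) / 18,
    n_stage = c(N0 = 11, N1 = 4, N2 = 3) / 18,
    subtype = c(adenocarcinoma = 15, dysplasia = 3) / 18,
    differentiation = c(well = 1, moderate = 11, poor = 6) / 18,
    emvi = 5 / 18, lvi = 6 / 18, pnvi = 1 / 18, kras = 2 / 18
  )
}

#' Simulate per-sample metadata for a synthetic cohort
#'
#' Draws patient-level histology features once per patient and expands
#' them across that patient's biopsy sites, so every feature is constant
#' within patient. Deterministic under the config seed.
#'
#' @param cfg a [cohort_config()].
#' @return a `data.frame` with one row per sample: `sample_id`,
#'   `patient_id`, `site`, and histology columns (`t_stage`, `n_stage`,
#'   `subtype`, `differentiation`, `emvi`, `lvi`, `pnvi`, `kras`;
#'   binary features coded 0/1). The class labels (tumour vs off-tumour)
#'   derivable from `site` constitute the simulation ground truth.
#' @export
simulate_metadata <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  pr <- cfg$histology_prevalences
  n <- cfg$n_patients
  set.seed(cfg$seed)
  draw_cat <- function(p, n) sample(names(p), n, replace = TRUE, prob = p)
  t_stage <- draw_cat(pr$t_stage, n)
  diffn <- character(n)
  for (i in seq_len(n)) {
    p <- pr$differentiation
    if (cfg$stage_diff_association && t_stage[i] == "T4") {
      # tilt towards poor differentiation for T4 lesions
      p <- p * c(well = 0.5, moderate = 0.8, poor = 2)[names(p)]
      p <- p / sum(p)
    }
    diffn[i] <- draw_cat(p, 1)
  }
  pat <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    t_stage = t_stage,
    n_stage = draw_cat(pr$n_stage, n),
    subtype = draw_cat(pr$subtype, n),
    differentiation = diffn,
    emvi = as.integer(stats::runif(n) < pr$emvi),
    lvi = as.integer(stats::runif(n) < pr$lvi),
    pnvi = as.integer(stats::runif(n) < pr$pnvi),
    kras = as.integer(stats::runif(n) < pr$kras),
    stringsAsFactors = FALSE
  )
  meta <- pat[rep(seq_len(n), each = length(cfg$sites)), , drop = FALSE]
  meta$site <- rep(cfg$sites, times = n)
  meta$sample_id <- paste0(meta$patient_id, "_", meta$site)
  rownames(meta) <- NULL
  meta <- meta[, c("sample_id", "patient_id", "site", "t_stage", "n_stage",
                   "subtype", "differentiation", "emvi", "lvi", "pnvi", "kras")]
  meta
}

#' Configuration for the compositional OTU count simulator
#'
#' Counts follow a Dirichlet-multinomial style model: per-sample genus
#' log-abundances are `base + patient effect + sum of planted effects`,
#' converted to expected proportions by softmax, perturbed by a
#' Dirichlet draw with concentration `softmax(log-abundance) /
#' overdispersion`, and realized as multinomial counts at a
#' uniformly-drawn sequencing depth.
#'
#' @param n_taxa number of genera.
#' @param genus_names optional genus labels (length `n_taxa`); defaults
#'   to a panel of common gut genera.
#' @param base_log_abundances baseline log-abundance per genus.
#' @param patient_effect_sd sd of the patient-level random effect
#'   (lognormal, shared by all samples of a patient, per genus).
#' @param planted_effects list of planted log-fold-change effects, each
#'   `list(taxon=, covariate=, level=, lfc=)`: the lfc is added to the
#'   taxon's log-abundance in samples whose metadata column `covariate`
#'   equals `level`.
#' @param depth_range integer `(min, max)` sequencing depth.
#' @param overdispersion Dirichlet overdispersion (0 = multinomial at
#'   the expected proportions; larger = noisier compositions).
#' @return an object of class `otu_sim_config`.
#' @export
otu_sim_config <- function(n_taxa = 60L,
                           genus_names = NULL,
                           base_log_abundances = NULL,
                           patient_effect_sd = 0.6,
                           planted_effects = default_planted_effects(),
                           depth_range = c(5000L, 50000L),
                           overdispersion = 0.02) {
  if (is.null(genus_names)) genus_names <- default_genus_names(n_taxa)
  if (length(genus_names) != n_taxa) stopf("genus_names must have length n_taxa")
  if (is.null(base_log_abundances)) {
    # smooth abundance gradient spanning ~4 nats, dominant genera first
    base_log_abundances <- seq(4, 0, length.out = n_taxa)
  }
  if (length(base_log_abundances) != n_taxa)
    stopf("base_log_abundances must have length n_taxa")
  if (depth_range[1] < n_taxa)
    stopf("minimum depth (%d) must be >= n_taxa (%d)", depth_range[1], n_taxa)
  if (patient_effect_sd < 0 || overdispersion < 0)
    stopf("patient_effect_sd and overdispersion must be nonnegative")
  for (pe in planted_effects) {
    if (!pe$taxon %in% genus_names)
      stopf("planted effect names unknown taxon '%s'", pe$taxon)
  }
  structure(list(n_taxa = as.integer(n_taxa), genus_names = genus_names,
                 base_log_abundances = base_log_abundances,
                 patient_effect_sd = patient_effect_sd,
                 planted_effects = planted_effects,
                 depth_range = as.integer(depth_range),
                 overdispersion = overdispersion),
            class = "otu_sim_config")
}

#' @rdname otu_sim_config
#' @export
default_genus_names <- function(n_taxa = 60L) {
  panel <- c(
    "Bacteroides", "Prevotella", "Paraprevotella", "Alistipes",
    "Parabacteroides", "Faecalibacterium", "Roseburia", "Blautia",
    "Lachnospiracea_incertae_sedis", "Clostridium_XI", "Clostridium_XIVa",
    "Clostridium_sensu_stricto", "Ruminococcus", "Subdoligranulum",
    "Streptococcus", "Solobacterium", "Enterococcus", "Lactobacillus",
    "Veillonella", "Dialister", "Fusobacterium", "Leptotrichia",
    "Escherichia_Shigella", "Salmonella", "Sutterella", "Parasutterella",
    "Aggregatibacter", "Haemophilus", "Campylobacter", "Helicobacter",
    "Shewanella", "Acidovorax", "Comamonas", "Neisseria", "Akkermansia",
    "Bifidobacterium", "Collinsella", "Eggerthella", "Anaerostipes",
    "Butyricicoccus", "Coprococcus", "Dorea", "Eubacterium",
    "Oscillibacter", "Phascolarctobacterium", "Megasphaera",
    "Acidaminococcus", "Desulfovibrio", "Bilophila", "Granulicatella",
    "Gemella", "Rothia", "Actinomyces", "Porphyromonas", "Peptostreptococcus",
    "Parvimonas", "Finegoldia", "Anaerococcus", "Odoribacter", "Barnesiella"
  )
  if (n_taxa <= length(panel)) return(panel[seq_len(n_taxa)])
  c(panel, sprintf("Genus%03d", seq_len(n_taxa - length(panel))))
}

#' Default planted genus-covariate enrichments
#'
#' Mirrors the qualitative enrichment structure reported for colorectal
#' mucosa: Fusobacterium (and epsilon-proteobacteria) up on tumour,
#' Bacteroides up with EMVI, Roseburia down with LVI, Aggregatibacter up
#' with KRAS mutation, Streptococcus/Solobacterium/Clostridium XI up and
#' Subdoligranulum down in poorly differentiated tumours.
#' @export
default_planted_effects <- function() {
  list(
    list(taxon = "Fusobacterium", covariate = "site", level = "tumour", lfc = 1.4),
    list(taxon = "Campylobacter", covariate = "site", level = "tumour", lfc = 1.0),
    list(taxon = "Bacteroides", covariate = "emvi", level = "1", lfc = 0.8),
    list(taxon = "Roseburia", covariate = "lvi", level = "1", lfc = -0.9),
    list(taxon = "Aggregatibacter", covariate = "kras", level = "1", lfc = 1.2),
    list(taxon = "Streptococcus", covariate = "differentiation", level = "poor", lfc = 0.9),
    list(taxon = "Solobacterium", covariate = "differentiation", level = "poor", lfc = 1.0),
    list(taxon = "Clostridium_XI", covariate = "differentiation", level = "poor", lfc = 0.8),
    list(taxon = "Subdoligranulum", covariate = "differentiation", level = "poor", lfc = -0.9),
    list(taxon = "Fusobacterium", covariate = "differentiation", level = "poor", lfc = 0.8)
  )
}

#' Simulate a genus-level OTU count table with known ground truth
#'
#' @param meta metadata as returned by [simulate_metadata()].
#' @param cfg an [otu_sim_config()].
#' @param seed integer seed.
#' @return a list with `otu` (an [otu_table()]) and `truth` (planted
#'   effects, per-sample expected proportions and depths).
#' @export
simulate_otu_table <- function(meta, cfg = otu_sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "otu_sim_config"), nrow(meta) >= 1)
  set.seed(seed)
  n <- nrow(meta)
  k <- cfg$n_taxa
  patients <- unique(meta$patient_id)
  pat_eff <- matrix(stats::rnorm(length(patients) * k, 0, cfg$patient_effect_sd),
                    nrow = length(patients), dimnames = list(patients, NULL))
  loga <- matrix(rep(cfg$base_log_abundances, each = n), nrow = n)
  loga <- loga + pat_eff[meta$patient_id, , drop = FALSE]
  for (pe in cfg$planted_effects) {
    if (!pe$covariate %in% names(meta))
      stopf("planted effect references unknown covariate '%s'", pe$covariate)
    j <- match(pe$taxon, cfg$genus_names)
    hit <- as.character(meta[[pe$covariate]]) == as.character(pe$level)
    loga[hit, j] <- loga[hit, j] + pe$lfc
  }
  expected_p <- t(apply(loga, 1, softmax))
  depths <- if (cfg$depth_range[1] == cfg$depth_range[2])
    rep(cfg$depth_range[1], n)
  else
    sample(seq(cfg$depth_range[1], cfg$depth_range[2]), n, replace = TRUE)
  counts <- matrix(0L, n, k, dimnames = list(meta$sample_id, cfg$genus_names))
  for (i in seq_len(n)) {
    p <- expected_p[i, ]
    if (cfg$overdispersion > 0) {
      g <- stats::rgamma(k, shape = p / cfg$overdispersion, rate = 1)
      if (sum(g) > 0) p <- g / sum(g)
    }
    counts[i, ] <- as.integer(stats::rmultinom(1, depths[i], p))
  }
  otu <- otu_table(counts, patient_ids = meta$patient_id, sites = meta$site)
  truth <- list(planted_effects = cfg$planted_effects,
                expected_proportions = expected_p, depths = depths)
  list(otu = otu, truth = truth)
}

#' Simulate a qPCR Ct table from known copy ratios
#'
#' The target Ct is derived from the pan-bacterial Ct by the exact
#' amplification relationship `Ct_target = Ct_pan - log2(ratio) + noise`,
#' i.e. Ct is inversely proportional to log copy number, so smaller
#' differences mean greater relative target quantity.
#'
#' @param meta metadata (one row per sample).
#' @param copy_ratio_model either a numeric vector of per-sample copy
#'   ratios (target/pan, named by sample or in metadata order), or a
#'   list with `base` (ratio at the last site), `site_fold` (named
#'   multiplier per site) and `log2_sd` (per-sample lognormal spread).
#' @param seed integer seed.
#' @param ct_pan_mean,ct_pan_sd distribution of the pan-bacterial Ct.
#' @param noise_sd Gaussian cycle noise added to the target Ct.
#' @return list with `ct` (data.frame `sample_id`, `target` in
#'   `{fn, pan}`, `ct`) and `truth` (per-sample copy ratios).
#' @export
simulate_qpcr <- function(meta,
                          copy_ratio_model = list(base = 0.002,
                                                  site_fold = c(tumour = 4, `5cm` = 1.5, `10cm` = 1),
                                                  log2_sd = 1),
                          seed = 1L, ct_pan_mean = 18, ct_pan_sd = 1,
                          noise_sd = 0.3) {
  set.seed(seed)
  n <- nrow(meta)
  if (is.numeric(copy_ratio_model)) {
    ratios <- rep(copy_ratio_model, length.out = n)
  } else {
    m <- copy_ratio_model
    fold <- m$site_fold[as.character(meta$site)]
    if (anyNA(fold)) stopf("copy_ratio_model$site_fold missing a site level")
    ratios <- m$base * fold * 2^stats::rnorm(n, 0, m$log2_sd %||% 0)
  }
  if (any(ratios <= 0)) stopf("copy ratios must be positive")
  ct_pan <- stats::rnorm(n, ct_pan_mean, ct_pan_sd)
  ct_fn <- ct_pan - log2(ratios) + stats::rnorm(n, 0, noise_sd)
  ct <- data.frame(
    sample_id = rep(meta$sample_id, 2),
    target = rep(c("fn", "pan"), each = n),
    ct = c(ct_fn, ct_pan),
    stringsAsFactors = FALSE
  )
  list(ct = ct, truth = list(copy_ratios = stats::setNames(ratios, meta$sample_id)))
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper chaining [simulate_metadata()],
#' [simulate_otu_table()], [simulate_spectra()] and [simulate_qpcr()]
#' with stage seeds derived deterministically from one run seed.
#'
#' @param cfg a [cohort_config()].
#' @param otu_cfg an [otu_sim_config()].
#' @param templates metabolite templates for the spectra.
#' @param seed run seed.
#' @param ... further arguments passed to [simulate_spectra()].
#' @return list with `meta`, `otu`, `spectra`, `ct` and per-stage `truth`.
#' @export
simulate_cohort <- function(cfg = cohort_config(), otu_cfg = otu_sim_config(),
                            templates = default_metabolite_templates(),
                            seed = 1L, ...) {
  cfg$seed <- derive_seed(seed, 1L)
  meta <- simulate_metadata(cfg)
  otu <- simulate_otu_table(meta, otu_cfg, seed = derive_seed(seed, 2L))
  sp <- simulate_spectra(meta, templates, seed = derive_seed(seed, 3L), ...)
  qp <- simulate_qpcr(meta, seed = derive_seed(seed, 4L))
  list(meta = meta, otu = otu$otu, spectra = sp$spectra, ct = qp$ct,
       truth = list(otu = otu$truth, spectra = sp$truth, qpcr = qp$truth))
}
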