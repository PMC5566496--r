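#' Configuration for an end-to-end pipeline run
#'
#' In simulate mode (default) the cohort is generated; otherwise the
#' four input files are read from `paths`.
#'
#' @param outdir output directory (created if absent).
#' @param seed run seed; stage seeds are derived from it.
#' @param simulate generate the cohort instead of reading files.
#' @param paths named list of input files (`otu`, `spectra`, `meta`,
#'   `ct`) for non-simulate mode.
#' @param cohort a [cohort_config()] (simulate mode).
#' @param otu_cfg an [otu_sim_config()] (simulate mode).
#' @param templates metabolite templates (simulation + bucket
#'   integration).
#' @param exclusion_regions spectral exclusion windows.
#' @param model_targets histology columns modelled by PLS-DA on the
#'   OTU data.
#' @param alpha,fdr network edge threshold and whether it applies to
#'   BH q-values.
#' @param n_clusters clusters for the Ward cut.
#' @param nmds_restarts NMDS random restarts.
#' @param stage_map named list mapping stage-group labels to T-stage
#'   levels for the per-stage networks.
#' @param max_orthogonal largest orthogonal component count tried for
#'   the OPLS model.
#' @return object of class `run_config`.
#' @export
run_config <- function(outdir = tempfile("mucometab_run_"), seed = 1L,
                       simulate = TRUE, paths = NULL,
                       cohort = cohort_config(), otu_cfg = otu_sim_config(),
                       templates = default_metabolite_templates(),
                       exclusion_regions = default_exclusion_regions(),
                       model_targets = c("emvi", "lvi", "kras", "differentiation"),
                       alpha = 0.05, fdr = FALSE, n_clusters = 3L,
                       nmds_restarts = 20L,
                       stage_map = list(early = c("T0", "T1", "T2"),
                                        T3 = "T3", T4 = "T4"),
                       max_orthogonal = 2L) {
  if (!simulate) {
    need <- c("otu", "spectra", "meta", "ct")
    miss <- setdiff(need, names(paths %||% list()))
    if (length(miss)) stopf("paths must name: %s", paste(miss, collapse = ", "))
    for (p in paths[need]) if (!file.exists(p)) stopf("input file not found: %s", p)
  }
  structure(list(outdir = outdir, seed = as.integer(seed), simulate = simulate,
                 paths = paths, cohort = cohort, otu_cfg = otu_cfg,
                 templates = templates, exclusion_regions = exclusion_regions,
                 model_targets = model_targets, alpha = alpha, fdr = fdr,
                 n_clusters = as.integer(n_clusters),
                 nmds_restarts = as.integer(nmds_restarts),
                 stage_map = stage_map,
                 max_orthogonal = as.integer(max_orthogonal)),
            class = "run_config")
}

# choose the orthogonal component count maximizing leave-one-patient-out Q2
select_n_orthogonal <- function(X, labels, groups, max_orthogonal = 2L) {
  q2 <- vapply(0:max_orthogonal, function(no)
    cross_validate(X, labels, kind = "oplsda", scheme = "lopo",
                   groups = groups, scale = FALSE, n_orthogonal = no)$q2,
    numeric(1))
  list(n_orthogonal = which.max(q2) - 1L, q2 = q2)
}

#' Run the full analysis pipeline
#'
#' Chains simulate/ingest, NMR preprocessing, supervised modelling,
#' mucosal ecology, qPCR quantification and network integration,
#' writing every artifact plus a manifest of parameters, seeds and
#' md5 hashes. Any stage failure aborts with a stage-named error.
#'
#' @param cfg a [run_config()].
#' @return object of class `run_manifest` (invisibly also written to
#'   `manifest.json`): per-stage parameters, outputs and hashes, plus
#'   the key results (`results` field).
#' @export
run_full <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, stages = list())
  results <- list()
  out <- function(...) file.path(cfg$outdir, ...)
  record <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      parameters = params, outputs = basename(files),
      md5 = as.list(tools::md5sum(files)), seed = derive_seed(cfg$seed, length(manifest$stages)))
  }
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  ## 1. simulate / ingest ----
  wrap("simulate", {
    if (cfg$simulate) {
      sim <- simulate_cohort(cfg$cohort, cfg$otu_cfg, cfg$templates,
                             seed = cfg$seed)
      meta <- sim$meta; otu <- sim$otu; spectra <- sim$spectra; ct <- sim$ct
      jsonlite::write_json(
        list(dilution_factors = as.list(sim$truth$spectra$dilution_factors),
             qpcr_copy_ratios = as.list(sim$truth$qpcr$copy_ratios)),
        out("truth.json"), auto_unbox = TRUE, digits = NA)
    } else {
      meta <- read_metadata(cfg$paths$meta)
      otu <- read_otu_table(cfg$paths$otu, meta)
      spectra <- read_spectra(cfg$paths$spectra)
      ct <- read_ct(cfg$paths$ct)
    }
    write_metadata(meta, out("metadata.csv"))
    write_otu_table(otu, out("otu.tsv"))
    write_ct(ct, out("ct.csv"))
    files <- out(c("metadata.csv", "otu.tsv", "ct.csv"))
    if (cfg$simulate) files <- c(files, out("truth.json"))
    record("simulate", list(simulate = cfg$simulate,
                            n_samples = nrow(meta)), files)
  })
  ## 2. NMR preprocessing ----
  wrap("nmr", {
    cal <- calibrate_to_alanine(spectra)
    sm <- bin_spectra(cal)
    sm <- apply_exclusions(sm, cfg$exclusion_regions)
    sm_norm <- pqn_normalize(sm)
    sm_uv <- unit_variance_scale(sm_norm)
    utils::write.csv(data.frame(sample_id = sm_norm$sample_ids,
                                dilution_factor = signif(sm_norm$dilution_factors, 8)),
                     out("dilution_factors.csv"), row.names = FALSE, quote = FALSE)
    write_spectral_matrix(sm_uv, out("spectral_matrix.tsv"))
    record("nmr", list(bins = length(sm$bins),
                       regions = length(cfg$exclusion_regions)),
           out(c("dilution_factors.csv", "spectral_matrix.tsv")))
    results$n_bins_retained <- length(sm$bins)
  })

  ## 3. chemometrics ----
  wrap("chemometrics", {
    # NMR: outlier screen, then tumour vs off-tumour models
    idx <- match(sm_uv$sample_ids, meta$sample_id)
    tissue <- ifelse(meta$site[idx] == "tumour", "tumour", "off")
    pca <- fit_pca(sm_uv, n_components = 3)
    scr <- remove_outliers(sm_uv, pca)
    keep <- setdiff(sm_uv$sample_ids, scr$removed)
    ki <- match(keep, sm_uv$sample_ids)
    Xn <- sm_norm$X[ki, , drop = FALSE]
    lab <- tissue[ki]
    grp <- meta$patient_id[idx][ki]
    # scale once (full-data model); CV rescales per fold from raw
    mu <- colMeans(Xn); sdv <- col_sds(Xn); sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(Xn, 2, mu), 2, sdv, "/")
    sel <- select_n_orthogonal(Xs, lab, grp, cfg$max_orthogonal)
    opls <- fit_oplsda(Xs, lab, n_orthogonal = sel$n_orthogonal,
                       positive = "tumour")
    opls_cv <- cross_validate(Xn, lab, kind = "oplsda", scheme = "lopo",
                              groups = grp, scale = TRUE,
                              n_orthogonal = sel$n_orthogonal,
                              positive = "tumour")
    mmc_cv <- cross_validate(Xn, lab, kind = "mmc", scheme = "lopo",
                             groups = grp, scale = TRUE, n_components = 2,
                             positive = "tumour")
    nmr_roc <- roc_auc(opls_cv$predictions$score, lab, positive = "tumour")
    pl <- pseudo_loadings_anova(
      spectral_matrix(Xs, sm_uv$bins, flags = sm_uv$flags), lab,
      scores = as.numeric(opls$scores),
      class_of_interest = "tumour", reference = "off")
    utils::write.table(
      transform(pl, magnitude = signif(magnitude, 6),
                p = signif(p, 6), q = signif(q, 6)),
      out("nmr_pseudo_loadings.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    # OTU: one PLS-DA per histology target, leave-one-sample-out
    ra <- relative_abundance(otu)
    oidx <- match(rownames(ra), meta$sample_id)
    otu_models <- list()
    for (tg in cfg$model_targets) {
      y <- as.character(meta[[tg]][oidx])
      if (length(unique(y)) < 2) next
      cv <- cross_validate(ra, y, kind = "plsda", scheme = "loso",
                           scale = TRUE, n_components = 2)
      pos <- cv$positive
      auc <- if (length(unique(y)) == 2)
        roc_auc(cv$predictions$score, y, positive = pos)$auc else NA_real_
      otu_models[[tg]] <- list(target = tg, q2 = cv$q2,
                               accuracy = cv$accuracy, auc = auc)
    }
    model_summary <- list(
      nmr = list(outliers_removed = as.list(scr$removed),
                 n_retained = length(keep),
                 n_orthogonal = sel$n_orthogonal,
                 opls_q2_cv = opls_cv$q2, opls_accuracy_cv = opls_cv$accuracy,
                 mmc_q2_cv = mmc_cv$q2, mmc_accuracy_cv = mmc_cv$accuracy,
                 roc_auc = nmr_roc$auc),
      otu = otu_models)
    jsonlite::write_json(model_summary, out("models.json"),
                         auto_unbox = TRUE, digits = NA)
    record("chemometrics",
           list(targets = cfg$model_targets, n_orthogonal = sel$n_orthogonal),
           out(c("models.json", "nmr_pseudo_loadings.tsv")))
    results$models <- model_summary
  })

  ## 4. ecology ----
  wrap("ecology", {
    rar <- rarefy(otu, seed = derive_seed(cfg$seed, 41L))
    shan <- shannon_index(rar)
    tau <- tau_index(rar)
    if (!("tumour" %in% unique(rar$sites)))
      stopf("no tumour samples present for patients: %s",
            paste(unique(rar$patient_ids), collapse = ", "))
    shan_norm <- normalize_index_to_tumour(shan, rar$patient_ids, rar$sites)
    tau_norm <- normalize_index_to_tumour(tau, rar$patient_ids, rar$sites)
    utils::write.csv(
      data.frame(sample_id = rar$sample_ids, site = rar$sites,
                 shannon = signif(shan, 8), tau = signif(tau, 8),
                 shannon_norm = signif(shan_norm, 8),
                 tau_norm = signif(tau_norm, 8)),
      out("ecology_indices.csv"), row.names = FALSE, quote = FALSE)
    D <- bray_curtis(rar)
    utils::write.table(signif(D, 8), out("bray_curtis.tsv"), sep = "\t",
                       quote = FALSE)
    dend <- ward_cluster(D, k = cfg$n_clusters)
    write_dendrogram(dend, out("dendrogram.nwk"))
    conc <- patient_concordance(dend, rar$patient_ids)
    ord <- nmds(D, k = 2, n_restarts = cfg$nmds_restarts,
                seed = derive_seed(cfg$seed, 42L))
    utils::write.csv(
      data.frame(sample_id = rownames(ord$coordinates),
                 signif(ord$coordinates, 8)),
      out("nmds.csv"), row.names = FALSE, quote = FALSE)
    midx <- match(rar$sample_ids, meta$sample_id)
    tests <- lapply(cfg$model_targets, function(tg) {
      tt <- taxon_feature_tests(rar, as.character(meta[[tg]][midx]))
      tt$feature <- tg
      tt
    })
    tests <- do.call(rbind, tests)
    utils::write.table(
      transform(tests, p = signif(p, 6), q = signif(q, 6)),
      out("taxon_tests.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    feat <- meta[midx, intersect(c("t_stage", "n_stage", "subtype",
                                   "differentiation", "emvi", "lvi"),
                                 names(meta)), drop = FALSE]
    feat <- feat[, vapply(feat, function(v) length(unique(v)) > 1, TRUE),
                 drop = FALSE]
    assoc <- cluster_feature_association(dend$clusters, feat)
    utils::write.csv(transform(assoc, p = signif(p, 6)),
                     out("cluster_associations.csv"),
                     row.names = FALSE, quote = FALSE)
    record("ecology",
           list(depth = min(rowSums(otu$counts)), k = cfg$n_clusters,
                nmds_stress = ord$stress),
           out(c("ecology_indices.csv", "bray_curtis.tsv", "dendrogram.nwk",
                 "nmds.csv", "taxon_tests.tsv", "cluster_associations.csv")))
    results$ecology <- list(concordant_patients = conc$count,
                            n_patients = length(conc$concordant),
                            nmds_stress = ord$stress)
  })

  ## 5. qPCR ----
  wrap("qpcr", {
    dq <- delta_ct(ct)
    qidx <- match(dq$quant$sample_id, meta$sample_id)
    cmp <- site_comparison(dq$quant, meta$patient_id[qidx], meta$site[qidx])
    utils::write.csv(transform(dq$quant, delta_ct = signif(delta_ct, 8),
                               rel_quantity = signif(rel_quantity, 8)),
                     out("qpcr_quant.csv"), row.names = FALSE, quote = FALSE)
    jsonlite::write_json(cmp, out("qpcr_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    record("qpcr", list(alternative = cmp$alternative),
           out(c("qpcr_quant.csv", "qpcr_comparison.json")))
    results$qpcr <- cmp
  })

  ## 6. network integration ----
  wrap("network", {
    buckets <- metabolite_buckets(sm_norm, cfg$templates)
    ra_all <- relative_abundance(otu)
    common <- intersect(rownames(buckets), rownames(ra_all))
    bidx <- match(common, meta$sample_id)
    is_t <- meta$site[bidx] == "tumour"
    build <- function(sel) {
      cr <- correlate(buckets[common[sel], , drop = FALSE],
                      ra_all[common[sel], , drop = FALSE])
      threshold_network(cr$rho, cr$p, alpha = cfg$alpha, fdr = cfg$fdr)
    }
    net_t <- build(is_t)
    net_o <- build(!is_t)
    cmp <- compare_networks(net_t, net_o)
    write_edge_set(net_t, out("network_tumour.tsv"))
    write_edge_set(net_o, out("network_off.tsv"))
    lay <- spring_layout(net_t, seed = derive_seed(cfg$seed, 61L))
    utils::write.csv(transform(lay$coordinates, x = signif(x, 8),
                               y = signif(y, 8)),
                     out("network_layout.csv"), row.names = FALSE, quote = FALSE)
    stage_nets <- list()
    for (sg in names(cfg$stage_map)) {
      sel <- meta$t_stage[bidx] %in% cfg$stage_map[[sg]]
      if (sum(sel) >= 4) stage_nets[[sg]] <- build(sel)
    }
    consistent <- if (length(stage_nets) >= 2)
      stage_consistency(stage_nets) else NULL
    if (!is.null(consistent))
      utils::write.table(consistent, out("stage_consistent_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    files <- out(c("network_tumour.tsv", "network_off.tsv",
                   "network_layout.csv"))
    if (!is.null(consistent)) files <- c(files, out("stage_consistent_edges.tsv"))
    record("network", list(alpha = cfg$alpha, fdr = cfg$fdr,
                           stages = names(stage_nets)), files)
    results$network <- list(
      tumour_edges = nrow(net_t$edges), off_edges = nrow(net_o$edges),
      shared_nodes = cmp$shared_nodes,
      mean_degree = cmp$summary$mean_degree,
      stage_consistent = if (is.null(consistent)) 0L else nrow(consistent))
  })

  manifest$results <- results
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: %d stages (%s), seed %d\n",
              length(x$stages), paste(names(x$stages), collapse = ", "),
              x$seed))
  invisible(x)
}
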