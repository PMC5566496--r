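#' Genus-level OTU count table
#'
#' @param counts samples x genera matrix of nonnegative integers,
#'   rownames = sample ids, colnames = genus names.
#' @param patient_ids,sites per-sample patient and site labels.
#' @return object of class `otu_table`.
#' @export
otu_table <- function(counts, patient_ids = NULL, sites = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stopf("negative count at row %d (%s), column %d (%s)", bad[1],
          rownames(counts)[bad[1]] %||% "?", bad[2],
          colnames(counts)[bad[2]] %||% "?")
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stopf("non-integer count at row %d, column %d", bad[1], bad[2])
  }
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate sample id '%s'", rownames(counts)[duplicated(rownames(counts))][1])
  if (!is.null(patient_ids) && length(patient_ids) != nrow(counts))
    stopf("patient_ids length mismatch")
  if (!is.null(sites) && length(sites) != nrow(counts))
    stopf("sites length mismatch")
  structure(list(counts = counts, sample_ids = rownames(counts),
                 patient_ids = patient_ids, sites = sites,
                 genus_names = colnames(counts)),
            class = "otu_table")
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d genera, depths %d-%d\n",
              nrow(x$counts), ncol(x$counts),
              min(rowSums(x$counts)), max(rowSums(x$counts))))
  invisible(x)
}

#' Relative abundances of an OTU table
#' @param t an [otu_table()] (or count matrix).
#' @return matrix of per-sample proportions (rows sum to 1).
#' @export
relative_abundance <- function(t) {
  counts <- if (inherits(t, "otu_table")) t$counts else as.matrix(t)
  rs <- rowSums(counts)
  if (any(rs == 0)) stopf("all-zero row(s): %s",
                          paste(rownames(counts)[rs == 0], collapse = ", "))
  counts / rs
}

#' Rarefy an OTU table to common depth
#'
#' Subsamples every sample's reads without replacement to the same
#' depth (the minimum observed depth by default), equalizing
#' sequencing effort across samples before diversity analysis.
#'
#' @param t an [otu_table()].
#' @param depth target depth; must not exceed any sample's depth.
#' @param seed integer seed.
#' @return rarefied [otu_table()] (every row sums to `depth`).
#' @export
rarefy <- function(t, depth = NULL, seed = 1L) {
  stopifnot(inherits(t, "otu_table"))
  depths <- rowSums(t$counts)
  if (is.null(depth)) depth <- min(depths)
  if (depth > min(depths))
    stopf("depth %d exceeds the smallest sample depth (%d)", depth, min(depths))
  set.seed(seed)
  # rrarefy lints any table whose smallest positive entry exceeds 1; the
  # depth precondition above already guards the failure mode it points at
  counts <- suppressWarnings(vegan::rrarefy(t$counts, depth))
  storage.mode(counts) <- "integer"
  otu_table(counts, patient_ids = t$patient_ids, sites = t$sites)
}

#' Shannon diversity index
#'
#' `H = -sum(p * ln p)` over positive relative abundances (natural
#' logarithm). Maximal (`ln S`) for a uniform community.
#'
#' @param p vector of relative abundances summing to 1, or an
#'   [otu_table()] (per-sample indices are then returned).
#' @return the index (or a named vector of per-sample indices).
#' @export
shannon_index <- function(p) {
  if (inherits(p, "otu_table")) {
    ra <- relative_abundance(p)
    return(apply(ra, 1, shannon_index))
  }
  if (any(p < 0)) stopf("negative abundance")
  if (abs(sum(p) - 1) > 1e-6) stopf("abundances must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-sample Tau community-similarity index
#'
#' The similarity of each sample's community to the rest of the cohort,
#' scored as the mean Kendall tau-b rank correlation between the
#' sample's genus-abundance vector and every other sample's vector.
#' A sample with a constant abundance vector has undefined tau and is
#' reported as `NA`.
#'
#' @param t an [otu_table()].
#' @param sample_id optional single sample id; default all samples.
#' @return named vector (or scalar) of mean pairwise tau values.
#' @export
tau_index <- function(t, sample_id = NULL) {
  stopifnot(inherits(t, "otu_table"))
  if (nrow(t$counts) < 2) stopf("tau index needs at least 2 samples")
  ra <- t(relative_abundance(t))       # genera x samples
  tau <- suppressWarnings(stats::cor(ra, method = "kendall"))
  diag(tau) <- NA
  out <- rowMeans(tau, na.rm = TRUE)
  out[apply(ra, 2, function(v) stats::sd(v) == 0)] <- NA_real_
  names(out) <- t$sample_ids
  if (!is.null(sample_id)) return(out[[sample_id]])
  out
}

#' Normalize a per-sample index to each patient's on-tumour value
#'
#' Divides every sample's index by the same patient's tumour-site
#' value, so tumour samples map to exactly 1 and off-tumour values are
#' expressed relative to the tumour.
#'
#' @param values named per-sample index values.
#' @param patient_ids,sites per-sample patient and site labels aligned
#'   with `values`.
#' @param tumour_site label of the tumour site.
#' @return normalized values (same order and names).
#' @export
normalize_index_to_tumour <- function(values, patient_ids, sites,
                                      tumour_site = "tumour") {
  stopifnot(length(values) == length(patient_ids),
            length(values) == length(sites))
  is_t <- as.character(sites) == tumour_site
  ref <- stats::setNames(values[is_t], patient_ids[is_t])
  missing <- setdiff(unique(patient_ids), names(ref))
  if (length(missing))
    stopf("no tumour sample for patient(s): %s", paste(missing, collapse = ", "))
  denom <- ref[as.character(patient_ids)]
  if (any(denom == 0, na.rm = TRUE))
    stopf("zero tumour index for patient(s): %s",
          paste(unique(patient_ids[which(denom == 0)]), collapse = ", "))
  as.numeric(values) / as.numeric(denom)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(u, v) = sum |u_i - v_i| / sum (u_i + v_i)` between community
#' count (or abundance) vectors; bounded in `[0, 1]`, 0 for identical
#' rows and 1 for disjoint support. Not a metric (no triangle
#' inequality is claimed).
#'
#' @param t an [otu_table()] or nonnegative matrix.
#' @return symmetric `dist`-convertible matrix with zero diagonal.
#' @export
bray_curtis <- function(t) {
  counts <- if (inherits(t, "otu_table")) t$counts else as.matrix(t)
  if (any(rowSums(counts) == 0)) stopf("all-zero row in Bray-Curtis input")
  as.matrix(vegan::vegdist(counts, method = "bray"))
}

#' Ward clustering of a dissimilarity matrix
#'
#' Agglomerative Ward linkage (Lance-Williams update on squared
#' dissimilarities, i.e. `hclust` method `ward.D2`). Merge heights are
#' non-decreasing; an ultrametric embedding of Bray-Curtis input is not
#' guaranteed and not needed.
#'
#' @param D symmetric dissimilarity matrix or `dist`.
#' @param k optional number of clusters to cut into.
#' @return object of class `ward_dendrogram`: the `hclust` tree plus
#'   `clusters` (when `k` given).
#' @export
ward_cluster <- function(D, k = NULL) {
  d <- stats::as.dist(D)
  hc <- stats::hclust(d, method = "ward.D2")
  cl <- NULL
  if (!is.null(k)) {
    if (k > attr(d, "Size")) stopf("k (%d) exceeds the number of samples", k)
    cl <- stats::cutree(hc, k = k)
  }
  structure(list(hclust = hc, clusters = cl, k = k),
            class = "ward_dendrogram")
}

#' Cut a Ward dendrogram into k clusters
#' @param dend a `ward_dendrogram`.
#' @param k number of clusters.
#' @export
cut_clusters <- function(dend, k) {
  stopifnot(inherits(dend, "ward_dendrogram"))
  stats::cutree(dend$hclust, k = k)
}

# leaf sets of every internal node of an hclust tree
merge_leaf_sets <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    l <- hc$merge[i, 1]; r <- hc$merge[i, 2]
    sets[[i]] <- c(if (l < 0) -l else sets[[l]],
                   if (r < 0) -r else sets[[r]])
  }
  sets
}

#' Patient concordance in a clustering dendrogram
#'
#' A patient is concordant when the smallest subtree containing all of
#' that patient's samples contains no other patient's samples, i.e.
#' the patient's on-tumour, 5 cm and 10 cm biopsies form a private
#' clade. Invariant to leaf-order permutations of the dendrogram.
#'
#' @param dend a `ward_dendrogram` (labels = sample ids).
#' @param patient_ids per-sample patient labels aligned with the
#'   dendrogram's leaf labels.
#' @return list with `concordant` (named logical per patient) and
#'   `count`.
#' @export
patient_concordance <- function(dend, patient_ids) {
  stopifnot(inherits(dend, "ward_dendrogram"))
  hc <- dend$hclust
  n <- length(hc$labels %||% seq_along(hc$order))
  stopifnot(length(patient_ids) == n)
  sets <- merge_leaf_sets(hc)
  sizes <- lengths(sets)
  patients <- unique(patient_ids)
  res <- stats::setNames(logical(length(patients)), patients)
  for (p in patients) {
    leaves <- which(patient_ids == p)
    if (length(leaves) < 2) { res[p] <- TRUE; next }
    containing <- which(vapply(sets, function(s) all(leaves %in% s), TRUE))
    smallest <- containing[which.min(sizes[containing])]
    res[p] <- sizes[smallest] == length(leaves)
  }
  list(concordant = res, count = sum(res))
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS (isotonic regression of configuration
#' distances on dissimilarities, iterative majorization) with random
#' restarts; the best solution over restarts is returned. Backed by
#' `vegan::metaMDS`/`monoMDS` with Kruskal's primary tie treatment.
#'
#' @param D dissimilarity matrix or `dist`.
#' @param k embedding dimension.
#' @param n_restarts number of random starts.
#' @param seed integer seed.
#' @return object of class `nmds_result`: `coordinates`, `stress` (in
#'   `[0, 1]`), `n_restarts`, `seed`, `converged`.
#' @export
nmds <- function(D, k = 2L, n_restarts = 20L, seed = 1L) {
  d <- stats::as.dist(D)
  if (k >= attr(d, "Size")) stopf("k must be below the number of samples")
  set.seed(seed)
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                   trace = 0, autotransform = FALSE, wascores = FALSE)))
  structure(list(coordinates = fit$points, stress = fit$stress,
                 n_restarts = n_restarts, seed = seed,
                 converged = isTRUE(fit$converged) || fit$stress < 1e-4),
            class = "nmds_result")
}

#' Univariate taxon-feature association tests
#'
#' Per genus, a two-sided Mann-Whitney U test (binary feature) or
#' Kruskal-Wallis test (feature with more than two levels) on relative
#' abundances, with Benjamini-Hochberg correction. Direction is the
#' sign of the median-abundance difference (binary) or of the Spearman
#' correlation with the ordinal level rank.
#'
#' @param t an [otu_table()].
#' @param feature per-sample feature values (2 or more levels).
#' @param samples optional subset of sample ids to test (e.g. tumour
#'   samples only).
#' @return data.frame with `genus`, `direction`, `p`, `q`.
#' @export
taxon_feature_tests <- function(t, feature, samples = NULL) {
  stopifnot(inherits(t, "otu_table"), length(feature) == nrow(t$counts))
  ra <- relative_abundance(t)
  if (!is.null(samples)) {
    keep <- t$sample_ids %in% samples
    ra <- ra[keep, , drop = FALSE]
    feature <- feature[keep]
  }
  f <- factor(feature)
  if (nlevels(f) < 2) stopf("feature has a single level")
  binary <- nlevels(f) == 2
  res <- lapply(seq_len(ncol(ra)), function(j) {
    x <- ra[, j]
    if (stats::sd(x) == 0)
      return(c(direction = 0, p = 1))
    if (binary) {
      p <- suppressWarnings(stats::wilcox.test(x ~ f)$p.value)
      med <- tapply(x, f, stats::median)
      dir <- sign(med[2] - med[1])
      if (dir == 0) dir <- sign(mean(x[f == levels(f)[2]]) - mean(x[f == levels(f)[1]]))
    } else {
      p <- suppressWarnings(stats::kruskal.test(x, f)$p.value)
      dir <- sign(suppressWarnings(stats::cor(x, as.integer(f), method = "spearman")))
    }
    c(direction = as.numeric(dir), p = p)
  })
  res <- do.call(rbind, res)
  data.frame(genus = t$genus_names, direction = res[, "direction"],
             p = res[, "p"], q = stats::p.adjust(res[, "p"], "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Association between cluster membership and clinical features
#'
#' Categorical features are tested with Fisher's exact test (2x2) or a
#' chi-square test (larger tables); ordinal features with a
#' Kruskal-Wallis test across clusters.
#'
#' @param clusters per-sample cluster labels.
#' @param features data.frame of per-sample features.
#' @param ordinal character vector naming the ordinal columns (tested
#'   by Kruskal-Wallis on their level rank).
#' @return data.frame with `feature`, `test`, `p`.
#' @export
cluster_feature_association <- function(clusters, features,
                                        ordinal = c("t_stage", "n_stage")) {
  cl <- factor(clusters)
  if (nlevels(cl) < 2) stopf("need at least 2 clusters")
  out <- lapply(names(features), function(nm) {
    x <- features[[nm]]
    if (length(unique(x)) < 2)
      stopf("feature '%s' has a single level", nm)
    if (nm %in% ordinal) {
      p <- stats::kruskal.test(as.integer(factor(x, levels = sort(unique(x)))),
                               cl)$p.value
      test <- "kruskal-wallis"
    } else {
      tab <- table(factor(x), cl)
      if (all(dim(tab) == 2)) {
        p <- stats::fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- suppressWarnings(stats::chisq.test(tab)$p.value)
        test <- "chi-square"
      }
    }
    data.frame(feature = nm, test = test, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
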