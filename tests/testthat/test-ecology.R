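toy_otu <- function(counts, patients = NULL, sites = NULL) {
  rownames(counts) <- rownames(counts) %||% paste0("s", seq_len(nrow(counts)))
  colnames(counts) <- colnames(counts) %||% paste0("g", seq_len(ncol(counts)))
  otu_table(counts, patient_ids = patients, sites = sites)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Shannon index matches the analytic formula", {
  expect_equal(shannon_index(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(1, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(shannon_index(c(0.5, 0.3, 0.2)),
               shannon_brute(c(0.5, 0.3, 0.2)), tolerance = 1e-12)
  expect_equal(shannon_index(c(0.5, 0.3, 0.2)), 1.0297, tolerance = 1e-4)
  # maximal iff uniform: H = ln S at uniformity, lower otherwise
  expect_lt(shannon_index(c(0.7, 0.1, 0.1, 0.1)), log(4))
  expect_error(shannon_index(c(-0.1, 1.1)), "negative")
})

test_that("tau index is mean pairwise Kendall tau-b", {
  m <- rbind(c(10, 20, 30, 40), c(1, 2, 3, 4))
  t2 <- toy_otu(m)
  expect_equal(unname(tau_index(t2)), c(1, 1), tolerance = 1e-12)
  rev2 <- toy_otu(rbind(c(10, 20, 30, 40), c(40, 30, 20, 10)))
  expect_equal(unname(tau_index(rev2)), c(-1, -1), tolerance = 1e-12)
  # 3-sample toy table vs brute-force pair counting
  m3 <- rbind(c(5, 1, 3, 7), c(2, 2, 6, 1), c(4, 9, 1, 1))
  t3 <- toy_otu(m3)
  ra <- m3 / rowSums(m3)
  expected <- vapply(1:3, function(i)
    mean(vapply(setdiff(1:3, i), function(j)
      tau_b_brute(ra[i, ], ra[j, ]), numeric(1))), numeric(1))
  expect_equal(unname(tau_index(t3)), expected, tolerance = 1e-10)
  # constant abundance vector reported missing
  tc <- toy_otu(rbind(c(2, 2, 2), c(1, 5, 9)))
  expect_true(is.na(tau_index(tc)["s1"]))
})

test_that("rarefaction subsamples to exact depth with hypergeometric means", {
  m <- rbind(c(600, 400), c(100, 0), c(50, 50))
  t <- toy_otu(m)
  r <- rarefy(t, depth = 100, seed = 1)
  expect_true(all(rowSums(r$counts) == 100))
  # row already at depth is unchanged
  expect_equal(r$counts[2, ], c(g1 = 100L, g2 = 0L))
  expect_error(rarefy(t, depth = 101), "exceeds")
  # expectation of subsampling (600,400) to 100 is (60,40)
  draws <- vapply(1:1000, function(i)
    rarefy(toy_otu(m), depth = 100, seed = i)$counts[1, 1], numeric(1))
  se <- sd(draws) / sqrt(1000)
  expect_lt(abs(mean(draws) - 60), 3 * se + 1e-9)
})

test_that("on-tumour normalization divides by each patient's tumour value", {
  v <- c(2.0, 1.0, 3.0, 4.0, 2.0, 6.0)
  pats <- rep(c("P1", "P2"), each = 3)
  sites <- rep(c("tumour", "5cm", "10cm"), 2)
  out <- normalize_index_to_tumour(v, pats, sites)
  expect_equal(out, c(1.0, 0.5, 1.5, 1.0, 0.5, 1.5), tolerance = 1e-12)
  expect_error(
    normalize_index_to_tumour(v[-1], pats[-1], sites[-1]), "P1")
  expect_error(
    normalize_index_to_tumour(c(0, 1, 1), rep("P9", 3), sites[1:3]), "P9")
})

test_that("Bray-Curtis follows the definition and its bounds", {
  expect_equal(bray_curtis(rbind(c(1, 2, 3), c(1, 2, 3)))[1, 2], 0)
  expect_equal(bray_curtis(rbind(c(5, 0, 0), c(0, 3, 2)))[1, 2], 1)
  expect_equal(bray_curtis(rbind(c(6, 2), c(2, 4)))[1, 2],
               bray_brute(c(6, 2), c(2, 4)), tolerance = 1e-12)
  expect_equal(bray_curtis(rbind(c(6, 2), c(2, 4)))[1, 2], 6 / 14,
               tolerance = 1e-12)
  set.seed(1)
  M <- matrix(rpois(60, 5) + 1, 6, 10)
  D <- bray_curtis(M)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("Ward clustering recovers planted community types", {
  skip_if_not_installed("mclust")
  set.seed(2)
  centers <- matrix(exp(rnorm(3 * 20, 0, 1.5)), 3, 20)
  truth <- rep(1:3, times = c(17, 17, 16))
  counts <- t(vapply(truth, function(g)
    as.numeric(rmultinom(1, 5000, centers[g, ] / sum(centers[g, ]))),
    numeric(20)))
  t <- toy_otu(counts)
  D <- bray_curtis(t)
  dend <- ward_cluster(D, k = 3)
  ari <- mclust::adjustedRandIndex(dend$clusters, truth)
  expect_gt(ari, 0.9)
  expect_true(all(diff(dend$hclust$height) >= -1e-9))
  # k = n: singletons
  expect_equal(length(unique(cut_clusters(dend, 50))), 50)
  expect_error(ward_cluster(D, k = 51), "exceeds")
})

test_that("patient concordance detects private clades, order-invariantly", {
  # P1's three samples merge first; P2's are split by P3
  D <- matrix(10, 9, 9)
  lab <- c("P1a", "P1b", "P1c", "P2a", "P2b", "P2c", "P3a", "P3b", "P3c")
  rownames(D) <- colnames(D) <- lab
  diag(D) <- 0
  close <- function(i, j, d) { D[i, j] <<- d; D[j, i] <<- d }
  close(1, 2, 1); close(1, 3, 1); close(2, 3, 1)          # P1 tight
  close(4, 7, 1); close(5, 8, 1)                           # P2/P3 interleaved
  pats <- substr(lab, 1, 2)
  dend <- ward_cluster(D)
  res <- patient_concordance(dend, pats)
  expect_true(res$concordant["P1"])
  expect_false(res$concordant["P2"])
  # invariant under a permutation of the input ordering
  perm <- c(5, 9, 1, 7, 3, 8, 2, 6, 4)
  res2 <- patient_concordance(ward_cluster(D[perm, perm]), pats[perm])
  expect_equal(res2$concordant[names(res$concordant)], res$concordant)
})

test_that("stronger patient effects raise concordance counts", {
  count_conc <- function(effect_sd, seed) {
    meta <- simulate_metadata(cohort_config(n_patients = 10, seed = seed))
    cfg <- otu_sim_config(n_taxa = 40, patient_effect_sd = effect_sd,
                          planted_effects = list(),
                          depth_range = c(3000L, 3000L))
    sim <- simulate_otu_table(meta, cfg, seed = seed)
    dend <- ward_cluster(bray_curtis(sim$otu))
    patient_concordance(dend, meta$patient_id)$count
  }
  diffs <- vapply(1:10, function(s)
    count_conc(1.5, s) - count_conc(0, s), numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(sum(diffs > 0), sum(diffs < 0))
})

test_that("NMDS embeds exactly embeddable distances with near-zero stress", {
  set.seed(3)
  pts <- matrix(rnorm(20 * 2), 20, 2)
  D <- as.matrix(dist(pts))
  fit <- nmds(D, k = 2, n_restarts = 10, seed = 1)
  expect_lt(fit$stress, 0.01)
  pro <- vegan::procrustes(pts, fit$coordinates, symmetric = TRUE)
  expect_lt(pro$ss, 1e-3)
  # planted groups remain separated in the embedding
  g1 <- matrix(rnorm(15 * 4), 15, 4)
  g2 <- matrix(rnorm(15 * 4, 6), 15, 4)
  Dg <- as.matrix(dist(rbind(g1, g2)))
  fg <- nmds(Dg, k = 2, n_restarts = 10, seed = 2)
  sil <- cluster::silhouette(rep(1:2, each = 15), dist(fg$coordinates))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("taxon-feature tests find planted enrichment and keep conventions", {
  set.seed(4)
  n <- 54
  feature <- rep(c("0", "1"), each = n / 2)
  counts <- matrix(rpois(n * 30, 100), n, 30)
  counts[feature == "1", 5] <- rpois(n / 2, 400)   # 4-fold enrichment
  t <- toy_otu(counts)
  res <- taxon_feature_tests(t, feature)
  expect_equal(which.min(res$p), 5)
  expect_lt(res$p[5], 0.01)
  expect_equal(res$direction[5], 1)
  # all-zero genus: p = 1
  t0 <- toy_otu(cbind(counts, 0))
  res0 <- taxon_feature_tests(t0, feature)
  expect_equal(res0$p[31], 1)
  expect_error(taxon_feature_tests(t, rep("x", n)), "single level")
  # ordinal feature path uses Kruskal-Wallis
  ord <- rep(c("I", "II", "III"), each = 18)
  res_o <- taxon_feature_tests(t, ord)
  expect_true(all(res_o$p >= 0 & res_o$p <= 1))
})

test_that("cluster-feature association picks the right exact tests", {
  cl <- rep(c(1, 2), times = c(8, 10))
  feat <- data.frame(bin = rep(c("x", "y"), times = c(8, 10)))
  res <- cluster_feature_association(cl, feat, ordinal = character(0))
  expect_equal(res$test, "fisher")
  # oracle: sum of hypergeometric table probabilities <= the observed one
  p_enum <- sum(dhyper(0:8, 8, 10, 8)[dhyper(0:8, 8, 10, 8) <=
                                        dhyper(8, 8, 10, 8) + 1e-12])
  expect_equal(res$p, p_enum, tolerance = 1e-12)
  expect_equal(res$p, 1 / choose(18, 8), tolerance = 1e-12)
  # ordinal features go through Kruskal-Wallis
  feat2 <- data.frame(t_stage = rep(c("T1", "T3", "T4"), 6))
  res2 <- cluster_feature_association(cl, feat2)
  expect_equal(res2$test, "kruskal-wallis")
  expect_error(cluster_feature_association(cl,
    data.frame(k = rep("a", 18))), "single level")
  expect_error(cluster_feature_association(rep(1, 18), feat), "2 clusters")
})
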