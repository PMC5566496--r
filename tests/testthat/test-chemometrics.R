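test_that("PCA captures dominant structure and flags displaced samples", {
  set.seed(1)
  # data on a line plus tiny noise
  t <- rnorm(40)
  X <- cbind(t, 2 * t, -t) + matrix(rnorm(120, 0, 0.01), 40)
  p <- fit_pca(X, 2)
  expect_gt(p$explained_variance[1], 0.99)
  expect_equal(crossprod(p$loadings), diag(2), tolerance = 1e-10)
  # displaced sample exceeds the 95% T2 limit
  set.seed(2)
  Xin <- matrix(rnorm(50 * 10), 50, 10)
  dir <- rnorm(10); dir <- dir / sqrt(sum(dir^2))
  Xout <- rbind(Xin, 10 * dir)
  m <- fit_pca(Xout, 2)
  expect_gt(m$hotelling_t2[51], m$t2_limit)
  expect_error(fit_pca(X, 10), "rank")
})

test_that("outlier removal mirrors the 54 to 51 retention pattern", {
  set.seed(3)
  X <- matrix(rnorm(51 * 20), 51, 20)
  dirs <- matrix(rnorm(3 * 20), 3, 20)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  X <- rbind(X, 10 * dirs)
  rownames(X) <- sprintf("s%02d", 1:54)
  model <- fit_pca(X, 3)
  red <- remove_outliers(X, model)
  expect_equal(nrow(red$X), 51)
  expect_setequal(red$removed, c("s52", "s53", "s54"))
  # no exceedances: identity; 100% confidence: identity
  calm <- matrix(rnorm(30 * 5), 30, 5)
  mc <- fit_pca(calm, 2, conf = 1 - 1e-12)
  expect_equal(nrow(remove_outliers(calm, mc)$X), 30)
  m100 <- fit_pca(calm, 2, conf = 1)
  expect_equal(nrow(remove_outliers(calm, m100)$X), 30)
})

test_that("PLS-DA separates separable classes and matches the eigen oracle", {
  set.seed(4)
  y <- rep(c("a", "b"), each = 20)
  X <- cbind(ifelse(y == "a", -2, 2) + rnorm(40, 0, 0.2),
             matrix(rnorm(40 * 5), 40))
  fit <- fit_plsda(X, y, n_components = 1)
  s <- fit$scores[, 1]
  expect_true(max(s[y == "a"]) < min(s[y == "b"]) ||
              min(s[y == "a"]) > max(s[y == "b"]))
  # first weight collinear with dominant eigenvector of X' Y Y' X
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(model.matrix(~ factor(y) - 1), scale = FALSE)
  M <- t(Xc) %*% Yc %*% t(Yc) %*% Xc
  v <- eigen(M, symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(sum(v * fit$W[, 1])), 1 - 1e-8)
  expect_error(fit_plsda(X, rep("a", 40)), "2 classes")
})

test_that("OPLS-DA separates predictive from orthogonal variation", {
  set.seed(5)
  n <- 60; p <- 30
  y <- rep(c(0, 1), each = n / 2)
  w <- rnorm(p); w <- w / sqrt(sum(w^2))
  po <- rnorm(p); po <- po - sum(po * w) * w; po <- po / sqrt(sum(po^2))
  t_o <- rnorm(n, 0, 2)
  X <- outer(y - mean(y), w) * 3 + outer(t_o, po) +
    matrix(rnorm(n * p, 0, 0.05), n)
  fit <- fit_oplsda(X, y, n_orthogonal = 1, positive = "1")
  expect_gt(abs(cor(fit$scores, y)), 0.99)
  expect_gt(abs(cor(fit$orthogonal_scores[, 1], t_o)), 0.99)
  expect_lt(abs(cor(fit$orthogonal_scores[, 1], y)), 0.05)
  # n_orthogonal = 0 reduces to single-component PLS-DA scores
  f0 <- fit_oplsda(X, y, n_orthogonal = 0, positive = "1")
  f1 <- fit_plsda(X, y, n_components = 1)
  expect_equal(abs(cor(as.numeric(f0$scores), f1$scores[, 1])), 1,
               tolerance = 1e-8)
  expect_error(fit_oplsda(X, y, n_orthogonal = 40), "rank")
})

test_that("MMC recovers a planted discriminant axis and degenerates correctly", {
  set.seed(6)
  n <- 100; p <- 10
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * p, 0, 0.5), n)
  X[y == "b", 1] <- X[y == "b", 1] + 5
  fit <- fit_mmc(X, y, n_components = 1)
  e1 <- c(1, rep(0, p - 1))
  cosang <- abs(sum(fit$loadings[, 1] * e1))
  expect_gt(cosang, 0.99)
  angle <- acos(pmin(cosang, 1)) * 180 / pi
  expect_lt(angle, 5)
  # identical class means: no positive eigenvalue
  X0 <- matrix(rnorm(60 * 4), 60)
  y0 <- rep(c("a", "b"), 30)
  X0c <- X0
  for (cl in c("a", "b"))   # force identical class means
    X0c[y0 == cl, ] <- scale(X0[y0 == cl, ], scale = FALSE)
  f0 <- fit_mmc(X0c, y0, n_components = 2)
  expect_true(all(f0$eigenvalues <= 1e-10))
  expect_error(fit_mmc(X[1:3, ], c("a", "b", "b"), 1), "single sample")
})

test_that("MMC in wide matrices uses a PCA subspace but still discriminates", {
  set.seed(7)
  n <- 30; p <- 200
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * p), n)
  X[y == "b", 1:5] <- X[y == "b", 1:5] + 2
  fit <- fit_mmc(X, y, n_components = 2)
  expect_equal(nrow(fit$loadings), p)
  s <- fit$scores[, 1]
  expect_gt(abs(cor(s, as.numeric(factor(y)))), 0.8)
})

test_that("cross-validation partitions correctly and calibrates Q2", {
  set.seed(8)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(ifelse(y == "a", -3, 3) + rnorm(n, 0, 0.1),
             matrix(rnorm(n * 2), n))
  rownames(X) <- paste0("s", 1:n)
  cv <- cross_validate(X, y, kind = "plsda", scheme = "loso",
                       n_components = 1)
  expect_equal(sort(cv$predictions$sample), sort(rownames(X)))
  expect_equal(anyDuplicated(cv$predictions$sample), 0L)
  expect_equal(cv$accuracy, 1.0)
  expect_gt(cv$q2, 0.9)
  expect_equal(roc_auc(cv$predictions$score, y, positive = "b")$auc, 1.0)
  # grouped CV keeps a patient's samples together
  grp <- rep(1:(n / 2), each = 2)
  cvg <- cross_validate(X, y, kind = "plsda", scheme = "lopo", groups = grp,
                        n_components = 1)
  expect_equal(length(unique(cvg$predictions$fold)), n / 2)
  expect_error(cross_validate(X, y, kind = "plsda", scheme = "lopo"),
               "group ids")
})

test_that("training Q2 bounds cross-validated Q2", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 30
    y <- rep(c("a", "b"), each = n / 2)
    X <- matrix(rnorm(n * 8), n)
    X[, 1] <- X[, 1] + ifelse(y == "b", rep, 0) * 0.3
    fit <- fit_plsda(scale(X), y, n_components = 2)
    cv <- cross_validate(X, y, kind = "plsda", scheme = "loso",
                         n_components = 2)
    expect_gte(fit$r2y, cv$q2 - 1e-8)
  }
})

test_that("ROC/AUC follows the trapezoid-with-ties convention", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("p", "p", "n", "n"), positive = "p")$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c("p", "n"), 5),
                       positive = "p")$auc, 0.5)
  # monotone-transform invariance
  set.seed(10)
  s <- rnorm(50); y <- sample(c("p", "n"), 50, replace = TRUE)
  a1 <- roc_auc(s, y, positive = "p")$auc
  a2 <- roc_auc(exp(3 * s) + 2, y, positive = "p")$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  # tpr/fpr monotone along the sweep
  rc <- roc_auc(s, y, positive = "p")
  expect_true(all(diff(rc$tpr) >= 0) && all(diff(rc$fpr) >= 0))
  # random scores concentrate near 0.5
  set.seed(11)
  s2 <- rnorm(2000); y2 <- rep(c("p", "n"), 1000)
  expect_true(abs(roc_auc(s2, y2, positive = "p")$auc - 0.5) < 0.03)
  expect_error(roc_auc(1:3, c("p", "p", "p")), "2 classes")
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  s <- rnorm(80); y <- sample(c("n", "p"), 80, replace = TRUE)
  ours <- roc_auc(s, y, positive = "p")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("pseudo-loadings ANOVA flags planted shifts with correct sign", {
  set.seed(13)
  n <- 40
  y <- rep(c("off", "tumour"), each = n / 2)
  X <- matrix(rnorm(n * 50), n)
  X[y == "tumour", 7] <- X[y == "tumour", 7] + 3   # 3 sd planted shift
  X[y == "tumour", 9] <- X[y == "tumour", 9] - 3
  pl <- pseudo_loadings_anova(X, y, class_of_interest = "tumour",
                              reference = "off")
  expect_lt(pl$q[7], 0.001)
  expect_equal(pl$sign[7], 1)
  expect_equal(pl$sign[9], -1)
  # constant variable convention
  Xc <- cbind(X, 5)
  plc <- pseudo_loadings_anova(Xc, y)
  expect_equal(plc$p[51], 1)
  expect_equal(plc$sign[51], 0)
  # single-column agreement with aov
  p_aov <- summary(aov(X[, 7] ~ factor(y)))[[1]][["Pr(>F)"]][1]
  expect_equal(pl$p[7], p_aov, tolerance = 1e-10)
})

test_that("Benjamini-Hochberg adjustment matches the step-up construction", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  expect_equal(p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  set.seed(14)
  y <- rep(c("a", "b"), 10)
  X <- matrix(rnorm(20 * 10), 20)
  pl <- pseudo_loadings_anova(X, y)
  expect_equal(pl$q, bh_brute(pl$p), tolerance = 1e-12)
  expect_true(all(pl$q >= pl$p))
})
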