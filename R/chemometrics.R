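dummy_code <- function(labels) {
  f <- factor(labels)
  if (nlevels(f) < 2) stopf("need at least 2 classes, got %d", nlevels(f))
  Y <- stats::model.matrix(~ f - 1)
  colnames(Y) <- levels(f)
  attr(Y, "assign") <- NULL
  attr(Y, "contrasts") <- NULL
  Y
}

as_matrix <- function(X) {
  if (inherits(X, "spectral_matrix")) X$X else as.matrix(X)
}

#' Principal component analysis with Hotelling T2 screening
#'
#' Centred SVD-based PCA. The per-sample Hotelling T2 statistic is
#' computed from the first `n_components` scores, with an
#' F-distribution based control limit at the requested confidence.
#'
#' @param X numeric matrix (samples x variables) or `spectral_matrix`.
#' @param n_components number of components.
#' @param conf confidence level for the T2 limit.
#' @return object of class `pca_model` with `scores`, `loadings`,
#'   `explained_variance` (fractions), `hotelling_t2`, `t2_limit`.
#' @export
fit_pca <- function(X, n_components = 2L, conf = 0.95) {
  X <- as_matrix(X)
  n <- nrow(X)
  if (n < 2) stopf("PCA needs at least 2 rows")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  if (n_components > rank)
    stopf("n_components (%d) exceeds matrix rank (%d)", n_components, rank)
  k <- n_components
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(X)
  lambda <- sv$d^2 / (n - 1)
  t2 <- rowSums(sweep(scores^2, 2, lambda[seq_len(k)], "/"))
  lim <- if (conf >= 1) Inf else
    k * (n - 1) * (n + 1) / (n * (n - k)) * stats::qf(conf, k, n - k)
  structure(list(loadings = sv$v[, seq_len(k), drop = FALSE],
                 scores = scores, centre = mu,
                 explained_variance = lambda[seq_len(k)] / sum(lambda),
                 singular_values = sv$d,
                 hotelling_t2 = stats::setNames(t2, rownames(X)),
                 t2_limit = lim, conf = conf, n_components = k),
            class = "pca_model")
}

#' Remove multivariate outliers flagged by Hotelling T2
#'
#' @param X the matrix the model was fitted on.
#' @param model a [fit_pca()] model.
#' @return list with `X` (reduced), `removed` (ids or indices),
#'   `t2` and `limit`.
#' @export
remove_outliers <- function(X, model) {
  Xm <- as_matrix(X)
  stopifnot(inherits(model, "pca_model"), nrow(Xm) == length(model$hotelling_t2))
  bad <- model$hotelling_t2 > model$t2_limit
  if (all(bad)) stopf("every sample exceeds the T2 limit; refusing to empty the matrix")
  removed <- if (!is.null(rownames(Xm))) rownames(Xm)[bad] else which(bad)
  list(X = Xm[!bad, , drop = FALSE], removed = removed,
       t2 = model$hotelling_t2, limit = model$t2_limit)
}

#' Partial least squares discriminant analysis (NIPALS PLS2)
#'
#' Fits NIPALS PLS2 of centred X against centred dummy-coded class
#' labels with standard X/Y deflation. Initialization is deterministic
#' (the Y column of largest variance starts each component).
#'
#' @param X numeric matrix (samples x variables), typically already
#'   unit-variance scaled.
#' @param labels class labels (>= 2 classes).
#' @param n_components number of latent components.
#' @return `supervised_model` of kind `"plsda"` with weights `W`,
#'   X-loadings `P`, Y-loadings `C`, scores `T`, regression matrix `B`,
#'   `r2y`, class encoding.
#' @export
fit_plsda <- function(X, labels, n_components = 2L) {
  X <- as_matrix(X)
  Y <- dummy_code(labels)
  if (ncol(Y) < 2) stopf("need at least 2 classes")
  if (any(colSums(Y) == 0)) stopf("empty class level")
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- colMeans(Y)
  E <- sweep(X, 2, xm); F <- sweep(Y, 2, ym)
  A <- n_components
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  C <- matrix(0, ncol(Y), A); Tm <- matrix(0, n, A)
  tss <- sum(F^2)
  for (a in seq_len(A)) {
    u <- F[, which.max(apply(F, 2, stats::var))]
    if (sum(u^2) == 0) { A <- a - 1L; break }
    w_old <- NULL
    for (it in 1:500) {
      w <- as.numeric(crossprod(E, u))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) stopf("degenerate component %d (X orthogonal to Y)", a)
      w <- w / nw
      tt <- as.numeric(E %*% w)
      cc <- as.numeric(crossprod(F, tt)) / sum(tt^2)
      u <- as.numeric(F %*% cc) / sum(cc^2)
      if (!is.null(w_old) && sum((w - w_old)^2) < 1e-24) break
      w_old <- w
    }
    pp <- as.numeric(crossprod(E, tt)) / sum(tt^2)
    E <- E - tcrossprod(tt, pp)
    F <- F - tcrossprod(tt, cc)
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc; Tm[, a] <- tt
  }
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  C <- C[, seq_len(A), drop = FALSE]; Tm <- Tm[, seq_len(A), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  B <- R %*% t(C)
  rownames(Tm) <- rownames(X)
  structure(list(kind = "plsda", W = W, P = P, C = C, scores = Tm,
                 R = R, B = B, x_centre = xm, y_centre = ym,
                 classes = colnames(Y), labels = as.character(labels),
                 n_components = A, r2y = 1 - sum(F^2) / tss),
            class = "supervised_model")
}

#' Orthogonal PLS discriminant analysis
#'
#' Orthogonal-projections-to-latent-structures decomposition for a
#' binary class contrast: each orthogonal component captures X
#' variation uncorrelated with the class, which is deflated before the
#' single predictive component is extracted. Predictive and orthogonal
#' scores are stored separately. Multi-class inputs are handled
#' one-vs-rest (a list of binary models is returned).
#'
#' @param X numeric matrix.
#' @param labels class labels; binary for a single model.
#' @param n_orthogonal number of orthogonal components (< rank).
#' @param positive label treated as the positive class (default: second
#'   factor level).
#' @return `supervised_model` of kind `"oplsda"`, or a named list of
#'   them (one per class) for multi-class input.
#' @export
fit_oplsda <- function(X, labels, n_orthogonal = 1L, positive = NULL) {
  X <- as_matrix(X)
  lv <- levels(factor(labels))
  if (length(lv) < 2) stopf("need at least 2 classes")
  if (length(lv) > 2 && is.null(positive)) {
    out <- lapply(lv, function(l)
      fit_oplsda(X, ifelse(labels == l, l, "rest"), n_orthogonal, positive = l))
    names(out) <- lv
    return(structure(out, class = "oplsda_ovr"))
  }
  if (is.null(positive)) positive <- lv[2]
  y <- as.numeric(labels == positive)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); yc <- y - ym
  n <- nrow(E); p <- ncol(E)
  if (n_orthogonal >= min(n - 1, p))
    stopf("n_orthogonal (%d) must be below the matrix rank", n_orthogonal)
  W_o <- matrix(0, p, n_orthogonal); P_o <- matrix(0, p, n_orthogonal)
  T_o <- matrix(0, n, n_orthogonal)
  n_o <- 0L
  w <- as.numeric(crossprod(E, yc)); w <- w / sqrt(sum(w^2))
  if (n_orthogonal > 0) for (j in seq_len(n_orthogonal)) {
    tt <- as.numeric(E %*% w)
    pp <- as.numeric(crossprod(E, tt)) / sum(tt^2)
    wo <- pp - as.numeric(crossprod(w, pp)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break
    wo <- wo / nwo
    to <- as.numeric(E %*% wo)
    po <- as.numeric(crossprod(E, to)) / sum(to^2)
    E <- E - tcrossprod(to, po)
    n_o <- j
    W_o[, j] <- wo; P_o[, j] <- po; T_o[, j] <- to
    w <- as.numeric(crossprod(E, yc)); w <- w / sqrt(sum(w^2))
  }
  W_o <- W_o[, seq_len(n_o), drop = FALSE]
  P_o <- P_o[, seq_len(n_o), drop = FALSE]
  T_o <- T_o[, seq_len(n_o), drop = FALSE]
  tt <- as.numeric(E %*% w)
  pp <- as.numeric(crossprod(E, tt)) / sum(tt^2)
  cc <- sum(yc * tt) / sum(tt^2)
  rn <- rownames(X)
  structure(list(kind = "oplsda", w = w, p = pp, c = cc,
                 scores = stats::setNames(tt, rn),
                 W_o = W_o, P_o = P_o,
                 orthogonal_scores = structure(T_o, dimnames = list(rn, NULL)),
                 x_centre = xm, y_centre = ym,
                 classes = c(setdiff(lv, positive)[1], positive),
                 positive = positive, labels = as.character(labels),
                 n_components = 1L, n_orthogonal = n_o,
                 r2y = 1 - sum((yc - tt * cc)^2) / sum(yc^2)),
            class = "supervised_model")
}

#' Maximum margin criterion projection
#'
#' Projects onto the leading eigenvectors of the difference between the
#' between-class and within-class scatter matrices, `S_b - S_w`,
#' computed from class means and pooled within-class scatter. When the
#' number of variables greatly exceeds the number of samples the
#' scatter matrices are formed in a PCA subspace retaining
#' `var_retained` of the variance, which stabilizes the decomposition.
#'
#' @param X numeric matrix.
#' @param labels class labels (>= 2 classes, >= 2 samples each unless
#'   `regularize`).
#' @param n_components number of discriminant directions.
#' @param var_retained PCA variance fraction retained when `p > n`.
#' @param regularize allow singleton classes (their within-scatter
#'   contribution is zero).
#' @return `supervised_model` of kind `"mmc"` with orthonormal
#'   `loadings` (in the original variable space), `scores`,
#'   `eigenvalues`, class encoding.
#' @export
fit_mmc <- function(X, labels, n_components = 2L, var_retained = 0.95,
                    regularize = FALSE) {
  X <- as_matrix(X)
  f <- factor(labels)
  if (nlevels(f) < 2) stopf("need at least 2 classes")
  cnt <- table(f)
  if (any(cnt < 2) && !regularize)
    stopf("class '%s' has a single sample; set regularize = TRUE to allow",
          names(cnt)[cnt < 2][1])
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  V_pca <- NULL
  Z <- Xc
  if (p > n - 1) {
    sv <- svd(Xc, nu = 0)
    lambda <- sv$d^2
    keep <- which(cumsum(lambda) / sum(lambda) <= var_retained + 1e-12)
    keep <- seq_len(max(1, length(keep)))
    keep <- keep[sv$d[keep] > max(sv$d) * 1e-10]
    V_pca <- sv$v[, keep, drop = FALSE]
    Z <- Xc %*% V_pca
  }
  d <- ncol(Z)
  Sb <- matrix(0, d, d); Sw <- matrix(0, d, d)
  for (l in levels(f)) {
    idx <- which(f == l)
    mcl <- colMeans(Z[idx, , drop = FALSE])
    Sb <- Sb + length(idx) / n * tcrossprod(mcl)
    Zc <- sweep(Z[idx, , drop = FALSE], 2, mcl)
    Sw <- Sw + crossprod(Zc) / n
  }
  eg <- eigen(Sb - Sw, symmetric = TRUE)
  k <- min(n_components, d)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  W <- if (is.null(V_pca)) V else V_pca %*% V
  scores <- Xc %*% W
  rownames(scores) <- rownames(X)
  structure(list(kind = "mmc", loadings = W, scores = scores,
                 eigenvalues = eg$values, x_centre = mu,
                 classes = levels(f), labels = as.character(labels),
                 n_components = k),
            class = "supervised_model")
}

#' Project new samples into a fitted model's score space
#'
#' For OPLS-DA, orthogonal variation is removed from the new samples
#' before computing the predictive score.
#'
#' @param object a `supervised_model`.
#' @param newdata matrix of new samples.
#' @param ... unused.
#' @return matrix of predicted scores (one column per component).
#' @export
predict.supervised_model <- function(object, newdata, ...) {
  Xn <- sweep(as_matrix(newdata), 2, object$x_centre)
  switch(object$kind,
    plsda = Xn %*% object$R,
    mmc = Xn %*% object$loadings,
    oplsda = {
      if (object$n_orthogonal > 0)
        for (j in seq_len(object$n_orthogonal)) {
          to <- Xn %*% object$W_o[, j]
          Xn <- Xn - tcrossprod(to, object$P_o[, j])
        }
      Xn %*% object$w
    })
}

# continuous dummy-Y predictions used for PRESS/Q2
predict_y <- function(model, newdata) {
  Xn <- sweep(as_matrix(newdata), 2, model$x_centre)
  if (model$kind == "plsda") {
    Yhat <- sweep(Xn %*% model$B, 2, model$y_centre, "+")
    colnames(Yhat) <- model$classes
    return(Yhat)
  }
  if (model$kind == "oplsda") {
    t <- predict.supervised_model(model, newdata)
    yhat <- as.numeric(t) * model$c + model$y_centre
    Y <- cbind(1 - yhat, yhat)
    colnames(Y) <- model$classes
    return(Y)
  }
  # mmc: regress training dummy Y on training scores
  Ytr <- dummy_code(model$labels)
  fit <- stats::lm.fit(cbind(1, model$scores), Ytr)
  t <- predict.supervised_model(model, newdata)
  Yhat <- cbind(1, t) %*% fit$coefficients
  colnames(Yhat) <- colnames(Ytr)
  Yhat
}

#' Grouped cross-validation of a supervised model
#'
#' Leave-one-sample-out or leave-one-patient-out cross-validation. In
#' every fold, column centring/unit-variance scaling is re-estimated on
#' the training rows only and applied to the held-out rows, the model
#' is refitted, and held-out predictions are pooled. Q2 = 1 -
#' PRESS/TSS on the dummy-coded class matrix; class assignment is by
#' nearest class mean in predicted-score space.
#'
#' @param X numeric matrix (unscaled when `scale = TRUE`).
#' @param labels class labels.
#' @param kind one of `"plsda"`, `"oplsda"`, `"mmc"`.
#' @param scheme `"loso"` (leave-one-sample-out) or `"lopo"`
#'   (leave-one-patient-out, requires `groups`).
#' @param groups patient/group ids for `"lopo"`.
#' @param scale re-estimate unit-variance scaling within each fold.
#' @param positive positive class for the ROC score (default last
#'   factor level).
#' @param ... passed to the fitting function (`n_components`,
#'   `n_orthogonal`, ...).
#' @return object of class `cv_result`: `predictions` (data.frame with
#'   true/predicted labels and decision scores), `q2`, `accuracy`,
#'   `scheme`.
#' @export
cross_validate <- function(X, labels, kind = c("plsda", "oplsda", "mmc"),
                           scheme = c("loso", "lopo"), groups = NULL,
                           scale = TRUE, positive = NULL, ...) {
  X <- as_matrix(X)
  kind <- match.arg(kind)
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  n <- nrow(X)
  if (scheme == "lopo") {
    if (is.null(groups)) stopf("leave-one-patient-out requires group ids")
    fold_of <- as.integer(factor(groups))
  } else fold_of <- seq_len(n)
  f <- factor(labels)
  if (is.null(positive)) positive <- levels(f)[nlevels(f)]
  Y <- dummy_code(labels)
  press <- 0; tss <- 0
  pred_class <- character(n); dec_score <- numeric(n)
  fitter <- switch(kind, plsda = fit_plsda, mmc = fit_mmc,
                   oplsda = function(X, labels, ...)
                     fit_oplsda(X, labels, positive = positive, ...))
  for (fd in unique(fold_of)) {
    te <- fold_of == fd; tr <- !te
    if (length(unique(labels[tr])) < 2)
      stopf("fold %s leaves a single training class", fd)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (scale) {
      mu <- colMeans(Xtr)
      sd <- col_sds(Xtr); sd[sd == 0 | !is.finite(sd)] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sd, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sd, "/")
    }
    model <- fitter(Xtr, labels[tr], ...)
    Yhat <- predict_y(model, Xte)
    Yte <- Y[te, model$classes, drop = FALSE]
    ybar_tr <- colMeans(Y[tr, model$classes, drop = FALSE])
    press <- press + sum((Yte - Yhat)^2)
    tss <- tss + sum(sweep(Yte, 2, ybar_tr)^2)
    # nearest class mean in score space
    str <- if (kind == "oplsda") matrix(model$scores, ncol = 1) else model$scores
    ste <- predict.supervised_model(model, Xte)
    cm <- do.call(rbind, lapply(model$classes, function(l) {
      idx <- model$labels == l
      colMeans(str[idx, , drop = FALSE])
    }))
    dmat <- outer(seq_len(nrow(ste)), seq_len(nrow(cm)),
                  Vectorize(function(i, j) sum((ste[i, ] - cm[j, ])^2)))
    pred_class[te] <- model$classes[apply(dmat, 1, which.min)]
    if (positive %in% model$classes)
      dec_score[te] <- predict_y(model, Xte)[, positive]
  }
  preds <- data.frame(sample = if (!is.null(rownames(X))) rownames(X) else seq_len(n),
                      fold = fold_of, true = labels, predicted = pred_class,
                      score = dec_score, stringsAsFactors = FALSE)
  structure(list(scheme = scheme, kind = kind, predictions = preds,
                 q2 = 1 - press / tss,
                 accuracy = mean(pred_class == labels),
                 positive = positive),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation (%s): Q2 = %.3f, accuracy = %.3f\n",
              x$kind, x$scheme, x$q2, x$accuracy))
  invisible(x)
}

#' Receiver operating characteristic curve and AUC
#'
#' Threshold sweep over the unique decision scores; AUC by the
#' trapezoidal rule, which averages tied scores (all-tied scores give
#' AUC 0.5).
#'
#' @param scores numeric decision scores (larger = more positive).
#' @param labels binary labels.
#' @param positive label counted as positive (default: second factor
#'   level).
#' @return object of class `roc_curve` with `thresholds`, `tpr`,
#'   `fpr`, `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  f <- factor(labels)
  if (nlevels(f) != 2) stopf("ROC needs exactly 2 classes present")
  if (is.null(positive)) positive <- levels(f)[2]
  y <- labels == positive
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  # collapse tied thresholds
  last <- rev(!duplicated(rev(s)))
  tp <- cumsum(y)[last]; fp <- cumsum(!y)[last]
  P <- sum(y); N <- sum(!y)
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[last]), tpr = tpr, fpr = fpr,
                 auc = auc, positive = positive),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve (positive = %s): AUC = %.3f\n", x$positive, x$auc))
  invisible(x)
}

#' Pseudo-loadings ANOVA with FDR colouring
#'
#' Per-variable one-way ANOVA across class labels with
#' Benjamini-Hochberg correction. Each variable also gets a direction
#' sign (sign of the class-of-interest mean minus the reference mean)
#' and a magnitude (covariance with the model's predictive score),
#' reproducing the information of an FDR-coloured pseudo-loadings
#' plot: peaks point towards the tissue state they associate with and
#' colour encodes significance.
#'
#' @param m numeric matrix or `spectral_matrix` (unit-variance scaled
#'   or not).
#' @param labels class labels (>= 2 levels).
#' @param scores predictive score vector (e.g. the cross-validated MMC
#'   or OPLS score); defaults to the centred class indicator.
#' @param class_of_interest,reference class levels defining the sign;
#'   default last/first factor level.
#' @return data.frame with `variable` (bin ppm when available), `sign`,
#'   `magnitude`, `p`, `q`.
#' @export
pseudo_loadings_anova <- function(m, labels, scores = NULL,
                                  class_of_interest = NULL, reference = NULL) {
  X <- as_matrix(m)
  f <- factor(labels)
  if (nlevels(f) < 2) stopf("need at least 2 classes")
  n <- nrow(X); k <- nlevels(f)
  if (is.null(class_of_interest)) class_of_interest <- levels(f)[k]
  if (is.null(reference)) reference <- levels(f)[1]
  if (is.null(scores)) scores <- as.numeric(f == class_of_interest)
  # vectorized one-way ANOVA over columns
  grand <- colMeans(X)
  ssb <- numeric(ncol(X)); ssw_tot <- colSums(sweep(X, 2, grand)^2)
  gm <- rowsum(X, f) / as.integer(table(f))
  for (l in levels(f))
    ssb <- ssb + sum(f == l) * (gm[l, ] - grand)^2
  ssw <- ssw_tot - ssb
  Fst <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(Fst, k - 1, n - k, lower.tail = FALSE)
  const <- ssw_tot <= .Machine$double.eps * n
  p[const | !is.finite(Fst)] <- 1
  q <- stats::p.adjust(p, method = "BH")
  sgn <- sign(gm[class_of_interest, ] - gm[reference, ])
  sgn[const] <- 0
  sc <- scores - mean(scores)
  magnitude <- as.numeric(crossprod(sweep(X, 2, grand), sc)) / (n - 1)
  vars <- if (inherits(m, "spectral_matrix")) m$bins
          else (colnames(X) %||% seq_len(ncol(X)))
  data.frame(variable = vars, sign = as.numeric(sgn),
             magnitude = magnitude, p = p, q = q,
             row.names = NULL, stringsAsFactors = FALSE)
}
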