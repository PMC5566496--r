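#' Spearman correlation of metabolite features against taxa
#'
#' Full cross-correlation of two aligned sample-by-feature matrices
#' using Spearman rank correlation (average ranks for ties). P-values
#' come from the t-approximation `t = rho * sqrt((n-2)/(1-rho^2))`; an
#' exact permutation p-value is used when `n <= exact_n` (no ties).
#' Constant columns yield `NA` entries.
#'
#' @param metab samples x metabolites matrix.
#' @param taxa samples x genera matrix (same sample order).
#' @param exact_n use the exact null distribution at or below this n.
#' @return list with `rho` and `p` matrices (metabolites x taxa) and
#'   `n`.
#' @export
correlate <- function(metab, taxa, exact_n = 10L) {
  metab <- as.matrix(metab); taxa <- as.matrix(taxa)
  if (nrow(metab) != nrow(taxa)) stopf("sample sets differ in size")
  n <- nrow(metab)
  if (n < 4) stopf("need at least 4 samples")
  Rm <- apply(metab, 2, rank)
  Rt <- apply(taxa, 2, rank)
  rho <- suppressWarnings(stats::cor(Rm, Rt))
  const_m <- apply(metab, 2, function(v) stats::sd(v) == 0)
  const_t <- apply(taxa, 2, function(v) stats::sd(v) == 0)
  rho[const_m, ] <- NA; rho[, const_t] <- NA
  if (n <= exact_n && !any(const_m) && !any(const_t) &&
      !anyDuplicated(Rm[, 1])) {
    p <- apply_exact_spearman_p(Rm, Rt, rho)
  } else {
    r <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
    p[abs(rho) >= 1] <- 0
  }
  list(rho = rho, p = p, n = n)
}

# exact two-sided permutation p for small n without ties
apply_exact_spearman_p <- function(Rm, Rt, rho) {
  n <- nrow(Rm)
  perms <- permutations_of(n)
  p <- rho
  for (i in seq_len(ncol(Rm))) for (j in seq_len(ncol(Rt))) {
    if (is.na(rho[i, j])) next
    null_rho <- apply(perms, 1, function(pp) stats::cor(Rm[pp, i], Rt[, j]))
    p[i, j] <- mean(abs(null_rho) >= abs(rho[i, j]) - 1e-12)
  }
  p
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Threshold a correlation matrix into a network edge set
#'
#' Keeps metabolite-taxon pairs with `p < alpha` (raw) or BH `q <
#' alpha` (when `fdr`); the edge sign is the sign of rho. Isolated
#' nodes are dropped unless `keep_isolated`.
#'
#' @param rho,p matrices from [correlate()].
#' @param alpha significance threshold.
#' @param fdr apply Benjamini-Hochberg across all pairs.
#' @param keep_isolated keep nodes without edges in the node table.
#' @return object of class `edge_set`: `nodes` (data.frame `name`,
#'   `type`), `edges` (data.frame `node_a`, `node_b`, `rho`, `p`, `q`,
#'   `sign`).
#' @export
threshold_network <- function(rho, p, alpha = 0.05, fdr = FALSE,
                              keep_isolated = FALSE) {
  stopifnot(all(dim(rho) == dim(p)))
  q <- matrix(stats::p.adjust(p, "BH"), nrow(p), ncol(p), dimnames = dimnames(p))
  crit <- if (fdr) q else p
  keep <- which(!is.na(crit) & crit < alpha, arr.ind = TRUE)
  mnames <- rownames(rho) %||% paste0("m", seq_len(nrow(rho)))
  tnames <- colnames(rho) %||% paste0("t", seq_len(ncol(rho)))
  edges <- data.frame(
    node_a = mnames[keep[, 1]], node_b = tnames[keep[, 2]],
    rho = rho[keep], p = p[keep], q = q[keep],
    sign = sign(rho[keep]), stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(name = c(mnames, tnames),
                      type = rep(c("metabolite", "taxon"),
                                 c(length(mnames), length(tnames))),
                      stringsAsFactors = FALSE)
  if (!keep_isolated)
    nodes <- nodes[nodes$name %in% c(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, alpha = alpha, fdr = fdr),
            class = "edge_set")
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("edge_set: %d nodes, %d edges (alpha = %g%s)\n",
              nrow(x$nodes), nrow(x$edges), x$alpha,
              if (x$fdr) ", BH-FDR" else ""))
  invisible(x)
}

edge_keys <- function(e, signed = TRUE) {
  if (nrow(e$edges) == 0) return(character(0))
  a <- pmin(e$edges$node_a, e$edges$node_b)
  b <- pmax(e$edges$node_a, e$edges$node_b)
  if (signed) paste(a, b, e$edges$sign, sep = "|") else paste(a, b, sep = "|")
}

#' Compare two correlation networks
#'
#' Intersection and differences of node and (unsigned) edge sets, plus
#' a connectivity summary per network, for contrasting e.g. the tumour
#' and normal-mucosa networks.
#'
#' @param a,b `edge_set` objects.
#' @return list with `shared_nodes`, `shared_edges`, `only_a`,
#'   `only_b` (node names), and `summary` (node/edge counts and mean
#'   degree per network). Symmetric in its intersection components.
#' @export
compare_networks <- function(a, b) {
  stopifnot(inherits(a, "edge_set"), inherits(b, "edge_set"))
  na <- a$nodes$name; nb <- b$nodes$name
  ea <- edge_keys(a, signed = FALSE); eb <- edge_keys(b, signed = FALSE)
  summ <- function(e) {
    deg <- table(c(e$edges$node_a, e$edges$node_b))
    data.frame(nodes = nrow(e$nodes), edges = nrow(e$edges),
               mean_degree = if (nrow(e$nodes)) 2 * nrow(e$edges) / nrow(e$nodes) else 0)
  }
  list(shared_nodes = intersect(na, nb),
       shared_edges = intersect(ea, eb),
       only_a = setdiff(na, nb), only_b = setdiff(nb, na),
       summary = rbind(a = summ(a), b = summ(b)))
}

#' Edges consistent across cancer stages
#'
#' Intersection over per-stage networks of signed edges: a pair must be
#' present with the same correlation sign in every stage to be
#' reported (a sign flip excludes the edge).
#'
#' @param edge_sets named list of >= 2 per-stage `edge_set`s.
#' @return data.frame of consistent edges (`node_a`, `node_b`, `sign`).
#' @export
stage_consistency <- function(edge_sets) {
  if (length(edge_sets) < 2)
    stopf("stage consistency needs at least 2 stage networks")
  keys <- Reduce(intersect, lapply(edge_sets, edge_keys, signed = TRUE))
  if (length(keys) == 0)
    return(data.frame(node_a = character(0), node_b = character(0),
                      sign = numeric(0)))
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  data.frame(node_a = parts[, 1], node_b = parts[, 2],
             sign = as.numeric(parts[, 3]), stringsAsFactors = FALSE)
}

#' Spring-embedded network layout
#'
#' Fruchterman-Reingold force-directed placement with edge attraction
#' weighted by `|rho|`; deterministic under the seed. Disconnected
#' components are laid out separately and tiled so their bounding
#' boxes do not overlap.
#'
#' @param e an `edge_set`.
#' @param iterations FR iterations.
#' @param seed integer seed.
#' @param separate_components tile components side by side.
#' @return object of class `network_layout`: `coordinates` (data.frame
#'   `name`, `x`, `y`), `iterations`, `seed`.
#' @export
spring_layout <- function(e, iterations = 500L, seed = 1L,
                          separate_components = TRUE) {
  stopifnot(inherits(e, "edge_set"))
  if (nrow(e$nodes) == 0) stopf("layout needs at least one node")
  g <- igraph::graph_from_data_frame(
    e$edges[, c("node_a", "node_b"), drop = FALSE],
    directed = FALSE, vertices = e$nodes$name)
  set.seed(seed)
  w <- if (nrow(e$edges)) abs(e$edges$rho) else NULL
  comps <- igraph::components(g)
  coords <- matrix(0, igraph::vcount(g), 2)
  if (separate_components && comps$no > 1) {
    x_off <- 0
    for (ci in seq_len(comps$no)) {
      vs <- which(comps$membership == ci)
      sub <- igraph::induced_subgraph(g, vs)
      sw <- if (nrow(e$edges)) {
        sub_e <- igraph::as_edgelist(sub)
        if (nrow(sub_e)) {
          k <- paste(pmin(sub_e[, 1], sub_e[, 2]), pmax(sub_e[, 1], sub_e[, 2]))
          ek <- paste(pmin(e$edges$node_a, e$edges$node_b),
                      pmax(e$edges$node_a, e$edges$node_b))
          abs(e$edges$rho)[match(k, ek)]
        } else NULL
      } else NULL
      xy <- igraph::layout_with_fr(sub, niter = iterations, weights = sw)
      xy <- sweep(xy, 2, apply(xy, 2, min))        # move to origin
      coords[vs, ] <- cbind(xy[, 1] + x_off, xy[, 2])
      x_off <- x_off + max(xy[, 1], 1) + 1          # gap between boxes
    }
  } else {
    coords <- igraph::layout_with_fr(g, niter = iterations, weights = w)
  }
  structure(list(coordinates = data.frame(name = igraph::V(g)$name,
                                          x = coords[, 1], y = coords[, 2],
                                          stringsAsFactors = FALSE),
                 iterations = iterations, seed = seed),
            class = "network_layout")
}

#' Integrate metabolite bucket intensities from a spectral matrix
#'
#' Sums the normalized (pre-scaling) spectral intensity over each
#' template's peak regions (each multiplet centre +/- `halfwidth`),
#' yielding one value per metabolite per sample: the feature matrix
#' the correlation network is built on.
#'
#' @param m a normalized `spectral_matrix`.
#' @param templates list of [metabolite_template()]s.
#' @param halfwidth integration half-window around each peak centre
#'   (ppm).
#' @return samples x metabolites matrix.
#' @export
metabolite_buckets <- function(m, templates = default_metabolite_templates(),
                               halfwidth = 0.03) {
  stopifnot(inherits(m, "spectral_matrix"))
  if (isTRUE(m$flags$scaled))
    stopf("bucket integration uses the normalized, unscaled matrix")
  out <- vapply(templates, function(tpl) {
    sel <- rep(FALSE, length(m$bins))
    for (r in seq_len(nrow(tpl$peaks)))
      sel <- sel | abs(m$bins - tpl$peaks$centre_ppm[r]) <= halfwidth
    if (!any(sel)) return(rep(NA_real_, nrow(m$X)))
    rowSums(m$X[, sel, drop = FALSE])
  }, numeric(nrow(m$X)))
  colnames(out) <- vapply(templates, `[[`, "", "name")
  rownames(out) <- m$sample_ids
  out
}
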