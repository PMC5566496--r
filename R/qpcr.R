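#' Delta-Ct relative quantification
#'
#' For each sample with both a target (Fusobacterium nucleatum) and a
#' pan-bacterial 16S Ct, computes `delta_ct = ct_fn - ct_pan` and the
#' relative quantity `efficiency^(-delta_ct)` (2 per cycle by default).
#' Ct is inversely proportional to log copy number, so the smaller the
#' difference the greater the relative target quantity. Samples
#' missing either target are reported and excluded.
#'
#' @param records data.frame with columns `sample_id`, `target`
#'   (`"fn"` / `"pan"`), `ct`.
#' @param efficiency amplification factor per cycle.
#' @return list with `quant` (data.frame `sample_id`, `delta_ct`,
#'   `rel_quantity`) and `excluded` (sample ids lacking a target).
#' @export
delta_ct <- function(records, efficiency = 2) {
  stopifnot(all(c("sample_id", "target", "ct") %in% names(records)))
  if (efficiency <= 1) stopf("amplification efficiency must exceed 1")
  wide <- split(records, records$sample_id)
  rows <- lapply(wide, function(d) {
    fn <- d$ct[d$target == "fn"]; pan <- d$ct[d$target == "pan"]
    if (length(fn) != 1 || length(pan) != 1) return(NULL)
    data.frame(sample_id = d$sample_id[1], delta_ct = fn - pan,
               rel_quantity = efficiency^(-(fn - pan)),
               stringsAsFactors = FALSE)
  })
  ok <- !vapply(rows, is.null, TRUE)
  quant <- do.call(rbind, rows[ok])
  if (is.null(quant))
    quant <- data.frame(sample_id = character(0), delta_ct = numeric(0),
                        rel_quantity = numeric(0))
  rownames(quant) <- NULL
  list(quant = quant, excluded = names(wide)[!ok])
}

#' Paired site comparison of qPCR relative quantities
#'
#' Tests whether the target is over-represented on tumour relative to
#' a comparison site with a paired Wilcoxon signed-rank test (one-sided
#' by default: tumour greater). Patients missing either sample are
#' dropped with a warning.
#'
#' @param quant data.frame from [delta_ct()]`$quant`.
#' @param patient_ids,sites per-sample labels aligned with `quant`
#'   rows.
#' @param site_a,site_b sites compared (alternative: `site_a > site_b`).
#' @param alternative passed to [stats::wilcox.test()].
#' @return list with `statistic`, `p`, `n_pairs`, `alternative`.
#' @export
site_comparison <- function(quant, patient_ids, sites,
                            site_a = "tumour", site_b = "10cm",
                            alternative = "greater") {
  stopifnot(nrow(quant) == length(patient_ids),
            nrow(quant) == length(sites))
  a <- stats::setNames(quant$rel_quantity[sites == site_a],
                       patient_ids[sites == site_a])
  b <- stats::setNames(quant$rel_quantity[sites == site_b],
                       patient_ids[sites == site_b])
  common <- intersect(names(a), names(b))
  dropped <- setdiff(union(names(a), names(b)), common)
  if (length(dropped))
    warning(sprintf("dropping unpaired patient(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  if (length(common) < 2) stopf("fewer than 2 complete pairs")
  if (all(a[common] == b[common]))   # no evidence either way
    return(list(statistic = 0, p = 1, n_pairs = length(common),
                alternative = alternative))
  wt <- suppressWarnings(stats::wilcox.test(a[common], b[common],
                                            paired = TRUE,
                                            alternative = alternative))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_pairs = length(common), alternative = alternative)
}
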