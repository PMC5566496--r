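#' Read and write the pipeline's plain-text formats
#'
#' OTU tables are TSV (first column `sample_id`, one column per genus,
#' integer counts); metadata and Ct tables are CSV; spectra are CSV
#' with a `ppm` column plus one intensity column per sample. Readers
#' validate the schema and report offending rows/ids.
#'
#' @param path file path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @param meta optional metadata used to attach patient/site labels.
#' @export
read_otu_table <- function(path, meta = NULL) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "sample_id") stopf("%s: first column must be 'sample_id'", path)
  if (anyDuplicated(d$sample_id))
    stopf("%s: duplicate sample id '%s'", path, d$sample_id[duplicated(d$sample_id)][1])
  counts <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(counts)) stopf("%s: non-numeric counts", path)
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg))
    stopf("%s: negative count at line %d, column '%s'", path,
          neg[1, 1] + 1L, colnames(counts)[neg[1, 2]])
  frac <- which(counts != round(counts), arr.ind = TRUE)
  if (nrow(frac))
    stopf("%s: non-integer count at line %d, column '%s'", path,
          frac[1, 1] + 1L, colnames(counts)[frac[1, 2]])
  rownames(counts) <- d$sample_id
  storage.mode(counts) <- "integer"
  pid <- sites <- NULL
  if (!is.null(meta)) {
    i <- match(d$sample_id, meta$sample_id)
    if (anyNA(i)) stopf("%s: sample '%s' missing from metadata", path,
                        d$sample_id[which(is.na(i))[1]])
    pid <- meta$patient_id[i]; sites <- meta$site[i]
  }
  otu_table(counts, patient_ids = pid, sites = sites)
}

#' @rdname pipeline_io
#' @param t an [otu_table()].
#' @export
write_otu_table <- function(t, path) {
  d <- data.frame(sample_id = rownames(t$counts), t$counts,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_metadata <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(sample_id = "character"))
  need <- c("sample_id", "patient_id", "site")
  miss <- setdiff(need, names(m))
  if (length(miss)) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stopf("%s: duplicate sample id '%s'", path, m$sample_id[duplicated(m$sample_id)][1])
  m
}

#' @rdname pipeline_io
#' @param meta metadata data.frame.
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_spectra <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "ppm") stopf("%s: first column must be 'ppm'", path)
  ppm <- d$ppm
  dp <- diff(ppm)
  if (length(dp) && !(all(dp > 0) || all(dp < 0)))
    stopf("%s: non-monotone ppm axis (first violation after line %d)",
          path, which(sign(dp) != sign(dp[1]))[1] + 1L)
  ids <- names(d)[-1]
  if (anyDuplicated(ids)) stopf("%s: duplicate sample id '%s'", path,
                                ids[duplicated(ids)][1])
  spectrum_set(lapply(ids, function(id) spectrum(ppm, d[[id]], id)))
}

#' @rdname pipeline_io
#' @param spectra a [spectrum_set()] with a shared ppm axis.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectrum_set"))
  ppm <- spectra$spectra[[1]]$ppm
  for (s in spectra$spectra)
    if (!isTRUE(all.equal(s$ppm, ppm)))
      stopf("spectra CSV export needs a shared ppm axis ('%s' differs)",
            s$sample_id)
  d <- data.frame(ppm = ppm, check.names = FALSE)
  for (s in spectra$spectra) d[[s$sample_id]] <- s$intensity
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_ct <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target", "ct")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (!all(d$target %in% c("fn", "pan")))
    stopf("%s: target must be 'fn' or 'pan' (line %d)", path,
          which(!d$target %in% c("fn", "pan"))[1] + 1L)
  bad <- !is.finite(d$ct) | d$ct <= 0
  if (any(bad)) stopf("%s: nonpositive Ct at line %d", path, which(bad)[1] + 1L)
  d
}

#' @rdname pipeline_io
#' @param ct Ct data.frame.
#' @export
write_ct <- function(ct, path) {
  utils::write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param m a `spectral_matrix`.
#' @export
write_spectral_matrix <- function(m, path) {
  stopifnot(inherits(m, "spectral_matrix"))
  d <- data.frame(sample_id = m$sample_ids,
                  signif(m$X, 8), check.names = FALSE)
  names(d)[-1] <- sprintf("%.5f", m$bins)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param dend a `ward_dendrogram`.
#' @export
write_dendrogram <- function(dend, path) {
  stopifnot(inherits(dend, "ward_dendrogram"))
  ape::write.tree(ape::as.phylo(dend$hclust), file = path)
  invisible(path)
}

#' @rdname pipeline_io
#' @param e an `edge_set`; writes the edge table as TSV.
#' @export
write_edge_set <- function(e, path) {
  stopifnot(inherits(e, "edge_set"))
  ed <- e$edges
  ed$rho <- signif(ed$rho, 8); ed$p <- signif(ed$p, 8); ed$q <- signif(ed$q, 8)
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
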