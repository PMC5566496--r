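#' Single 1H spectrum
#'
#' @param ppm strictly monotone chemical-shift axis.
#' @param intensity intensities, same length as `ppm`.
#' @param sample_id sample identifier.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(ppm, intensity, sample_id = "sample") {
  if (length(ppm) != length(intensity))
    stopf("ppm and intensity lengths differ for '%s'", sample_id)
  d <- diff(ppm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stopf("ppm axis must be strictly monotone for '%s'", sample_id)
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 sample_id = sample_id, calibrated = FALSE),
            class = "spectrum")
}

#' Collection of spectra
#' @param spectra list of [spectrum()] objects.
#' @export
spectrum_set <- function(spectra) {
  stopifnot(all(vapply(spectra, inherits, TRUE, "spectrum")))
  ids <- unname(vapply(spectra, `[[`, "", "sample_id"))
  if (anyDuplicated(ids)) stopf("duplicate sample id '%s'", ids[duplicated(ids)][1])
  structure(list(spectra = spectra, sample_ids = ids), class = "spectrum_set")
}

#' @export
length.spectrum_set <- function(x) length(x$spectra)

#' Calibrate a spectrum to the alanine methyl doublet
#'
#' Shifts the ppm axis so the apex of the tallest peak inside the search
#' window sits at the alanine methyl reference position (1.47 ppm).
#'
#' @param s a [spectrum()] or [spectrum_set()].
#' @param search_window `(lo, hi)` ppm window searched for the apex.
#' @param reference_ppm target position of the apex.
#' @return the calibrated object, flagged `calibrated`.
#' @export
calibrate_to_alanine <- function(s, search_window = c(1.40, 1.55),
                                 reference_ppm = 1.47) {
  if (inherits(s, "spectrum_set")) {
    s$spectra <- lapply(s$spectra, calibrate_to_alanine,
                        search_window = search_window,
                        reference_ppm = reference_ppm)
    return(s)
  }
  stopifnot(inherits(s, "spectrum"))
  idx <- which(s$ppm >= search_window[1] & s$ppm <= search_window[2])
  if (length(idx) < 3)
    stopf("calibration window [%g, %g] outside the axis of '%s'",
          search_window[1], search_window[2], s$sample_id)
  y <- s$intensity[idx]
  if (diff(range(y)) <= 0)
    stopf("no peak found in calibration window for '%s' (flat signal)",
          s$sample_id)
  apex <- idx[which.max(y)]
  # require a local maximum, not a window-edge ramp
  if (apex == idx[1] || apex == idx[length(idx)])
    stopf("no local maximum in calibration window for '%s'", s$sample_id)
  s$ppm <- s$ppm - (s$ppm[apex] - reference_ppm)
  s$calibrated <- TRUE
  s
}

#' Bin spectra onto a uniform statistical matrix
#'
#' Builds the samples-by-bins matrix used for all downstream modelling:
#' contiguous half-open bins `[lo + k*res, lo + (k+1)*res)` spanning the
#' full region (-1 to 10 ppm at 0.00055 ppm by default, i.e. 20000
#' bins); the bin value is the mean intensity of raw points falling in
#' the bin (0 where no point falls).
#'
#' @param spectra a [spectrum_set()] (or list of spectra).
#' @param lo,hi region bounds in ppm.
#' @param resolution bin width in ppm.
#' @return a `spectral_matrix`.
#' @export
bin_spectra <- function(spectra, lo = -1, hi = 10, resolution = 0.00055) {
  if (inherits(spectra, "spectrum_set")) spectra <- spectra$spectra
  if (length(spectra) == 0) stopf("empty spectrum list")
  n_bins <- floor((hi - lo) / resolution + 1e-9)
  edges <- lo + (0:n_bins) * resolution
  centres <- edges[-1] - resolution / 2
  X <- matrix(0, length(spectra), n_bins)
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    keep <- s$ppm >= lo & s$ppm < edges[n_bins + 1]
    b <- floor((s$ppm[keep] - lo) / resolution) + 1
    b[b > n_bins] <- n_bins
    sums <- rowsum(s$intensity[keep], b)
    cnt <- rowsum(rep(1, length(b)), b)
    X[i, as.integer(rownames(sums))] <- sums / cnt
  }
  rownames(X) <- vapply(spectra, `[[`, "", "sample_id")
  spectral_matrix(X, centres,
                  flags = list(calibrated = all(vapply(spectra, `[[`, TRUE, "calibrated")),
                               excluded = FALSE, normalized = FALSE, scaled = FALSE))
}

#' Spectral statistical matrix
#'
#' @param X samples x bins matrix (rownames = sample ids).
#' @param bins strictly increasing bin-centre ppm vector.
#' @param flags processing provenance flags.
#' @export
spectral_matrix <- function(X, bins,
                            flags = list(calibrated = FALSE, excluded = FALSE,
                                         normalized = FALSE, scaled = FALSE)) {
  stopifnot(is.matrix(X), length(bins) == ncol(X))
  if (any(diff(bins) <= 0)) stopf("bin centres must be strictly increasing")
  if (!all(is.finite(X))) stopf("spectral matrix contains non-finite values")
  structure(list(X = X, bins = as.numeric(bins),
                 sample_ids = rownames(X), flags = flags,
                 dilution_factors = NULL, scale_centre = NULL,
                 scale_sd = NULL, zero_variance = NULL),
            class = "spectral_matrix")
}

#' @export
dim.spectral_matrix <- function(x) dim(x$X)

#' @export
print.spectral_matrix <- function(x, ...) {
  fl <- names(Filter(isTRUE, x$flags))
  cat(sprintf("spectral_matrix: %d samples x %d bins [%g, %g] ppm; flags: %s\n",
              nrow(x$X), ncol(x$X), min(x$bins), max(x$bins),
              if (length(fl)) paste(fl, collapse = ", ") else "none"))
  invisible(x)
}

#' Spectral exclusion region
#' @param lo_ppm,hi_ppm bounds (lo < hi).
#' @param label region label.
#' @export
exclusion_region <- function(lo_ppm, hi_ppm, label = "") {
  if (!(lo_ppm < hi_ppm)) stopf("exclusion region '%s': lo must be < hi", label)
  structure(list(lo_ppm = lo_ppm, hi_ppm = hi_ppm, label = label),
            class = "exclusion_region")
}

#' Default solvent/contaminant exclusion regions
#'
#' Water (4.50-5.19 ppm), ethanol (1.10-1.20 and 3.60-3.90 ppm) and
#' polyethylene glycol (3.70-3.75 ppm, nested inside the second ethanol
#' window): regions carrying no biological information.
#' @export
default_exclusion_regions <- function() {
  list(exclusion_region(4.50, 5.19, "water"),
       exclusion_region(1.10, 1.20, "ethanol"),
       exclusion_region(3.60, 3.90, "ethanol"),
       exclusion_region(3.70, 3.75, "PEG"))
}

#' Remove excluded spectral regions
#'
#' Drops every column whose bin centre falls inside any region; a column
#' covered by several overlapping regions is removed once.
#'
#' @param m a binned `spectral_matrix`.
#' @param regions list of [exclusion_region()]s.
#' @return reduced `spectral_matrix`, flagged `excluded`.
#' @export
apply_exclusions <- function(m, regions = default_exclusion_regions()) {
  stopifnot(inherits(m, "spectral_matrix"))
  if (isTRUE(m$flags$normalized))
    stopf("exclusions must be applied before normalization")
  drop <- rep(FALSE, length(m$bins))
  for (r in regions)
    drop <- drop | (m$bins >= r$lo_ppm & m$bins <= r$hi_ppm)
  if (all(drop)) stopf("exclusion regions cover every bin")
  m$X <- m$X[, !drop, drop = FALSE]
  m$bins <- m$bins[!drop]
  m$flags$excluded <- TRUE
  m
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution: (1) each row is total-area normalized;
#' (2) the reference is the column-wise median spectrum; (3) each row's
#' quotient factor is the median of row/reference over columns where
#' the reference is positive; (4) the row is divided by its factor.
#' The stored `dilution_factors` combine the area and quotient factors,
#' so they are proportional to the physical per-sample dilution.
#'
#' @param m an excluded `spectral_matrix` with nonnegative intensities.
#' @param reference optional reference row (defaults to the median
#'   spectrum of the area-normalized matrix).
#' @return normalized `spectral_matrix` with `dilution_factors` set.
#' @export
pqn_normalize <- function(m, reference = NULL) {
  stopifnot(inherits(m, "spectral_matrix"))
  if (isTRUE(m$flags$scaled)) stopf("cannot normalize an already scaled matrix")
  areas <- rowSums(m$X)
  if (any(areas <= 0))
    stopf("zero-area row(s): %s",
          paste(m$sample_ids[areas <= 0], collapse = ", "))
  Xa <- m$X / areas
  ref <- if (is.null(reference)) apply(Xa, 2, stats::median) else reference
  pos <- ref > 0
  if (!any(pos)) stopf("all-zero reference spectrum")
  q <- apply(Xa[, pos, drop = FALSE], 1, function(r)
    stats::median(r / ref[pos]))
  m$X <- Xa / q
  m$dilution_factors <- stats::setNames(areas * q / stats::median(areas * q),
                                        m$sample_ids)
  m$pqn_reference <- ref
  m$flags$normalized <- TRUE
  m
}

#' Unit-variance scale a spectral matrix
#'
#' Mean-centres each column and divides by its sample standard
#' deviation. Zero-variance columns are centred only and flagged so
#' model stages can ignore them; column means/sds are stored so the
#' same scaling can be applied to held-out samples.
#'
#' @param m a normalized `spectral_matrix`.
#' @return scaled `spectral_matrix` with `scale_centre`, `scale_sd` and
#'   `zero_variance` fields.
#' @export
unit_variance_scale <- function(m) {
  stopifnot(inherits(m, "spectral_matrix"))
  if (!isTRUE(m$flags$normalized))
    stopf("matrix must be normalized before unit-variance scaling")
  mu <- colMeans(m$X)
  sd <- col_sds(m$X)
  zv <- sd == 0 | !is.finite(sd)
  sd[zv] <- 1
  m$X <- sweep(sweep(m$X, 2, mu), 2, sd, "/")
  m$scale_centre <- mu
  m$scale_sd <- sd
  m$zero_variance <- zv
  m$flags$scaled <- TRUE
  m
}

#' Statistical total correlation spectroscopy (STOCSY)
#'
#' Correlates one driver bin against every bin of the matrix, returning
#' per-bin Pearson r and covariance. Peaks of a single molecule
#' correlate near 1 with each other, which supports data-driven
#' structural assignment. Computed on the normalized (not unit-variance
#' scaled) matrix.
#'
#' @param m a normalized, unscaled `spectral_matrix` with >= 3 samples.
#' @param driver_ppm chemical shift of the driver bin (nearest bin used).
#' @return data.frame with `ppm`, `r`, `covariance`.
#' @export
stocsy <- function(m, driver_ppm) {
  stopifnot(inherits(m, "spectral_matrix"))
  if (isTRUE(m$flags$scaled))
    stopf("STOCSY runs on the normalized, not unit-variance scaled, matrix")
  if (nrow(m$X) < 3) stopf("STOCSY needs at least 3 samples")
  j <- which.min(abs(m$bins - driver_ppm))
  if (abs(m$bins[j] - driver_ppm) > 10 * stats::median(diff(m$bins)))
    stopf("no bin near driver ppm %g", driver_ppm)
  d <- m$X[, j]
  if (stats::sd(d) == 0) stopf("driver column at %g ppm is constant", m$bins[j])
  Xc <- sweep(m$X, 2, colMeans(m$X))
  dc <- d - mean(d)
  n <- nrow(m$X)
  cov <- as.numeric(crossprod(Xc, dc)) / (n - 1)
  sds <- sqrt(colSums(Xc^2) / (n - 1))
  r <- cov / (sds * stats::sd(d))
  r[sds == 0] <- NA_real_
  data.frame(ppm = m$bins, r = r, covariance = cov)
}
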