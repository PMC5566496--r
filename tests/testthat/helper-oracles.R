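# Brute-force oracles, kept independent of the package implementations.

shannon_brute <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

bray_brute <- function(u, v) sum(abs(u - v)) / sum(u + v)

# Kendall tau-b via O(n^2) pair counting with tie corrections
tau_b_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Spearman rho as Pearson on midranks
spearman_brute <- function(x, y) stats::cor(rank(x), rank(y))

# Benjamini-Hochberg step-up by direct construction
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# small metadata frame for unit tests
tiny_meta <- function(n_patients = 4, sites = c("tumour", "5cm", "10cm")) {
  simulate_metadata(cohort_config(n_patients = n_patients, sites = sites,
                                  seed = 42))
}

# single-metabolite template helpers
singlet_template <- function(name = "x", centre = 2.5, lfc = 0) {
  metabolite_template(name, data.frame(centre_ppm = centre, multiplicity = 1L,
                                       j_spacing_ppm = 0.0175,
                                       rel_intensity = 1),
                      tumour_log_fc = lfc)
}

neutral_templates <- function() {
  lapply(default_metabolite_templates(), function(t) { t$tumour_log_fc <- 0; t })
}
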