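#' @keywords internal
"_PACKAGE"

# Derive a stage seed from a run seed; keeps every stream below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# softmax over a numeric vector
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# fast column standard deviations
col_sds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sqrt(pmax(colSums(X^2) - n * mu^2, 0) / (n - 1))
}
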