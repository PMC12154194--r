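# Internal numeric helpers shared across modules.

# Row means/variances with NA handling, without looping in R.
.rowStats <- function(x) {
  n <- rowSums(!is.na(x))
  mu <- rowMeans(x, na.rm = TRUE)
  mu[n == 0L] <- NA_real_
  ss <- rowSums((x - mu)^2, na.rm = TRUE)
  v <- ifelse(n > 1L, ss / (n - 1L), NA_real_)
  list(n = n, mean = mu, var = v)
}

# Serialize doubles at full precision so tables round-trip bit-comparably.
.formatFull <- function(x) {
  if (is.double(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "NA" else sprintf("%.17g", v)
    }, character(1L))
    out
  } else if (is.logical(x) || is.integer(x) || is.factor(x)) {
    as.character(x)
  } else {
    as.character(x)
  }
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Derive a stream-specific 32-bit seed from a base seed; keeps independent
# stages decoupled while remaining a pure function of the base seed.
.deriveSeed <- function(seed, stream) {
  s <- (as.numeric(seed) * 69069 + 12345 * stream) %% 2147483647
  as.integer(s)
}
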