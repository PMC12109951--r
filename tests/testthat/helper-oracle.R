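# Independent brute-force reference for the entropy feature, written as
# plain double loops straight from the defining sums. Deliberately naive:
# it shares no code with the package implementation.

oracle_phi <- function(x, m, r, delay = 1) {
  N <- length(x)
  n <- N - (m - 1) * delay
  stopifnot(n >= 2)
  templates <- lapply(seq_len(n), function(i) {
    v <- x[i + (0:(m - 1)) * delay]
    v - mean(v)
  })
  total <- 0
  for (i in seq_len(n)) {
    ci <- 0
    for (j in seq_len(n)) {
      d <- max(abs(templates[[i]] - templates[[j]]))
      ci <- ci + exp(-d^2 / (2 * r^2))
    }
    total <- total + log(ci / n)
  }
  total / n
}

oracle_fapen <- function(x, m, k = 0.2) {
  r <- max(k * stats::sd(x), 1e-12)
  oracle_phi(x, m, r) - oracle_phi(x, m + 1, r)
}

oracle_mfapen <- function(x, m = 2, scales = 1:3, k = 0.2, eps = 1e-6) {
  r <- max(k * stats::sd(x), 1e-12)
  terms <- vapply(scales, function(s) {
    EX <- oracle_phi(x, m * s, r) - oracle_phi(x, m * s + 1, r)
    EY <- oracle_phi(x, m * s + 1, r) - oracle_phi(x, m * s + 2, r)
    EX <- max(EX, 0)
    EY <- max(EY, 0)
    EY * log((EY + eps) / (EX + eps))
  }, numeric(1))
  -mean(terms)
}

oracle_mfaren <- function(x, ...) oracle_mfapen(x, ...) + sqrt(mean(x^2))
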