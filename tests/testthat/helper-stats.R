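## Brute-force step-up oracle for the Benjamini-Hochberg procedure: reject
## H_(1..k) where k is the largest i with p_(i) <= i/m * alpha.
bhOracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) / m * alpha)))
  rej <- logical(m)
  if (is.finite(k) && k >= 1) rej[o[seq_len(k)]] <- TRUE
  rej
}
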