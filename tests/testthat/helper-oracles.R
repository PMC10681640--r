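# Independent oracles used by both the unit and acceptance suites.

# literal Benjamini-Hochberg step-up rule, written independently of p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# data with an exact sample correlation matrix: centered orthonormal basis
# times the Cholesky factor of the target matrix
exact_corr_data <- function(R, n = 40, seed = 1) {
  set.seed(seed)
  A <- scale(matrix(rnorm(n * ncol(R)), n), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(A))
  Q %*% chol(R)
}
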