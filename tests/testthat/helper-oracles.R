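# Independent oracles, deliberately written without reusing the package's
# vectorized code paths.

# Var(sum_c w_c Z_c) by explicit construction of the C x C covariance
# matrix of study-level Z scores, with scalar double loops.
brute_force_sigma2 <- function(sizes, h2, among, m_causal) {
  C <- length(sizes)
  NT <- sum(sizes)
  V <- matrix(0, C, C)
  for (c in seq_len(C)) {
    for (d in seq_len(C)) {
      V[c, d] <- if (c == d) {
        1 + sizes[c] * h2[c] / m_causal
      } else {
        sqrt(sizes[c] * sizes[d]) * among[c, d] *
          sqrt(h2[c] * h2[d]) / m_causal
      }
    }
  }
  w <- sqrt(sizes / NT)
  out <- 0
  for (c in seq_len(C)) for (d in seq_len(C)) out <- out + w[c] * w[d] * V[c, d]
  out
}

# random valid design with a factor-model correlation matrix (PSD by
# construction) for property sweeps
random_design <- function(seed, max_studies = 10) {
  set.seed(seed)
  C <- sample(1:max_studies, 1)
  sizes <- sample(500:50000, C, replace = TRUE)
  h2 <- runif(C, 0.05, 0.8)
  L <- matrix(rnorm((C + 1) * 2), C + 1, 2)
  Sigma <- tcrossprod(L) + diag(runif(C + 1, 0.2, 1))
  R <- stats::cov2cor(Sigma)
  list(panel = study_panel(sizes, h2),
       cgr = cgr_structure(R[seq_len(C), seq_len(C), drop = FALSE],
                           R[seq_len(C), C + 1], runif(1, 0.05, 0.8)),
       arch = architecture(sample(2000:100000, 1), sample(100:2000, 1)))
}
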