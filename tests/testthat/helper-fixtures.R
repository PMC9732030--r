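# Small fixtures built in code; everything is seeded.

tiny_assoc <- function() {
  A <- matrix(c(1, 0, 1, 0, 0, 1), 2, 3)
  association_data(A, c("CID 1", "CID 2"),
                   c("hsa-mir-a", "hsa-mir-b", "hsa-mir-c"))
}

# a small planted-block instance, cheap enough for repeated CV loops;
# near-deterministic blocks so that at this size the low-rank branch of
# the denoiser (rather than the all-noise branch) is optimal and the
# graph retains signal
small_synth <- function(seed = 5) {
  generate_synthetic(synthetic_spec(n_sm = 10, n_mirna = 20, n_blocks = 2,
                                    p_in = 0.9, p_out = 0.02,
                                    sim_noise = 0.02, seed = seed))
}

# fast run configuration for training tests
fast_config <- function(...) {
  args <- utils::modifyList(
    list(embed_dim = 8, epochs = 30, seed = 7, cv_seed = 7), list(...))
  do.call(run_config, args)
}

# 1-D brute-force prox oracles (independent of the closed forms):
# nuclear-norm prox reduces to per-singular-value scalar problems by
# unitary invariance; the L2,1 prox is separable per column and the
# minimizer is a non-negative multiple of the column.
svt_oracle <- function(M, tau) {
  s <- svd(M)
  d <- vapply(s$d, function(sig) {
    stats::optimize(function(x) tau * x + 0.5 * (x - sig)^2,
                    c(0, sig + 2 * tau + 1), tol = 1e-12)$minimum
  }, 0)
  s$u %*% (d * t(s$v))
}

l21_oracle <- function(M, tau) {
  out <- M
  for (j in seq_len(ncol(M))) {
    m <- M[, j]
    nrm <- sqrt(sum(m^2))
    if (nrm == 0) next
    t_opt <- stats::optimize(function(t) tau * t * nrm + 0.5 * nrm^2 * (t - 1)^2,
                             c(0, 1), tol = 1e-12)$minimum
    out[, j] <- t_opt * m
  }
  out
}
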