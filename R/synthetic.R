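#' Specification of a synthetic SM--miRNA dataset
#'
#' Describes a bipartite association matrix with planted block
#' structure plus block-consistent similarity matrices, so the whole
#' denoise-embed-score pipeline can be exercised without any external
#' data.  SMs and miRNAs are assigned to blocks round-robin;
#' associations occur with probability `p_in` within a block and
#' `p_out` across blocks; similarities are elevated within blocks
#' (mirroring the premise that similar molecules share miRNA targets).
#' The defaults emulate the sparsity of curated association data at
#' desk scale: 40 SMs x 120 miRNAs in two blocks with an expected
#' count of about 146 associations (density ~3%).
#'
#' @param n_sm,n_mirna numbers of SMs and miRNAs.
#' @param n_blocks number of planted blocks.
#' @param p_in association probability within a block (in (0, 1\]).
#' @param p_out association probability across blocks (< `p_in`).
#' @param sim_in mean within-block similarity (> `sim_out`).
#' @param sim_out mean cross-block similarity.
#' @param sim_noise standard deviation of the Gaussian jitter added to
#'   similarities before clipping to \[0, 1\].
#' @param seed integer seed; generation is fully deterministic given
#'   the spec.
#' @return list of class `smma_synth_spec`.
#' @export
synthetic_spec <- function(n_sm = 40L, n_mirna = 120L, n_blocks = 2L,
                           p_in = 0.06, p_out = 0.001, sim_in = 0.8,
                           sim_out = 0.2, sim_noise = 0.05, seed = 1L) {
  stopifnot(n_sm >= 1, n_mirna >= 1, n_blocks >= 1,
            p_in > 0, p_in <= 1, p_out >= 0, p_out < 1,
            p_in > p_out, sim_in > sim_out, sim_noise >= 0)
  structure(list(n_sm = as.integer(n_sm), n_mirna = as.integer(n_mirna),
                 n_blocks = as.integer(n_blocks), p_in = p_in,
                 p_out = p_out, sim_in = sim_in, sim_out = sim_out,
                 sim_noise = sim_noise, seed = as.integer(seed)),
            class = "smma_synth_spec")
}

sim_block_matrix <- function(block, sim_in, sim_out, sim_noise) {
  n <- length(block)
  S <- ifelse(outer(block, block, `==`), sim_in, sim_out)
  if (sim_noise > 0) {
    E <- matrix(0, n, n)
    up <- upper.tri(E)
    E[up] <- stats::rnorm(sum(up), 0, sim_noise)
    S <- S + E + t(E)
  }
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  S
}

#' Generate a synthetic dataset with planted block structure
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data` (an [association_data()]), `SSM`, `SMR`
#'   (similarity matrices with identifier dimnames), and `truth` (the
#'   block assignments `sm_block`, `mirna_block`).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "smma_synth_spec"))
  set.seed(spec$seed)
  sm_ids <- sprintf("CID %d", 1000 + seq_len(spec$n_sm))
  mirna_ids <- sprintf("hsa-mir-s%03d", seq_len(spec$n_mirna))
  sm_block <- (seq_len(spec$n_sm) - 1L) %% spec$n_blocks + 1L
  mirna_block <- (seq_len(spec$n_mirna) - 1L) %% spec$n_blocks + 1L
  p <- ifelse(outer(sm_block, mirna_block, `==`), spec$p_in, spec$p_out)
  A <- matrix(as.numeric(stats::runif(length(p)) < p),
              spec$n_sm, spec$n_mirna)
  SSM <- sim_block_matrix(sm_block, spec$sim_in, spec$sim_out, spec$sim_noise)
  SMR <- sim_block_matrix(mirna_block, spec$sim_in, spec$sim_out, spec$sim_noise)
  dimnames(SSM) <- list(sm_ids, sm_ids)
  dimnames(SMR) <- list(mirna_ids, mirna_ids)
  list(data = association_data(A, sm_ids, mirna_ids),
       SSM = SSM, SMR = SMR,
       truth = list(sm_block = sm_block, mirna_block = mirna_block))
}

#' Drop SMs and miRNAs with no known association
#'
#' Removes all-zero rows and columns from the association matrix,
#' reducing the identifier lists consistently; the number of known
#' associations is unchanged.  This is the reduction that turns a full
#' identifier universe into the compact dataset containing only
#' entities that occur in at least one known pair.
#'
#' @param data an [association_data()] object.
#' @return the filtered [association_data()]; an input whose known
#'   associations are empty is an error.
#' @export
degree_filter <- function(data) {
  stopifnot(inherits(data, "smma_association"))
  keep_r <- rowSums(data$A) > 0
  keep_c <- colSums(data$A) > 0
  if (!any(keep_r) || !any(keep_c))
    stop("degree filter would remove every SM/miRNA (no known associations)")
  association_data(data$A[keep_r, keep_c, drop = FALSE],
                   data$sm_ids[keep_r], data$mirna_ids[keep_c])
}
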