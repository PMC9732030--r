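#' Ranking AUC of test scores against candidate scores
#'
#' Area under the ROC curve obtained by sweeping a rank threshold over
#' the pooled test and candidate scores: the fraction of test samples
#' above threshold is the true positive rate, the fraction of
#' candidates above it the false positive rate.  Computed as the
#' Mann-Whitney statistic with midranks, so ties contribute 1/2: 0.5
#' means random ranking, 1 perfect separation.
#'
#' @param test_scores numeric scores of the held-out (true) samples.
#' @param candidate_scores numeric scores of the candidate (unknown)
#'   samples.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(test_scores, candidate_scores) {
  nt <- length(test_scores)
  nc <- length(candidate_scores)
  if (nt == 0 || nc == 0) stop("test and candidate score lists must be non-empty")
  r <- rank(c(test_scores, candidate_scores), ties.method = "average")
  (sum(r[seq_len(nt)]) - nt * (nt + 1) / 2) / (nt * nc)
}

#' Scoring functions for the cross-validation harnesses
#'
#' Every CV harness takes a `scorer`: a function
#' `function(train_data, SSM, SMR, cfg)` returning an `ns x nm` score
#' matrix in association orientation.  `scorer_pipeline()` is the real
#' model (denoise + GCN, via [train_model()]); `scorer_random()` gives
#' every pair an independent uniform(0,1) score from the current RNG (a
#' calibration null whose AUC must hover at 0.5); `scorer_oracle(full)`
#' closes over the complete dataset and scores 1 exactly on pairs known
#' in `full` but absent from the training copy -- i.e. the held-out
#' pairs -- and 0 elsewhere, so a correct harness must report AUC 1.
#'
#' @param full an [association_data()] with the complete association
#'   set (for the oracle).
#' @param invert logical; the inverted oracle scores held-out pairs 0
#'   and everything else 1 (AUC must be exactly 0).
#' @return a scorer function.
#' @name scorers
NULL

#' @rdname scorers
#' @export
scorer_pipeline <- function() {
  function(train_data, SSM, SMR, cfg) score_matrix(train_model(train_data, SSM, SMR, cfg))
}

#' @rdname scorers
#' @export
scorer_random <- function() {
  function(train_data, SSM, SMR, cfg) {
    A <- train_data$A
    matrix(stats::runif(length(A)), nrow(A), ncol(A), dimnames = dimnames(A))
  }
}

#' @rdname scorers
#' @export
scorer_oracle <- function(full, invert = FALSE) {
  stopifnot(inherits(full, "smma_association"))
  function(train_data, SSM, SMR, cfg) {
    s <- (full$A == 1 & train_data$A == 0) * 1
    if (invert) 1 - s else s
  }
}

cv_result <- function(aucs, mode, n_test) {
  structure(list(auc_mean = mean(aucs),
                 auc_std = if (length(aucs) > 1) stats::sd(aucs) else 0,
                 per_repeat_aucs = aucs, mode = mode,
                 n_test_samples = n_test),
            class = "smma_cv")
}

#' @export
print.smma_cv <- function(x, ...) {
  cat(sprintf("%s: AUC %.4f +/- %.4f over %d AUC value(s), %d test samples\n",
              x$mode, x$auc_mean, x$auc_std, length(x$per_repeat_aucs),
              x$n_test_samples))
  invisible(x)
}

mask_pair <- function(data, i, j) {
  data$A[cbind(i, j)] <- 0
  data
}

#' Global leave-one-out cross-validation
#'
#' Each known association is held out in turn: it is zeroed in a
#' training copy of the association matrix (before denoising, so the
#' model never sees the test label), the scorer is retrained, and the
#' held-out pair's score is ranked against the scores of every unknown
#' pair.  One pooled AUC is computed over all held-out samples: all
#' held-out scores form the test list and all candidate scores from
#' every retraining form the candidate list of [rank_auc()].
#'
#' @param data an [association_data()] with at least 2 known
#'   associations.
#' @param SSM,SMR integrated similarity matrices.
#' @param cfg a [run_config()].
#' @param scorer see [scorers]; defaults to the full pipeline.
#' @return an `smma_cv` result (mode `"global_loocv"`).
#' @export
global_loocv <- function(data, SSM, SMR, cfg = run_config(),
                         scorer = scorer_pipeline()) {
  pairs <- which(data$A == 1, arr.ind = TRUE)
  if (nrow(pairs) < 2) stop("need at least 2 known associations")
  unknown <- data$A == 0
  tests <- numeric(nrow(pairs))
  cands <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    train <- mask_pair(data, pairs[p, 1], pairs[p, 2])
    s <- scorer(train, SSM, SMR, cfg)
    tests[p] <- s[pairs[p, 1], pairs[p, 2]]
    cands[[p]] <- s[unknown]
  }
  cv_result(rank_auc(tests, unlist(cands)), "global_loocv", nrow(pairs))
}

#' Local (miRNA-fixed or SM-fixed) leave-one-out cross-validation
#'
#' As [global_loocv()], but the candidate set of a held-out pair
#' `(s, m)` is restricted to unknown pairs sharing its miRNA `m`
#' (`mode = "mirna_fixed"`) or its SM `s` (`mode = "sm_fixed"`).
#' Held-out pairs with an empty restricted candidate set are skipped
#' with a warning and counted in the result.
#'
#' @inheritParams global_loocv
#' @param mode `"mirna_fixed"` or `"sm_fixed"`.
#' @return an `smma_cv` result with an extra `n_skipped` element.
#' @export
local_loocv <- function(data, SSM, SMR, cfg = run_config(),
                        mode = c("mirna_fixed", "sm_fixed"),
                        scorer = scorer_pipeline()) {
  mode <- match.arg(mode)
  pairs <- which(data$A == 1, arr.ind = TRUE)
  if (nrow(pairs) < 1) stop("need at least 1 known association")
  unknown <- data$A == 0
  tests <- numeric(0)
  cands <- list()
  skipped <- 0L
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    cand_cells <- if (mode == "mirna_fixed") which(unknown[, j]) else which(unknown[i, ])
    if (!length(cand_cells)) {
      skipped <- skipped + 1L
      next
    }
    train <- mask_pair(data, i, j)
    s <- scorer(train, SSM, SMR, cfg)
    tests <- c(tests, s[i, j])
    cands[[length(cands) + 1]] <-
      if (mode == "mirna_fixed") s[cand_cells, j] else s[i, cand_cells]
  }
  if (skipped > 0)
    warning(skipped, " held-out pair(s) skipped: empty candidate set")
  if (!length(tests)) stop("all candidate sets empty in ", mode, " LOOCV")
  out <- cv_result(rank_auc(tests, unlist(cands)),
                   paste0(sub("_fixed", "", mode), "_loocv"), length(tests))
  out$n_skipped <- skipped
  out
}

#' Repeated k-fold cross-validation
#'
#' Per repeat, the known associations are randomly partitioned into `k`
#' subsets whose sizes differ by at most one.  Each subset in turn is
#' zeroed out of the training matrix, the scorer retrained, and the
#' subset's pairs ranked against all unknown pairs, giving one AUC per
#' fold; the result aggregates all `repeats * k` fold AUCs.  All fold
#' assignments are drawn up-front from `seed`, independently of any
#' randomness inside the scorer, so partitions are reproducible.
#'
#' @inheritParams global_loocv
#' @param k number of folds (default 5).
#' @param repeats number of random re-partitions (the published
#'   protocol uses 100; smaller values are typical for desk-scale
#'   runs).
#' @param seed integer seed for the partitions; defaults to
#'   `cfg$cv_seed`.
#' @return an `smma_cv` result (mode `"kfold"`) with an extra `folds`
#'   element: a list (per repeat) of fold-index vectors over the known
#'   pairs.
#' @export
kfold_cv <- function(data, SSM, SMR, cfg = run_config(), k = 5L,
                     repeats = 1L, seed = cfg$cv_seed,
                     scorer = scorer_pipeline()) {
  pairs <- which(data$A == 1, arr.ind = TRUE)
  np <- nrow(pairs)
  if (k < 2) stop("k must be at least 2")
  if (np < k) stop("fewer known associations (", np, ") than folds (", k, ")")
  set.seed(seed)
  assignments <- lapply(seq_len(repeats), function(r)
    sample(rep_len(seq_len(k), np)))
  unknown <- data$A == 0
  aucs <- numeric(0)
  for (r in seq_len(repeats)) {
    fold_of <- assignments[[r]]
    for (f in seq_len(k)) {
      test_idx <- which(fold_of == f)
      train <- mask_pair(data, pairs[test_idx, 1], pairs[test_idx, 2])
      s <- scorer(train, SSM, SMR, cfg)
      aucs <- c(aucs, rank_auc(s[pairs[test_idx, , drop = FALSE]], s[unknown]))
    }
  }
  out <- cv_result(aucs, "kfold", np)
  out$folds <- assignments
  out
}

#' Rank candidate miRNAs for one small molecule
#'
#' Two case-study modes: mode 1 trains on all known associations and
#' ranks the miRNAs not already associated with the SM; mode 2 first
#' removes every known association of the investigated SM (so the model
#' predicts for an SM with no training signal of its own) and ranks all
#' its miRNAs.  Candidates are miRNAs not known-associated with the SM
#' in the training matrix; ties in score are broken lexicographically.
#'
#' @inheritParams global_loocv
#' @param sm_id identifier of the investigated SM.
#' @param mode 1 or 2.
#' @param top_n number of top-ranked miRNAs to return (default 50).
#' @return data.frame with columns `rank`, `mirna_id`, `score`.
#' @export
case_study <- function(data, SSM, SMR, cfg = run_config(), sm_id,
                       mode = 1, top_n = 50L,
                       scorer = scorer_pipeline()) {
  i <- match(sm_id, data$sm_ids)
  if (is.na(i)) stop("unknown SM id: ", sm_id)
  train <- data
  if (mode == 2) {
    if (sum(data$A[i, ]) < 1)
      stop("mode 2 requires at least one known association to remove")
    train$A[i, ] <- 0
  } else if (mode != 1) stop("mode must be 1 or 2")
  s <- scorer(train, SSM, SMR, cfg)
  candidates <- which(train$A[i, ] == 0)
  sc <- s[i, candidates]
  ids <- data$mirna_ids[candidates]
  ord <- order(-sc, ids)
  utils::head(data.frame(rank = seq_along(ord), mirna_id = ids[ord],
                         score = sc[ord], row.names = NULL), top_n)
}

#' Score a random control sample of unknown pairs
#'
#' Trains once on the full data, then uniformly samples `n_pairs`
#' unknown SM-miRNA pairs without replacement and reports their scores
#' and global ranks among all unknown pairs (rank 1 = highest score;
#' ties get midranks).  Used as a negative control for the case-study
#' rankings: randomly chosen pairs should sit near the middle of the
#' ranking.
#'
#' @inheritParams global_loocv
#' @param n_pairs how many unknown pairs to sample.
#' @param seed integer seed for the sample; defaults to `cfg$cv_seed`.
#' @return data.frame with columns `sm_id`, `mirna_id`, `score`,
#'   `rank`, and attribute `n_candidates` (total unknown pairs).
#' @export
random_control <- function(data, SSM, SMR, cfg = run_config(), n_pairs,
                           seed = cfg$cv_seed,
                           scorer = scorer_pipeline()) {
  unknown <- which(data$A == 0, arr.ind = TRUE)
  if (n_pairs > nrow(unknown))
    stop("n_pairs exceeds the number of unknown pairs (", nrow(unknown), ")")
  s <- scorer(data, SSM, SMR, cfg)
  scores <- s[unknown]
  ranks <- rank(-scores, ties.method = "average")
  set.seed(seed)
  idx <- sample.int(nrow(unknown), n_pairs)
  out <- data.frame(sm_id = data$sm_ids[unknown[idx, 1]],
                    mirna_id = data$mirna_ids[unknown[idx, 2]],
                    score = scores[idx], rank = ranks[idx])
  attr(out, "n_candidates") <- nrow(unknown)
  out
}
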