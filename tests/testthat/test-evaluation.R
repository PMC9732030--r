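test_that("rank AUC equals the pairwise-comparison oracle", {
  expect_equal(rank_auc(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(rank_auc(0.1, 0.9), 0.0)
  expect_equal(rank_auc(rep(0.5, 4), rep(0.5, 7)), 0.5)
  expect_error(rank_auc(numeric(0), 1), "non-empty")

  set.seed(1)
  for (rep in 1:5) {
    tests <- runif(30)
    cands <- sample(c(runif(250), tests[1:50 %% 30 + 1]))  # inject ties
    brute <- (sum(outer(tests, cands, `>`)) +
                0.5 * sum(outer(tests, cands, `==`))) /
      (length(tests) * length(cands))
    expect_equal(rank_auc(tests, cands), brute)
  }
})

test_that("oracle scorers bound every CV mode at exactly 1 and 0", {
  syn <- small_synth()
  d <- syn$data
  cfg <- fast_config()
  perfect <- scorer_oracle(d)
  inverted <- scorer_oracle(d, invert = TRUE)
  expect_equal(global_loocv(d, syn$SSM, syn$SMR, cfg, scorer = perfect)$auc_mean, 1.0)
  expect_equal(local_loocv(d, syn$SSM, syn$SMR, cfg, "mirna_fixed",
                           scorer = perfect)$auc_mean, 1.0)
  expect_equal(local_loocv(d, syn$SSM, syn$SMR, cfg, "sm_fixed",
                           scorer = perfect)$auc_mean, 1.0)
  expect_equal(kfold_cv(d, syn$SSM, syn$SMR, cfg, k = 5,
                        scorer = perfect)$auc_mean, 1.0)
  expect_equal(global_loocv(d, syn$SSM, syn$SMR, cfg, scorer = inverted)$auc_mean, 0.0)
  expect_equal(kfold_cv(d, syn$SSM, syn$SMR, cfg, k = 5,
                        scorer = inverted)$auc_mean, 0.0)
})

test_that("global LOOCV retrains once per known association", {
  A <- matrix(0, 3, 4)
  A[cbind(1:3, 1:3)] <- 1
  d <- association_data(A, paste0("s", 1:3), paste0("m", 1:4))
  calls <- 0L
  counting <- function(train, SSM, SMR, cfg) {
    calls <<- calls + 1L
    expect_equal(sum(train$A), 2)  # exactly one association held out
    matrix(0.5, 3, 4)
  }
  global_loocv(d, diag(3), diag(4), fast_config(), scorer = counting)
  expect_equal(calls, 3L)
})

test_that("local LOOCV restricts candidates to the shared miRNA or SM", {
  A <- matrix(0, 2, 2)
  A[1, 1] <- 1
  d <- association_data(A, c("s1", "s2"), c("m1", "m2"))
  seen <- list()
  spy <- function(train, SSM, SMR, cfg) {
    matrix(c(0.9, 0.4, 0.2, 0.1), 2, 2)
  }
  # miRNA-fixed: candidates for (s1,m1) = {(s2,m1)} -> test 0.9 vs 0.4
  r <- local_loocv(d, diag(2), diag(2), fast_config(), "mirna_fixed", scorer = spy)
  expect_equal(r$auc_mean, 1.0)
  expect_equal(r$n_test_samples, 1L)
  # sm-fixed: candidates = {(s1,m2)} -> 0.9 vs 0.2
  r2 <- local_loocv(d, diag(2), diag(2), fast_config(), "sm_fixed", scorer = spy)
  expect_equal(r2$auc_mean, 1.0)
})

test_that("a uniform-random scorer calibrates to AUC 0.5 in every CV mode", {
  syn <- small_synth()
  d <- syn$data
  cfg <- fast_config()
  rnd <- scorer_random()
  modes <- list(
    global = function() global_loocv(d, syn$SSM, syn$SMR, cfg, scorer = rnd)$auc_mean,
    mirna = function() local_loocv(d, syn$SSM, syn$SMR, cfg, "mirna_fixed",
                                   scorer = rnd)$auc_mean,
    sm = function() local_loocv(d, syn$SSM, syn$SMR, cfg, "sm_fixed",
                                scorer = rnd)$auc_mean,
    kfold = function() kfold_cv(d, syn$SSM, syn$SMR, cfg, k = 5,
                                scorer = rnd)$auc_mean)
  set.seed(11)
  for (m in names(modes)) {
    aucs <- replicate(200, modes[[m]]())
    expect_lt(abs(mean(aucs) - 0.5), 0.02, label = paste("mode", m))
  }
})

test_that("k-fold partitions are balanced, exhaustive and seed-reproducible", {
  mk <- function(n_assoc) {
    A <- matrix(0, 4, 6)
    A[sample(length(A), n_assoc)] <- 1
    association_data(A, paste0("s", 1:4), paste0("m", 1:6))
  }
  set.seed(3)
  d10 <- mk(10); d11 <- mk(11)
  rnd <- scorer_random()
  r10 <- kfold_cv(d10, diag(4), diag(6), fast_config(), k = 5, seed = 9, scorer = rnd)
  expect_true(all(table(r10$folds[[1]]) == 2))
  r11 <- kfold_cv(d11, diag(4), diag(6), fast_config(), k = 5, seed = 9, scorer = rnd)
  expect_lte(diff(range(table(r11$folds[[1]]))), 1)

  # every pair lands in a test fold exactly once per repeat
  r3 <- kfold_cv(d11, diag(4), diag(6), fast_config(), k = 5, repeats = 3,
                 seed = 4, scorer = rnd)
  for (f in r3$folds) expect_equal(sort(unique(f)), 1:5)
  expect_length(r3$per_repeat_aucs, 15)

  a <- kfold_cv(d10, diag(4), diag(6), fast_config(), k = 5, seed = 21, scorer = rnd)
  b <- kfold_cv(d10, diag(4), diag(6), fast_config(), k = 5, seed = 21, scorer = rnd)
  expect_identical(a$folds, b$folds)
  expect_error(kfold_cv(mk(3), diag(4), diag(6), fast_config(), k = 5,
                        scorer = rnd), "fewer known associations")
})

test_that("case studies remove the right associations and rank candidates", {
  syn <- small_synth()
  d <- syn$data
  sm <- d$sm_ids[which.max(rowSums(d$A))]
  n_known <- sum(d$A[match(sm, d$sm_ids), ])
  removed <- NULL
  spy <- function(train, SSM, SMR, cfg) {
    removed <<- sum(d$A) - sum(train$A)
    matrix(seq_len(length(train$A)) / length(train$A),
           nrow(train$A), ncol(train$A))
  }
  r1 <- case_study(d, syn$SSM, syn$SMR, fast_config(), sm_id = sm,
                   mode = 1, top_n = 5, scorer = spy)
  expect_equal(removed, 0)
  expect_equal(nrow(r1), 5)
  # mode 1 excludes the SM's known miRNAs from the candidate list
  known <- d$mirna_ids[d$A[match(sm, d$sm_ids), ] == 1]
  full1 <- case_study(d, syn$SSM, syn$SMR, fast_config(), sm_id = sm,
                      mode = 1, top_n = Inf, scorer = spy)
  expect_length(intersect(full1$mirna_id, known), 0)
  expect_equal(nrow(full1), length(d$mirna_ids) - n_known)

  r2 <- case_study(d, syn$SSM, syn$SMR, fast_config(), sm_id = sm,
                   mode = 2, top_n = Inf, scorer = spy)
  expect_equal(removed, n_known)
  expect_equal(nrow(r2), length(d$mirna_ids))
  expect_true(all(diff(r2$score) <= 0))
  expect_error(case_study(d, syn$SSM, syn$SMR, fast_config(), sm_id = "nope"),
               "unknown SM")
})

test_that("random controls sample unknown pairs reproducibly with global ranks", {
  syn <- small_synth()
  d <- syn$data
  rnd <- scorer_random()
  n_unknown <- sum(d$A == 0)
  set.seed(8)
  all_pairs <- random_control(d, syn$SSM, syn$SMR, fast_config(),
                              n_pairs = n_unknown, seed = 2, scorer = rnd)
  expect_equal(nrow(all_pairs), n_unknown)
  expect_equal(anyDuplicated(paste(all_pairs$sm_id, all_pairs$mirna_id)), 0L)
  expect_equal(sort(all_pairs$rank), seq_len(n_unknown))

  a <- random_control(d, syn$SSM, syn$SMR, fast_config(), n_pairs = 10,
                      seed = 3, scorer = scorer_oracle(d))
  b <- random_control(d, syn$SSM, syn$SMR, fast_config(), n_pairs = 10,
                      seed = 3, scorer = scorer_oracle(d))
  expect_identical(a[c("sm_id", "mirna_id")], b[c("sm_id", "mirna_id")])
  expect_error(random_control(d, syn$SSM, syn$SMR, fast_config(),
                              n_pairs = n_unknown + 1, scorer = rnd),
               "exceeds")

  # under a random scorer the sampled mean rank sits near the middle
  set.seed(9)
  mean_ranks <- replicate(200, {
    rc <- random_control(d, syn$SSM, syn$SMR, fast_config(), n_pairs = 20,
                         seed = sample.int(1e6, 1), scorer = rnd)
    mean(rc$rank)
  })
  expect_lt(abs(mean(mean_ranks) - (n_unknown + 1) / 2), 0.05 * n_unknown)
})
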