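test_that("fold plans partition the known associations as specified", {
  Y <- recovery_fixture()
  n_pos <- sum(Y)
  plan <- make_folds(Y, "kfold", seed = 3, k_folds = 10)
  expect_length(plan$folds, 10)
  all_pairs <- do.call(rbind, plan$folds)
  expect_equal(nrow(all_pairs), n_pos)                       # covers all
  expect_false(anyDuplicated(all_pairs) > 0)                 # disjoint
  expect_true(all(Y[all_pairs] == 1))
  sizes <- vapply(plan$folds, nrow, integer(1))
  expect_lte(max(sizes) - min(sizes), 1)                     # balanced

  # 10 positives into 10 folds: singletons covering every pair
  Ys <- association_matrix(diag(10), paste0("m", 1:10), paste0("d", 1:10))
  ps <- make_folds(Ys, "kfold", seed = 1, k_folds = 10)
  expect_true(all(vapply(ps$folds, nrow, integer(1)) == 1))

  expect_length(make_folds(Y, "global_loocv")$folds, n_pos)

  expect_error(make_folds(Ys, "kfold", k_folds = 11), "11 folds")
})

test_that("local LOOCV enumerates one fold per known pair, grouped by disease", {
  Y <- association_matrix(rbind(c(1, 0), c(1, 1)), c("m1", "m2"), c("d1", "d2"))
  plan <- make_folds(Y, "local_loocv")
  expect_length(plan$folds, 3)
  expect_equal(plan$disease, c(1L, 1L, 2L))
  expect_equal(do.call(rbind, plan$folds),
               rbind(c(1L, 1L), c(2L, 1L), c(2L, 2L)))
})

test_that("fold plans are reproducible for a seed and differ across seeds", {
  Y <- recovery_fixture()
  p1 <- make_folds(Y, "kfold", seed = 5, k_folds = 5)
  p2 <- make_folds(Y, "kfold", seed = 5, k_folds = 5)
  expect_identical(p1$folds, p2$folds)
  p3 <- make_folds(Y, "kfold", seed = 6, k_folds = 5)
  expect_false(identical(p1$folds, p3$folds))
})

test_that("AUC equals Mann-Whitney pair counting on random instances", {
  withr::local_seed(41)
  for (rep in 1:1000) {
    n <- sample(4:12, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))   # both classes present
    scores <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    expect_equal(auc_score(scores, labels), brute_force_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC hits its anchor values", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)  # all tied
  expect_equal(auc_score(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(auc_score(c(1, 2), c(1, 1)), "negative")
})

test_that("AUC matches the trapezoidal ROC integral on tie-free inputs", {
  skip_if_not_installed("pROC")
  withr::local_seed(42)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    scores <- sample(seq_len(100), n)  # distinct => tie-free
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    got <- auc_score(scores, labels)
    want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("AUPR equals the rank-accumulation oracle and its anchors", {
  withr::local_seed(43)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    labels <- c(1, rbinom(n - 1, 1, 0.4))
    scores <- round(runif(n), 2)
    expect_equal(aupr_score(scores, labels), brute_force_aupr(scores, labels),
                 tolerance = 1e-12)
  }
  expect_equal(aupr_score(c(0.9, 0.1, 0.2), c(1, 0, 0)), 1)  # positive first
  expect_equal(aupr_score(c(0.2, 0.9), c(0, 1)), 1)
  expect_equal(aupr_score(c(0.9, 0.2), c(0, 1)), 0.5)        # two-point curve
  expect_error(aupr_score(c(1, 2), c(0, 0)), "positive")
})

test_that("oracle and constant scorers bound cross-validated AUC", {
  Y <- recovery_fixture()
  for (scheme in c("kfold", "local_loocv")) {
    plan <- make_folds(Y, scheme, seed = 2, k_folds = 5)
    oracle <- evaluate_cv(Y, plan, scorer = function(Ytr) Y)
    expect_equal(oracle$auc, 1)
    flat <- evaluate_cv(Y, plan, scorer = function(Ytr) matrix(0, nrow(Y), ncol(Y)))
    expect_equal(flat$auc, 0.5)
  }
})

test_that("per-fold training uses only the masked association matrix", {
  Y <- recovery_fixture()[1:25, 1:15]
  for (scheme in c("kfold", "global_loocv", "local_loocv")) {
    plan <- make_folds(Y, scheme, seed = 9, k_folds = 5)
    probe <- if (scheme == "kfold") seq_along(plan$folds) else c(1L, 2L)
    rep <- evaluate_cv(Y, plan, k = 5, keep_fold_details = TRUE)
    for (f in probe) {
      Ytr <- mask_associations(Y, plan$folds[[f]])
      leak_free <- predict_associations(
        Ytr, list(gip_kernel(Ytr, "miRNA")), list(gip_kernel(Ytr, "disease")),
        k = 5
      )
      # training kernel identical to one rebuilt from the masked matrix alone
      expect_equal(rep$details[[f]]$kernel_m, leak_free$kernel_m)
      expect_equal(rep$details[[f]]$weights_m$mu, leak_free$weights_m$mu)
      # and sensitive to the sentinel: rebuilding from the UNMASKED matrix
      # (test entries restored to 1) gives a different kernel
      leaky <- gip_kernel(Y, "miRNA")
      sp <- sparsify_kernel(combine_kernels(
        list(leaky), fkl_fit(list(leaky), fusion_target(Y, "miRNA"))), 5)$kernel
      expect_false(isTRUE(all.equal(rep$details[[f]]$kernel_m, sp)))
    }
  }
})

test_that("evaluation reports serialize and rankings behave", {
  Y <- recovery_fixture()
  plan <- make_folds(Y, "kfold", seed = 2, k_folds = 5)
  report <- evaluate_cv(Y, plan, scorer = function(Ytr) Y)
  f <- withr::local_tempfile(fileext = ".tsv")
  pf <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(report, f, pf)
  lines <- readLines(f)
  expect_match(lines[1], "^scheme\tkfold$")
  expect_equal(nrow(utils::read.delim(pf)), 5)
})

test_that("candidate ranking excludes known associations and breaks ties by catalog", {
  Y <- association_matrix(rbind(c(1, 0), c(0, 0), c(0, 1), c(0, 0)),
                          paste0("m", 1:4), c("d1", "d2"))
  S <- matrix(0.5, 4, 2, dimnames = dimnames(Y))  # all tied
  top <- rank_candidates(S, Y, "d1", top_n = 2)
  expect_equal(top$miRNA, c("m2", "m3"))          # catalog order, m1 excluded
  S2 <- S; S2[4, 1] <- 0.9
  expect_equal(rank_candidates(S2, Y, "d1", top_n = 1)$miRNA, "m4")
  expect_false("m1" %in% rank_candidates(S2, Y, "d1", top_n = 4)$miRNA)
  expect_error(rank_candidates(S, Y, "d9"), "unknown disease")
})

test_that("local LOOCV averages per-disease AUCs unweighted", {
  Y <- association_matrix(rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0)),
                          paste0("m", 1:4), c("d1", "d2"))
  plan <- make_folds(Y, "local_loocv")
  # scorer with perfect ranking for d1 and inverted ranking for d2
  S <- cbind(c(1, 0.9, 0.1, 0.2), c(0, 0.3, 0.1, 0.9))
  dimnames(S) <- dimnames(Y)
  rep <- evaluate_cv(Y, plan, scorer = function(Ytr) S)
  expect_equal(nrow(rep$per_disease), 2)
  expect_equal(rep$per_disease$auc[1], 1)    # held-out m1, m2 beat m3, m4
  expect_equal(rep$auc, mean(rep$per_disease$auc))
})
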