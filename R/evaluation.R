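#' Build a cross-validation fold plan over known associations
#'
#' Three schemes over the 1-entries of `Y`:
#' \describe{
#'   \item{`"kfold"`}{the known associations are randomly divided into
#'     `k_folds` disjoint groups ("uncrossed"); each group is a test set in
#'     turn.}
#'   \item{`"global_loocv"`}{one fold per known association.}
#'   \item{`"local_loocv"`}{per disease: for every disease with at least one
#'     known miRNA, each known (miRNA, disease) pair is a fold, tagged with
#'     its disease so per-disease aggregation is possible.}
#' }
#' Fold membership is deterministic given `seed`.
#'
#' @param Y association matrix.
#' @param scheme `"kfold"`, `"global_loocv"` or `"local_loocv"`.
#' @param seed RNG seed (only `"kfold"` draws random numbers, but the seed
#'   is recorded for all schemes).
#' @param k_folds group count for `"kfold"`; default 10.
#' @return object of class `"fold_plan"`: list with `scheme`, `folds` (list
#'   of two-column index matrices), `disease` (per-fold disease index for
#'   `"local_loocv"`, else `NULL`), `seed`, `k_folds`.
#' @export
make_folds <- function(Y, scheme = c("kfold", "global_loocv", "local_loocv"),
                       seed = 1L, k_folds = 10L) {
  scheme <- match.arg(scheme)
  pos <- which(Y == 1, arr.ind = TRUE)
  dimnames(pos) <- NULL
  n_pos <- nrow(pos)
  if (n_pos == 0L) stop_mda("association matrix has no known associations")
  disease <- NULL
  if (scheme == "kfold") {
    if (n_pos < k_folds) {
      stop_mda(sprintf("only %d known associations for %d folds", n_pos, k_folds))
    }
    grp <- with_seed(seed, sample(rep_len(seq_len(k_folds), n_pos)))
    folds <- lapply(seq_len(k_folds), function(g) pos[grp == g, , drop = FALSE])
  } else if (scheme == "global_loocv") {
    folds <- lapply(seq_len(n_pos), function(i) pos[i, , drop = FALSE])
  } else {
    ord <- order(pos[, 2L], pos[, 1L])
    pos <- pos[ord, , drop = FALSE]
    folds <- lapply(seq_len(n_pos), function(i) pos[i, , drop = FALSE])
    disease <- pos[, 2L]
  }
  structure(list(scheme = scheme, folds = folds, disease = disease,
                 seed = seed, k_folds = if (scheme == "kfold") k_folds else NULL),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold plan: %s, %d folds, seed %s\n",
              x$scheme, length(x$folds), format(x$seed)))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = (concordant pairs + 0.5 * tied pairs) / (P * N)` over all
#' positive-negative score pairs, computed from midranks. Equals the
#' trapezoidal ROC integral; ties contribute one half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive), same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop_mda("scores and labels differ in length")
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0L || N == 0L) {
    stop_mda("AUC needs at least one positive and one negative")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve (average precision)
#'
#' Sorts by descending score (ties broken by original position, positives
#' not favored) and accumulates `precision(k) * delta_recall(k)` — the
#' average-precision estimator, which avoids the optimism of linear PR
#' interpolation.
#'
#' @inheritParams auc_score
#' @return AUPR in `(0, 1]`.
#' @export
aupr_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop_mda("scores and labels differ in length")
  P <- sum(labels == 1)
  if (P == 0L) stop_mda("AUPR needs at least one positive")
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1]) / P
}

# Candidate row indices for one disease: miRNAs with no known association
# in the reference matrix.
unassociated_rows <- function(Y, j) which(Y[, j] == 0)

#' Cross-validated evaluation of the prediction pipeline
#'
#' For every fold: the test pairs are reset to 0 in `Y`, every
#' association-dependent quantity (GIP kernels, fusion targets, fusion
#' weights) is recomputed from the masked matrix only, the pipeline is run,
#' and the held-out pairs are scored against the pairs that are unverified
#' in the full matrix. Kernels that do not depend on `Y` (sequence,
#' semantic, functional) are passed in fixed and reused across folds.
#'
#' Scoring: under `"kfold"` each fold's test pairs are ranked against all
#' unverified pairs and per-fold AUC/AUPR are averaged; under
#' `"global_loocv"` each held-out association is ranked against all
#' unverified pairs and the per-fold concordances are averaged; under
#' `"local_loocv"` each held-out miRNA is ranked against the miRNAs
#' unassociated with its disease, per-fold AUCs are averaged within each
#' disease and then unweighted across diseases.
#'
#' @param Y association matrix.
#' @param plan fold plan from [make_folds()] built from this `Y`.
#' @param kernels_m,kernels_d fixed (association-independent) kernels per
#'   side; may be empty lists when `use_gip = TRUE`.
#' @param use_gip append a GIP kernel per side, recomputed from the masked
#'   matrix inside every fold (default `TRUE`).
#' @param gamma,gip_mode,gip_normalize GIP parameters (see [gip_kernel()]).
#' @param scorer optional function `(Y_masked) -> m x n score matrix`
#'   replacing the pipeline entirely (used for oracle/baseline checks);
#'   when supplied all pipeline arguments are ignored.
#' @param keep_fold_details also return per-fold fusion weights and
#'   training kernels (memory-heavy; intended for audits on small data).
#' @inheritParams predict_associations
#' @return object of class `"eval_report"`: list with `scheme`, `auc`,
#'   `aupr`, `per_fold` (data frame: fold, auc, aupr), `per_disease` (local
#'   scheme only), and `details` when requested.
#' @export
evaluate_cv <- function(Y, plan, kernels_m = list(), kernels_d = list(),
                        use_gip = TRUE, gamma = -1, gip_mode = "magnitude",
                        gip_normalize = "none", lam = 200, k = 20,
                        sparsify = TRUE, beta_m = 2^-5, beta_d = 2^-5,
                        jitter = 1e-8, fusion = "fkl", scorer = NULL,
                        keep_fold_details = FALSE) {
  if (!inherits(plan, "fold_plan")) stop_mda("`plan` must come from make_folds()")
  if (!use_gip && (!length(kernels_m) || !length(kernels_d)) && is.null(scorer)) {
    stop_mda("no kernels: supply fixed kernels or set use_gip = TRUE")
  }
  neg_all <- which(Y == 0)  # unverified pairs, the negative pool
  n_folds <- length(plan$folds)
  fold_auc <- fold_aupr <- rep(NA_real_, n_folds)
  details <- if (keep_fold_details) vector("list", n_folds) else NULL

  for (f in seq_len(n_folds)) {
    test <- plan$folds[[f]]
    if (nrow(test) == 0L) next
    Ytr <- mask_associations(Y, test)
    if (is.null(scorer)) {
      km <- kernels_m
      kd <- kernels_d
      if (use_gip) {
        km <- c(km, list(gip_kernel(Ytr, "miRNA", gamma = gamma, mode = gip_mode,
                                    normalize = gip_normalize)))
        kd <- c(kd, list(gip_kernel(Ytr, "disease", gamma = gamma, mode = gip_mode,
                                    normalize = gip_normalize)))
      }
      fit <- predict_associations(Ytr, km, kd, lam = lam, k = k,
                                  sparsify = sparsify, beta_m = beta_m,
                                  beta_d = beta_d, jitter = jitter,
                                  fusion = fusion)
      S <- fit$F_star
      if (keep_fold_details) {
        details[[f]] <- list(weights_m = fit$weights_m, weights_d = fit$weights_d,
                             kernel_m = fit$kernel_m, kernel_d = fit$kernel_d)
      }
    } else {
      S <- scorer(Ytr)
    }
    if (plan$scheme == "local_loocv") {
      j <- test[1L, 2L]
      cand <- unassociated_rows(Y, j)
      sc <- c(S[test[1L, 1L], j], S[cand, j])
      lb <- c(1, numeric(length(cand)))
    } else {
      sc <- c(S[test], S[neg_all])
      lb <- c(rep(1, nrow(test)), numeric(length(neg_all)))
    }
    fold_auc[f] <- auc_score(sc, lb)
    fold_aupr[f] <- aupr_score(sc, lb)
  }

  per_fold <- data.frame(fold = seq_len(n_folds), auc = fold_auc, aupr = fold_aupr)
  per_disease <- NULL
  if (plan$scheme == "local_loocv") {
    dz <- factor(plan$disease, levels = sort(unique(plan$disease)))
    per_disease <- data.frame(
      disease = colnames(Y)[sort(unique(plan$disease))],
      auc = as.numeric(tapply(fold_auc, dz, mean)),
      aupr = as.numeric(tapply(fold_aupr, dz, mean))
    )
    auc <- mean(per_disease$auc)
    aupr <- mean(per_disease$aupr)
  } else {
    auc <- mean(fold_auc, na.rm = TRUE)
    aupr <- mean(fold_aupr, na.rm = TRUE)
  }
  structure(list(scheme = plan$scheme, auc = auc, aupr = aupr,
                 per_fold = per_fold, per_disease = per_disease,
                 details = details),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation (%s): AUC = %.4f, AUPR = %.4f over %d folds\n",
              x$scheme, x$auc, x$aupr, nrow(x$per_fold)))
  invisible(x)
}

#' Write an evaluation report to text files
#'
#' Writes a flat key-value summary to `path` and, optionally, the per-fold
#' table next to it.
#'
#' @param report an [evaluate_cv()] result.
#' @param path summary output path.
#' @param per_fold_path optional TSV path for the per-fold metrics.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, per_fold_path = NULL) {
  lines <- c(paste0("scheme\t", report$scheme),
             paste0("auc\t", format_g12(report$auc)),
             paste0("aupr\t", format_g12(report$aupr)),
             paste0("n_folds\t", nrow(report$per_fold)))
  writeLines(lines, path)
  if (!is.null(per_fold_path)) {
    utils::write.table(report$per_fold, per_fold_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Rank candidate miRNAs for one disease
#'
#' Orders all miRNAs without a known training association to the disease by
#' descending combined score; ties break by catalog order. Known-associated
#' miRNAs never appear.
#'
#' @param F_star m x n combined score matrix.
#' @param Y_train training association matrix (same shape).
#' @param disease disease id (column name) or index.
#' @param top_n number of candidates to return; default 50.
#' @return data frame with columns `rank`, `miRNA`, `score`.
#' @export
rank_candidates <- function(F_star, Y_train, disease, top_n = 50L) {
  if (is.character(disease)) {
    if (!disease %in% colnames(Y_train)) {
      stop_mda(sprintf("unknown disease '%s'", disease))
    }
    j <- match(disease, colnames(Y_train))
  } else {
    j <- as.integer(disease)
    if (is.na(j) || j < 1L || j > ncol(Y_train)) {
      stop_mda(sprintf("disease index %s out of range", format(disease)))
    }
  }
  cand <- unassociated_rows(Y_train, j)
  ord <- cand[order(-F_star[cand, j], cand)]
  top <- utils::head(ord, top_n)
  data.frame(rank = seq_along(top),
             miRNA = rownames(Y_train)[top],
             score = F_star[cbind(top, j)],
             stringsAsFactors = FALSE)
}
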