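#' Normalized graph Laplacian of a similarity kernel
#'
#' `L = D^{-1/2} (D - K) D^{-1/2}` with `D` the diagonal matrix of row sums
#' of `K`. Rows whose sum is zero (possible after aggressive sparsification)
#' receive `D[i, i] = jitter` before the inverse square root so the
#' construction stays finite. Eigenvalues of `L` lie in `[0, 2]` up to
#' floating-point error.
#'
#' @param K symmetric nonnegative similarity kernel.
#' @param jitter replacement diagonal for zero-sum rows; default `1e-8`.
#' @return symmetric Laplacian matrix with the kernel's dimnames.
#' @export
normalized_laplacian <- function(K, jitter = 1e-8) {
  if (any(K < 0)) stop_mda("normalized_laplacian requires a nonnegative kernel")
  check_scalar_number(jitter, "jitter")
  if (jitter <= 0) stop_mda("`jitter` must be positive")
  d <- rowSums(K)
  d[d == 0] <- jitter
  inv_sqrt <- 1 / sqrt(d)
  L <- -unclass(K) * outer(unname(inv_sqrt), unname(inv_sqrt))
  attr(L, "kernel_name") <- NULL
  diag(L) <- diag(L) + 1  # D^{-1/2} D D^{-1/2} contributes the identity
  L <- (L + t(L)) / 2
  dimnames(L) <- dimnames(K)
  L
}

# Solve (K + beta L K + ridge I) X = B by LU factorization, escalating the
# ridge x10 from `jitter` up to 1e-4 when the unridged system is singular or
# too ill-conditioned to meet the residual contract.
solve_with_jitter <- function(A, B, jitter, rtol = 1e-6) {
  bnorm <- sqrt(sum(B^2))
  ridges <- c(0, jitter * 10^(0:ceiling(log10(1e-4 / jitter))))
  ridges <- ridges[c(TRUE, ridges[-1L] <= 1e-4)]
  for (ridge in ridges) {
    Aj <- A
    if (ridge > 0) diag(Aj) <- diag(Aj) + ridge
    X <- tryCatch(solve(Aj, B), error = function(e) NULL)
    if (is.null(X)) next
    resid <- sqrt(sum((A %*% X - B)^2))
    if (bnorm == 0 || resid <= max(rtol * bnorm, ridge * sqrt(sum(X^2)) + 1e-12)) {
      return(list(X = X, ridge = ridge))
    }
  }
  stop_mda("linear solve failed even after ridge escalation to 1e-4")
}

#' Laplacian regularized least squares from one subspace
#'
#' Closed-form LapRLS scores for one entity side: fits coefficients `alpha`
#' minimizing the least-squares error to `Y_side` with a graph-Laplacian
#' smoothness penalty `beta * tr(alpha' K L K alpha)`, whose exact minimizer
#' gives
#' `F = K (K + beta L K)^{-1} Y_side`.
#' The system is solved by factorization (never an explicit inverse); when
#' it is singular a Tikhonov ridge starting at `jitter` and escalating
#' tenfold up to `1e-4` is applied, and the solve must meet the residual
#' contract `||(K + beta L K) alpha - Y_side|| <= 1e-6 ||Y_side||` (up to
#' the applied ridge).
#'
#' @param K symmetric similarity kernel for the side (m x m or n x n).
#' @param Y_side association matrix viewed from the side: `Y` for miRNAs
#'   (m x n), `t(Y)` for diseases (n x m).
#' @param beta regularization coefficient, `>= 0`; default `2^-5`.
#' @param jitter starting fallback ridge; default `1e-8`.
#' @return list with `F` (the score matrix, same shape as `Y_side`),
#'   `alpha` (the coefficient matrix) and `ridge` (the ridge actually used,
#'   0 when none was needed).
#' @export
laprls_solve <- function(K, Y_side, beta = 2^-5, jitter = 1e-8) {
  check_scalar_number(beta, "beta", lower = 0)
  if (nrow(K) != ncol(K)) stop_mda("kernel must be square")
  if (nrow(Y_side) != nrow(K)) {
    stop_mda(sprintf("kernel is %dx%d but Y_side has %d rows",
                     nrow(K), ncol(K), nrow(Y_side)))
  }
  L <- normalized_laplacian(K, jitter = jitter)
  A <- K + beta * (L %*% K)
  sol <- solve_with_jitter(A, Y_side, jitter = jitter)
  if (sol$ridge > 0) {
    msg_info("laprls_solve applied ridge %g to a near-singular system", sol$ridge)
  }
  FF <- K %*% sol$X
  dimnames(FF) <- dimnames(Y_side)
  list(F = FF, alpha = sol$X, ridge = sol$ridge)
}

#' Combine subspace predictions
#'
#' Averages the miRNA-view and disease-view score matrices into the final
#' prediction: `F_star = (F_m + t(F_d)) / 2`.
#'
#' @param F_m m x n score matrix from the miRNA subspace.
#' @param F_d n x m score matrix from the disease subspace.
#' @return list of class `"prediction_scores"` with `F_m`, `F_d`, `F_star`.
#' @export
combine_predictions <- function(F_m, F_d) {
  if (nrow(F_m) != ncol(F_d) || ncol(F_m) != nrow(F_d)) {
    stop_mda(sprintf("F_m is %dx%d but F_d is %dx%d (expected the transpose shape)",
                     nrow(F_m), ncol(F_m), nrow(F_d), ncol(F_d)))
  }
  structure(list(F_m = F_m, F_d = F_d, F_star = (F_m + t(F_d)) / 2),
            class = "prediction_scores")
}

#' @export
print.prediction_scores <- function(x, ...) {
  cat(sprintf("prediction scores: %d miRNAs x %d diseases (range [%.4g, %.4g])\n",
              nrow(x$F_star), ncol(x$F_star), min(x$F_star), max(x$F_star)))
  invisible(x)
}

#' Full multi-kernel prediction pipeline
#'
#' Runs the complete flow for both entity sides: build the
#' association-similarity fusion target, fit fusion weights over the input
#' kernels ([fkl_fit()]), combine them into one kernel per side, optionally
#' denoise by top-k sparsification ([sparsify_kernel()]), solve LapRLS from
#' each subspace and average the two views. Deterministic given its inputs.
#'
#' @param Y association matrix (the training matrix; mask test pairs
#'   beforehand for evaluation).
#' @param kernels_m list of miRNA-side similarity kernels (m x m).
#' @param kernels_d list of disease-side similarity kernels (n x n).
#' @param lam fusion regularization weight (both sides); default 200.
#' @param k sparsifier neighbor count; default 20. Ignored when
#'   `sparsify = FALSE`. Capped nowhere: must satisfy `0 < k < side dim`.
#' @param sparsify logical; apply the top-k denoiser (default `TRUE`).
#' @param beta_m,beta_d LapRLS regularization per side; default `2^-5`.
#' @param jitter fallback ridge for near-singular solves.
#' @param fusion `"fkl"` (learned weights) or `"avg"` (uniform average
#'   baseline).
#' @return a `"prediction_scores"` list with `F_m`, `F_d`, `F_star`, plus
#'   `weights_m`, `weights_d` (fusion weights; `NULL` under `"avg"`) and
#'   `kernel_m`, `kernel_d` (the per-side kernels actually fed to LapRLS).
#' @export
predict_associations <- function(Y, kernels_m, kernels_d, lam = 200, k = 20,
                                 sparsify = TRUE, beta_m = 2^-5, beta_d = 2^-5,
                                 jitter = 1e-8, fusion = c("fkl", "avg")) {
  fusion <- match.arg(fusion)
  if (!length(kernels_m) || !length(kernels_d)) {
    stop_mda("at least one kernel per side is required")
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop_mda(sprintf("[%s] %s", what, conditionMessage(e)))
    })
  }
  fuse_side <- function(kernels, side) {
    if (fusion == "avg") {
      list(kernel = average_kernel(kernels), weights = NULL)
    } else {
      w <- fkl_fit(kernels, fusion_target(Y, side), lam = lam)
      list(kernel = combine_kernels(kernels, w), weights = w)
    }
  }
  fm <- stage("fusion/miRNA", fuse_side(kernels_m, "miRNA"))
  fd <- stage("fusion/disease", fuse_side(kernels_d, "disease"))
  Km <- fm$kernel
  Kd <- fd$kernel
  if (isTRUE(sparsify)) {
    Km <- stage("sparsify/miRNA", sparsify_kernel(Km, k)$kernel)
    Kd <- stage("sparsify/disease", sparsify_kernel(Kd, k)$kernel)
  }
  sol_m <- stage("laprls/miRNA", laprls_solve(Km, Y, beta = beta_m, jitter = jitter))
  sol_d <- stage("laprls/disease", laprls_solve(Kd, t(Y), beta = beta_d, jitter = jitter))
  out <- combine_predictions(sol_m$F, sol_d$F)
  out$weights_m <- fm$weights
  out$weights_d <- fd$weights
  out$kernel_m <- Km
  out$kernel_d <- Kd
  out
}
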