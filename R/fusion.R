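#' Association-similarity target for kernel fusion
#'
#' The Gram matrix of the association profiles on one side: `Y %*% t(Y)`
#' (m x m) for miRNAs, `t(Y) %*% Y` (n x n) for diseases. Kernel weights are
#' fitted so the fused kernel is close to this target in Frobenius norm.
#'
#' @param Y association matrix.
#' @param side `"miRNA"` or `"disease"`.
#' @return square symmetric positive semi-definite matrix with catalog
#'   dimnames.
#' @export
fusion_target <- function(Y, side = c("miRNA", "disease")) {
  side <- match.arg(side)
  if (side == "miRNA") tcrossprod(Y) else crossprod(Y)
}

# Solve min over the simplex {mu >= 0, sum(mu) = 1} of
#   mu' Q mu - 2 c' mu
# exactly, by enumerating support subsets: for each subset S the
# equality-constrained KKT system
#   [2 Q_SS  1] [mu_S]   [2 c_S]
#   [1'      0] [nu  ] = [1    ]
# is solved; among subsets whose solution is nonnegative the smallest
# objective wins. For a convex objective the optimum's support is one of the
# subsets, so the minimum over feasible candidates is the global optimum.
# Exponential in the number of kernels, which is small (3 in the standard
# pipeline); refuse absurd sizes.
solve_simplex_qp <- function(Q, c_vec, tol = 1e-9) {
  p <- length(c_vec)
  if (p > 12L) stop_mda("simplex QP support enumeration is limited to 12 kernels")
  best <- NULL
  best_obj <- Inf
  q_scale <- max(1, max(abs(Q)))  # equilibrate the KKT system at large lam
  for (mask in seq_len(2^p - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0L)
    s <- length(S)
    A <- rbind(cbind(2 * Q[S, S, drop = FALSE] / q_scale, rep(1, s)),
               c(rep(1, s), 0))
    b <- c(2 * c_vec[S] / q_scale, 1)
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol)) next
    mu_S <- sol[seq_len(s)]
    if (any(mu_S < -tol)) next
    mu <- numeric(p)
    mu[S] <- pmax(mu_S, 0)
    mu <- mu / sum(mu)
    obj <- drop(mu %*% Q %*% mu - 2 * sum(c_vec * mu))
    if (obj < best_obj - 1e-15) {
      best_obj <- obj
      best <- mu
    }
  }
  if (is.null(best)) stop_mda("simplex QP solve failed on every support subset")
  list(mu = best, objective = best_obj)
}

#' Fit kernel fusion weights by fast kernel learning
#'
#' Finds simplex-constrained weights `mu` (nonnegative, summing to 1)
#' minimizing
#' `|| sum_j mu_j K_j - T ||_F^2 + lam * ||mu||^2`,
#' where `T` is the association-similarity target of [fusion_target()]. The
#' problem reduces to a tiny quadratic program with
#' `Q[j, k] = <K_j, K_k>_F + lam * 1[j == k]` and `c[j] = <K_j, T>_F`,
#' solved exactly by support enumeration (all KKT systems over nonnegative
#' supports). The ridge `lam` discourages concentrating all weight on one
#' kernel; at very large `lam` the weights approach uniform.
#'
#' @param kernels list of similarity kernels sharing the target's catalog
#'   and shape; at least two for a meaningful fusion (one is accepted and
#'   returns weight 1).
#' @param target square matrix from [fusion_target()].
#' @param lam regularization weight, `>= 0`; 200 by default.
#' @return object of class `"fusion_weights"`: list with `mu` (named by
#'   kernel provenance tags), `lam`, `objective` (the full objective
#'   including the constant `||T||_F^2` term).
#' @export
fkl_fit <- function(kernels, target, lam = 200) {
  check_scalar_number(lam, "lam", lower = 0)
  if (!length(kernels)) stop_mda("no kernels to fuse")
  dims <- vapply(kernels, nrow, integer(1))
  if (any(dims != nrow(target)) ||
      any(vapply(kernels, ncol, integer(1)) != ncol(target))) {
    stop_mda(sprintf("kernel shapes (%s) do not match the %dx%d target",
                     paste(dims, collapse = ", "), nrow(target), ncol(target)))
  }
  p <- length(kernels)
  G <- matrix(0, p, p)
  for (j in seq_len(p)) {
    for (k in j:p) {
      G[j, k] <- G[k, j] <- sum(kernels[[j]] * kernels[[k]])
    }
  }
  c_vec <- vapply(kernels, function(K) sum(K * target), numeric(1))
  Q <- G + diag(lam, p)
  sol <- solve_simplex_qp(Q, c_vec)
  nms <- vapply(kernels, kernel_name, character(1))
  if (anyDuplicated(nms)) nms <- paste0(nms, "_", seq_len(p))
  structure(list(mu = stats::setNames(sol$mu, nms),
                 lam = lam,
                 objective = sol$objective + sum(target^2)),
            class = "fusion_weights")
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat(sprintf("fusion weights (lambda = %g, objective = %.6g):\n",
              x$lam, x$objective))
  for (nm in names(x$mu)) cat(sprintf("  %-12s %.6g\n", nm, x$mu[[nm]]))
  invisible(x)
}

#' Combine kernels with fitted fusion weights
#'
#' @param kernels list of similarity kernels over one catalog.
#' @param weights a [fkl_fit()] result, or a bare numeric weight vector.
#' @return the weighted-sum similarity kernel, named `"fused"`.
#' @export
combine_kernels <- function(kernels, weights) {
  mu <- if (inherits(weights, "fusion_weights")) weights$mu else as.numeric(weights)
  if (length(mu) != length(kernels)) {
    stop_mda(sprintf("%d weights for %d kernels", length(mu), length(kernels)))
  }
  dims <- vapply(kernels, nrow, integer(1))
  if (length(unique(dims)) != 1L) stop_mda("kernels differ in shape")
  K <- Reduce(`+`, Map(function(k, w) w * k, kernels, mu))
  similarity_kernel(K, rownames(kernels[[1L]]), name = "fused")
}

#' Unweighted average of similarity kernels
#'
#' The elementwise mean of the input kernels — the simple integration
#' baseline against which learned fusion weights are compared.
#'
#' @param kernels non-empty list of similarity kernels over one catalog.
#' @return the average similarity kernel, named `"fused"`.
#' @export
average_kernel <- function(kernels) {
  if (!length(kernels)) stop_mda("no kernels to average")
  combine_kernels(kernels, rep(1 / length(kernels), length(kernels)))
}

#' Write fitted fusion weights as a key-value text file
#'
#' @param weights a [fkl_fit()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fusion_weights <- function(weights, path) {
  lines <- c(paste0("lambda\t", format_g12(weights$lam)),
             paste0("objective\t", format_g12(weights$objective)),
             paste0("mu.", names(weights$mu), "\t", format_g12(weights$mu)))
  writeLines(lines, path)
  invisible(path)
}
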