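# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Global alignment score by exhaustive enumeration over all alignments
# (linear gap). Feasible only for short sequences (<= ~7 symbols).
brute_force_nw <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= length(a)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(b)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Objective of the kernel-fusion QP at a given weight vector.
fusion_objective <- function(mu, kernels, target, lam) {
  K <- Reduce(`+`, Map(`*`, kernels, mu))
  sum((K - target)^2) + lam * sum(mu^2)
}

# All simplex grid points at the given step for 3 weights.
simplex_grid3 <- function(step = 0.01) {
  g <- seq(0, 1, by = step)
  pts <- expand.grid(mu1 = g, mu2 = g)
  pts <- pts[pts$mu1 + pts$mu2 <= 1 + 1e-12, ]
  cbind(pts$mu1, pts$mu2, pmax(0, 1 - pts$mu1 - pts$mu2))
}

# Brute-force top-k sparsifier: per-pair order statistics from scratch.
brute_force_sparsify <- function(K, k) {
  n <- nrow(K)
  w <- matrix(NA_real_, n, n)
  kth <- function(v) sort(v, decreasing = TRUE)[k]
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ti <- kth(K[i, ])   # row order statistic
      tj <- kth(K[, j])   # column order statistic
      w[i, j] <- if (K[i, j] > max(ti, tj)) 1
      else if (K[i, j] < min(ti, tj)) 0
      else 0.5
    }
  }
  list(weights = w, kernel = w * K)
}

# Mann-Whitney AUC by explicit pair counting.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Average precision by rank-by-rank accumulation.
brute_force_aupr <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  tp <- 0; ap <- 0
  for (i in seq_along(lab)) {
    if (lab[i] == 1) {
      tp <- tp + 1
      ap <- ap + tp / i
    }
  }
  ap / sum(labels == 1)
}

# Numerical minimizer of the LapRLS trace-form objective
#   ||Y - K a||_F^2 + beta * tr(a' K L K a)
# by BFGS with the analytic gradient.
numeric_laprls <- function(K, L, Y, beta) {
  n <- nrow(K); q <- ncol(Y)
  KLK <- K %*% L %*% K
  fn <- function(v) {
    a <- matrix(v, n, q)
    R <- Y - K %*% a
    sum(R^2) + beta * sum(diag(t(a) %*% KLK %*% a))
  }
  gr <- function(v) {
    a <- matrix(v, n, q)
    as.vector(-2 * K %*% (Y - K %*% a) + beta * (KLK + t(KLK)) %*% a)
  }
  res <- stats::optim(rep(0, n * q), fn, gr, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  K %*% matrix(res$par, n, q)
}

# Random symmetric nonnegative kernel with unit diagonal.
random_kernel <- function(n, name = "kernel") {
  K <- matrix(runif(n * n), n)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  similarity_kernel(K, paste0("e", seq_len(n)), name = name)
}

# Random symmetric positive-definite kernel (nonnegative entries).
random_spd_kernel <- function(n) {
  A <- matrix(runif(n * n, 0.1, 1), n)
  K <- crossprod(A) / n + diag(n) * 0.5
  similarity_kernel(K / max(K), paste0("e", seq_len(n)))
}

tiny_assoc <- function() {
  association_matrix(rbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1), c(1, 1, 1)),
                     paste0("m", 1:4), paste0("d", 1:3))
}
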