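#' k-th largest element of a kernel row
#'
#' The top-k threshold used by the sparsifier: the k-th largest value of row
#' `axis_index` (duplicates occupy consecutive ranks; the diagonal entry
#' participates). For a symmetric kernel rows and columns coincide.
#'
#' @param K similarity kernel.
#' @param k order statistic, `0 < k <= nrow(K)` (the sparsifier further
#'   requires `k < nrow(K)`).
#' @param axis_index row index.
#' @return the k-th largest value of the row.
#' @export
topk_value <- function(K, k, axis_index) {
  n <- nrow(K)
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k) || k < 1 || k > n) {
    stop_mda(sprintf("`k` must be an integer in [1, %d], got %s", n, format(k)))
  }
  unname(sort(K[axis_index, ], decreasing = TRUE)[as.integer(k)])
}

#' Top-k neighbor sparsification of a similarity kernel
#'
#' Denoises a fused kernel by reweighting each entry according to its rank
#' relative to the k-th order statistics of its row and column. With
#' `T(k, i)` the k-th largest element of row `i` (diagonal included), the
#' weight of entry `(i, j)` is
#' \describe{
#'   \item{1}{if `K(i, j) > max(T(k, i), T(k, j))` — a top neighbor from
#'     both viewpoints;}
#'   \item{0.5}{if `K(i, j)` lies in the closed interval
#'     `[min(T(k, i), T(k, j)), max(T(k, i), T(k, j))]` — a top neighbor
#'     from one viewpoint (boundary equality included);}
#'   \item{0}{if `K(i, j) < min(T(k, i), T(k, j))` — below both thresholds.}
#' }
#' The sparsified kernel is the elementwise product `w * K`, so every entry
#' is `0`, `K/2` or `K`.
#'
#' @param K symmetric similarity kernel.
#' @param k neighbor count, `0 < k < nrow(K)`. The pipeline default is 20
#'   (40 for local leave-one-out evaluation).
#' @return list with `weights` (the `{0, 0.5, 1}` matrix) and `kernel` (the
#'   sparsified similarity kernel, named `"sparsified"`).
#' @examples
#' K <- similarity_kernel(rbind(c(1, 0.9, 0.2), c(0.9, 1, 0.4), c(0.2, 0.4, 1)))
#' sparsify_kernel(K, 2)$weights
#' @export
sparsify_kernel <- function(K, k) {
  n <- nrow(K)
  if (max_asymmetry(K) > 1e-9) {
    stop_mda("sparsify_kernel requires a symmetric kernel; symmetrize upstream")
  }
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k) || k < 1 || k >= n) {
    stop_mda(sprintf("`k` must be an integer in [1, %d) for a %dx%d kernel",
                     n, n, n))
  }
  thresholds <- vapply(seq_len(n), function(i) topk_value(K, k, i), numeric(1))
  lo <- outer(thresholds, thresholds, pmin)
  hi <- outer(thresholds, thresholds, pmax)
  w <- matrix(0.5, n, n, dimnames = dimnames(K))
  w[K > hi] <- 1
  w[K < lo] <- 0
  Ks <- w * K
  list(weights = w,
       kernel = similarity_kernel(Ks, rownames(K), name = "sparsified"))
}
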