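#' Construct (and validate) a similarity kernel
#'
#' A similarity kernel is a named square matrix of pairwise similarity
#' scores over one entity side (miRNAs or diseases). All kernels produced by
#' this package satisfy: symmetric within `1e-9`, finite, nonnegative, with
#' identical row and column name order.
#'
#' @param values square numeric matrix.
#' @param ids character vector of entity identifiers; defaults to existing
#'   rownames.
#' @param name provenance tag (e.g. `"gip"`, `"sequence"`, `"semantic"`,
#'   `"functional"`, `"fused"`, `"sparsified"`), stored as the
#'   `"kernel_name"` attribute.
#' @param tol symmetry tolerance.
#' @return the validated matrix with dimnames and the name attribute set.
#' @export
similarity_kernel <- function(values, ids = rownames(values), name = "kernel",
                              tol = 1e-9) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop_mda(sprintf("kernel must be square, got %dx%d",
                     nrow(values), ncol(values)))
  }
  if (is.null(ids)) ids <- paste0("e", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (length(ids) != nrow(values)) {
    stop_mda("kernel dimension does not match its catalog")
  }
  if (anyDuplicated(ids)) stop_mda("kernel catalog ids must be unique")
  if (!all(is.finite(values))) stop_mda("kernel entries must all be finite")
  if (any(values < 0)) stop_mda("kernel entries must all be nonnegative")
  if (max_asymmetry(values) > tol) {
    stop_mda(sprintf("kernel is asymmetric beyond tolerance %g", tol))
  }
  dimnames(values) <- list(ids, ids)
  attr(values, "kernel_name") <- name
  values
}

kernel_name <- function(K) {
  nm <- attr(K, "kernel_name")
  if (is.null(nm)) "kernel" else nm
}

format_g12 <- function(x) sprintf("%.12g", x)

# Shared TSV dialect for square named matrices (kernels, score matrices):
# header row of column ids, leading id column, %.12g cells.
write_matrix_tsv <- function(M, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(M)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(M)), function(i) {
    paste(c(rownames(M)[i], format_g12(M[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           row.names = 1L, comment.char = "#",
                           stringsAsFactors = FALSE, colClasses = NA)
  M <- as.matrix(tab)
  if (!is.numeric(M)) stop_mda(sprintf("non-numeric cell in matrix file %s", path))
  M
}

#' Read a similarity kernel from a TSV matrix file
#'
#' The file format is a tab-separated square matrix: a header row of entity
#' ids (first cell is an ignored corner label), then one row per entity with
#' the id in the first column. Row and column id orders must be identical.
#' Asymmetric input is symmetrized as `(K + t(K)) / 2`; a warning is issued
#' when the asymmetry exceeds `1e-6`.
#'
#' @param path path to the kernel file.
#' @param ids optional catalog; when supplied the file ids must match it
#'   exactly (same order).
#' @param name provenance tag for the kernel.
#' @return a similarity kernel (see [similarity_kernel()]).
#' @export
read_kernel <- function(path, ids = NULL, name = "kernel") {
  M <- read_matrix_tsv(path)
  if (nrow(M) != ncol(M)) {
    stop_mda(sprintf("kernel file %s is not square (%dx%d)",
                     path, nrow(M), ncol(M)))
  }
  if (!identical(rownames(M), colnames(M))) {
    stop_mda(sprintf("kernel file %s: row ids differ from column ids", path))
  }
  if (!is.null(ids) && !identical(rownames(M), as.character(ids))) {
    stop_mda(sprintf("kernel file %s ids do not match the supplied catalog", path))
  }
  asym <- max_asymmetry(M)
  if (asym > 1e-6) {
    warning(sprintf("kernel file %s asymmetric (max |K - t(K)| = %g); symmetrized",
                    path, asym), call. = FALSE)
  }
  M <- (M + t(M)) / 2
  similarity_kernel(M, rownames(M), name = name)
}

#' Write a similarity kernel (or score matrix) to TSV
#'
#' Values are printed with `%.12g` so a write/read round trip reproduces
#' them to 12 significant digits.
#'
#' @param K matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(K, path) write_matrix_tsv(K, path)
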