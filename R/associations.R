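#' Construct a binary miRNA-disease association matrix
#'
#' The association matrix `Y` is the central data structure: rows are miRNAs,
#' columns are diseases, and `Y[i, j] = 1` records a verified association.
#' Row `i` is the interaction profile of miRNA `i`; column `j` is the
#' interaction profile of disease `j`.
#'
#' @param values numeric matrix with entries in `{0, 1}`.
#' @param mirnas character vector of unique miRNA identifiers (row order).
#' @param diseases character vector of unique disease identifiers (column
#'   order).
#' @return a base matrix with `dimnames = list(mirnas, diseases)` whose
#'   entries are 0/1 doubles.
#' @examples
#' Y <- association_matrix(rbind(c(1, 0), c(0, 1)), c("mA", "mB"), c("d1", "d2"))
#' interaction_profile(Y, "miRNA", 1)
#' @export
association_matrix <- function(values, mirnas, diseases) {
  values <- as.matrix(values)
  mirnas <- as.character(mirnas)
  diseases <- as.character(diseases)
  if (anyDuplicated(mirnas)) stop_mda("miRNA identifiers must be unique")
  if (anyDuplicated(diseases)) stop_mda("disease identifiers must be unique")
  if (nrow(values) != length(mirnas) || ncol(values) != length(diseases)) {
    stop_mda(sprintf(
      "association matrix is %dx%d but catalogs have %d miRNAs and %d diseases",
      nrow(values), ncol(values), length(mirnas), length(diseases)
    ))
  }
  if (!all(values %in% c(0, 1))) {
    stop_mda("association matrix entries must all be 0 or 1")
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(mirnas, diseases)
  values
}

#' Extract an interaction profile from an association matrix
#'
#' @param Y association matrix (see [association_matrix()]).
#' @param side `"miRNA"` (a row of `Y`) or `"disease"` (a column).
#' @param id entity name or index.
#' @return numeric 0/1 vector.
#' @export
interaction_profile <- function(Y, side = c("miRNA", "disease"), id) {
  side <- match.arg(side)
  if (side == "miRNA") Y[id, ] else Y[, id]
}

#' Read a miRNA-disease association pair list
#'
#' Reads a two-column tab-separated file (`miRNA_id<TAB>disease_id`, one
#' verified association per line, `#` comment lines ignored) into a binary
#' association matrix. Duplicate pairs collapse to a single 1. When catalogs
#' are not supplied they are inferred from the file and sorted
#' lexicographically so that matrix axis order is deterministic.
#'
#' @param path path to the pair-list file.
#' @param mirnas optional character vector fixing the miRNA catalog (row
#'   order); every miRNA in the file must be a member.
#' @param diseases optional character vector fixing the disease catalog.
#' @return association matrix (see [association_matrix()]).
#' @export
read_associations <- function(path, mirnas = NULL, diseases = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  pairs <- vector("list", sum(keep))
  n_pair <- 0L
  for (ln in which(keep)) {
    fields <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L || !nzchar(fields[[1L]]) || !nzchar(fields[[2L]])) {
      stop_mda(sprintf("malformed association line %d in %s: %s",
                       ln, path, lines[[ln]]))
    }
    n_pair <- n_pair + 1L
    pairs[[n_pair]] <- c(fields[[1L]], fields[[2L]], ln)
  }
  pairs <- pairs[seq_len(n_pair)]
  file_m <- vapply(pairs, `[[`, character(1), 1L)
  file_d <- vapply(pairs, `[[`, character(1), 2L)
  file_ln <- vapply(pairs, `[[`, character(1), 3L)

  check_members <- function(found, catalog, what) {
    bad <- which(!(found %in% catalog))
    if (length(bad)) {
      stop_mda(sprintf("unknown %s id '%s' at line %s of %s",
                       what, found[bad[1L]], file_ln[bad[1L]], path))
    }
  }
  if (is.null(mirnas)) mirnas <- sort(unique(file_m)) else {
    check_members(file_m, mirnas, "miRNA")
  }
  if (is.null(diseases)) diseases <- sort(unique(file_d)) else {
    check_members(file_d, diseases, "disease")
  }

  Y <- matrix(0, length(mirnas), length(diseases),
              dimnames = list(as.character(mirnas), as.character(diseases)))
  if (n_pair) Y[cbind(file_m, file_d)] <- 1
  association_matrix(Y, rownames(Y), colnames(Y))
}

#' Write an association matrix as a pair list
#'
#' Inverse of [read_associations()] on the set of 1-entries: writes one
#' `miRNA_id<TAB>disease_id` line per known association, in row-major order.
#'
#' @param Y association matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(Y, path) {
  idx <- which(Y == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  lines <- paste(rownames(Y)[idx[, 1L]], colnames(Y)[idx[, 2L]], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Mask known associations for cross-validation
#'
#' Returns a copy of `Y` with the given known associations reset to 0, the
#' masking step that turns a test fold into unobserved pairs. The input is
#' left unchanged.
#'
#' @param Y association matrix.
#' @param test_pairs two-column integer matrix of (row, column) indices, one
#'   test pair per row; every indexed entry must currently be 1. A zero-row
#'   matrix (or `NULL`) masks nothing.
#' @return association matrix with the test entries set to 0.
#' @export
mask_associations <- function(Y, test_pairs) {
  if (is.null(test_pairs) || NROW(test_pairs) == 0L) return(Y)
  test_pairs <- matrix(as.integer(test_pairs), ncol = 2L)
  vals <- Y[test_pairs]
  if (any(vals != 1)) {
    bad <- which(vals != 1)[1L]
    stop_mda(sprintf(
      "test pair (%d, %d) does not index a known association (value %g)",
      test_pairs[bad, 1L], test_pairs[bad, 2L], vals[bad]
    ))
  }
  Y[test_pairs] <- 0
  Y
}
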