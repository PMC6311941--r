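#' Generate a block-structured association matrix
#'
#' Draws a bipartite stochastic block model: miRNAs and diseases are
#' assigned to `b` aligned blocks (contiguous, remainders joining the last
#' block) and each pair is associated with probability `p_in` inside an
#' aligned block and `p_out` across blocks. This emulates the clustered
#' structure the similarity assumption presumes — similar miRNAs associate
#' with similar diseases — and is the package's recovery benchmark.
#'
#' @param m,n miRNA and disease counts.
#' @param b block count.
#' @param p_in within-block association probability.
#' @param p_out cross-block probability; must satisfy
#'   `0 <= p_out < p_in <= 1`.
#' @param seed RNG seed; the draw is a pure function of the arguments.
#' @return association matrix with ids `mir_001...` / `dis_001...` and
#'   block assignments in attributes `"block_m"`, `"block_d"`.
#' @export
generate_block_associations <- function(m, n, b, p_in = 0.8, p_out = 0.05,
                                        seed = 1L) {
  check_scalar_number(p_in, "p_in", 0, 1)
  check_scalar_number(p_out, "p_out", 0, 1)
  if (!(p_out < p_in) && !(p_in == 0 && p_out == 0)) {
    stop_mda("need 0 <= p_out < p_in <= 1 (or both zero)")
  }
  if (b < 1 || b > min(m, n)) stop_mda("block count must be in [1, min(m, n)]")
  block_of <- function(size) pmin(((seq_len(size) - 1L) %/% (size %/% b)) + 1L, b)
  bm <- block_of(m)
  bd <- block_of(n)
  aligned <- outer(bm, bd, `==`)
  prob <- ifelse(aligned, p_in, p_out)
  vals <- with_seed(seed, matrix(stats::rbinom(m * n, 1L, prob), m, n))
  Y <- association_matrix(vals,
                          sprintf("mir_%03d", seq_len(m)),
                          sprintf("dis_%03d", seq_len(n)))
  attr(Y, "block_m") <- bm
  attr(Y, "block_d") <- bd
  Y
}

#' Generate a random disease DAG
#'
#' Builds a single-rooted acyclic hierarchy with `depth` levels below the
#' root and the given leaves at the bottom; every non-root node gets one or
#' two parents drawn from the level above. `depth = 1` yields a star with
#' all leaves under the root.
#'
#' @param n_leaves leaf (disease) count, or a character vector of leaf ids.
#' @param depth number of levels below the root, `>= 1`.
#' @param delta semantic contribution factor for the resulting DAG.
#' @param seed RNG seed.
#' @return a [disease_dag()] whose leaves are `dis_001...` (or the supplied
#'   ids).
#' @export
generate_dag <- function(n_leaves, depth = 3L, delta = 0.5, seed = 1L) {
  if (is.character(n_leaves)) {
    leaves <- n_leaves
  } else {
    if (n_leaves < 1) stop_mda("need at least one leaf")
    leaves <- sprintf("dis_%03d", seq_len(n_leaves))
  }
  if (depth < 1) stop_mda("`depth` must be >= 1")
  nl <- length(leaves)
  # Level sizes shrink geometrically from the leaves up to the single root.
  sizes <- vapply(seq_len(depth - 1L), function(l) {
    max(2L, as.integer(ceiling(nl * (0.5^(depth - l)))))
  }, integer(1))
  levels <- c(list("root"),
              lapply(seq_along(sizes), function(l) {
                sprintf("t%d_%03d", l, seq_len(sizes[l]))
              }),
              list(leaves))
  edges <- with_seed(seed, {
    do.call(rbind, lapply(seq_along(levels)[-1L], function(l) {
      parents <- levels[[l - 1L]]
      do.call(rbind, lapply(levels[[l]], function(node) {
        np <- if (length(parents) > 1L) sample(1:2, 1L) else 1L
        data.frame(child = node,
                   parent = sample(parents, min(np, length(parents))),
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  disease_dag(edges, delta = delta)
}

#' Generate random miRNA sequences
#'
#' Independent uniform RNA strings over `{A, C, G, U}` with lengths drawn
#' uniformly from `len_range`.
#'
#' @param ids miRNA catalog (sequence names).
#' @param len_range integer length range, e.g. `c(20, 25)`.
#' @param seed RNG seed.
#' @return named character vector of sequences.
#' @export
generate_sequences <- function(ids, len_range = c(20L, 25L), seed = 1L) {
  if (any(len_range < 1)) stop_mda("sequence lengths must be positive")
  with_seed(seed, {
    lens <- sample(seq(len_range[1L], len_range[2L]), length(ids), replace = TRUE)
    stats::setNames(vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
    }, character(1)), ids)
  })
}

#' Generate a random gene network and disease gene sets
#'
#' Draws an Erdos-Renyi gene network whose edges carry uniform raw LLS
#' scores in `lls_range`, plus a random non-empty gene set per disease —
#' the two inputs the disease functional-similarity kernel needs.
#'
#' @param n_genes gene count.
#' @param edge_prob edge probability.
#' @param diseases disease catalog (one gene set per id).
#' @param set_size range of gene-set sizes, e.g. `c(3L, 8L)`.
#' @param lls_range raw LLS score range; must have positive width so
#'   normalization is well defined.
#' @param seed RNG seed.
#' @return list with `network` (raw [gene_network()]) and `sets` (named
#'   list of gene sets).
#' @export
generate_gene_network <- function(n_genes, edge_prob = 0.1, diseases,
                                  set_size = c(3L, 8L),
                                  lls_range = c(0.5, 5), seed = 1L) {
  check_scalar_number(edge_prob, "edge_prob", 0, 1)
  if (lls_range[2L] <= lls_range[1L]) stop_mda("`lls_range` must have positive width")
  if (n_genes < 2) stop_mda("need at least two genes")
  genes <- sprintf("g%04d", seq_len(n_genes))
  with_seed(seed, {
    pairs <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < edge_prob
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) < 2L) stop_mda("edge_prob too small: fewer than two edges drawn")
    net <- gene_network(data.frame(
      gene1 = genes[pairs[, 1L]],
      gene2 = genes[pairs[, 2L]],
      lls = stats::runif(nrow(pairs), lls_range[1L], lls_range[2L])
    ))
    sizes <- sample(seq(set_size[1L], min(set_size[2L], n_genes)),
                    length(diseases), replace = TRUE)
    sets <- stats::setNames(lapply(sizes, function(s) sample(genes, s)),
                            diseases)
    list(network = net, sets = sets)
  })
}

#' The packaged synthetic recovery fixture
#'
#' The fixed block-model instance used throughout the test suite and the
#' reproduction script: 60 miRNAs and 40 diseases in 4 aligned blocks, with
#' within-block association probability 0.8 against a 0.05 background, seed
#' 13. Small enough for sub-minute cross-validation yet structured enough
#' that the default pipeline separates held-out associations cleanly.
#'
#' @return association matrix (see [generate_block_associations()]).
#' @export
recovery_fixture <- function() {
  generate_block_associations(m = 60, n = 40, b = 4,
                              p_in = 0.8, p_out = 0.05, seed = 13)
}

#' Write a full synthetic input bundle to a directory
#'
#' Generates and writes every file format the pipeline reads: association
#' pair list, miRNA FASTA, disease DAG edge list, gene network, and
#' disease-gene sets — all derived deterministically from one seed.
#'
#' @param dir output directory (created if absent).
#' @param m,n,b,p_in,p_out block-model parameters
#'   (see [generate_block_associations()]).
#' @param seed master seed; sub-generators use fixed offsets from it.
#' @return named character vector of the written file paths, invisibly.
#' @export
write_synthetic_bundle <- function(dir, m = 60, n = 40, b = 4, p_in = 0.8,
                                   p_out = 0.05, seed = 13) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Y <- generate_block_associations(m, n, b, p_in, p_out, seed = seed)
  dag <- generate_dag(colnames(Y), depth = 3L, seed = seed + 1)
  seqs <- generate_sequences(rownames(Y), seed = seed + 2)
  gn <- generate_gene_network(5 * n, edge_prob = 0.05, diseases = colnames(Y),
                              seed = seed + 3)
  paths <- c(associations = file.path(dir, "associations.tsv"),
             sequences = file.path(dir, "mirna_sequences.fasta"),
             dag = file.path(dir, "disease_dag.tsv"),
             gene_network = file.path(dir, "gene_network.tsv"),
             disease_genes = file.path(dir, "disease_genes.tsv"))
  write_associations(Y, paths[["associations"]])
  write_sequences(seqs, paths[["sequences"]])
  write_dag(dag, paths[["dag"]])
  write_gene_network(gn$network, paths[["gene_network"]])
  write_disease_gene_sets(gn$sets, paths[["disease_genes"]])
  invisible(paths)
}
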