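#' Weighted gene functional-interaction network
#'
#' A HumanNet-style undirected gene network whose edges carry log-likelihood
#' scores (LLS) of functional linkage. Edges are stored once and queried
#' symmetrically.
#'
#' @param edges data frame (or matrix) with columns `(gene1, gene2, lls)`.
#' @param normalized logical flag set by [normalize_lls()].
#' @return object of class `"gene_network"`.
#' @export
gene_network <- function(edges, normalized = FALSE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 3L) stop_mda("gene network needs (gene1, gene2, lls) columns")
  edges <- data.frame(gene1 = as.character(edges[[1L]]),
                      gene2 = as.character(edges[[2L]]),
                      lls = as.numeric(edges[[3L]]),
                      stringsAsFactors = FALSE)
  if (!all(is.finite(edges$lls))) stop_mda("LLS scores must all be finite")
  structure(list(edges = edges, normalized = normalized),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene network: %d edges (%s LLS, range [%g, %g])\n",
              nrow(x$edges), if (x$normalized) "normalized" else "raw",
              min(x$edges$lls), max(x$edges$lls)))
  invisible(x)
}

#' Read a gene network from TSV
#'
#' File format: `gene1<TAB>gene2<TAB>LLS` per line, `#` comments ignored.
#'
#' @param path network file.
#' @return a raw (unnormalized) [gene_network()].
#' @export
read_gene_network <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("gene1", "gene2", "lls"))
  gene_network(tab)
}

#' Write a gene network to TSV
#'
#' @param net a [gene_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_network <- function(net, path) {
  writeLines(paste(net$edges$gene1, net$edges$gene2,
                   format_g12(net$edges$lls), sep = "\t"), path)
  invisible(path)
}

#' Min-max normalize the LLS scores of a gene network
#'
#' Rescales every edge score to `(LLS - LLS_min) / (LLS_max - LLS_min)` so
#' normalized scores span `[0, 1]` over the network.
#'
#' @param net a raw [gene_network()] with at least two distinct scores.
#' @return the network with normalized scores and `normalized = TRUE`.
#' @export
normalize_lls <- function(net) {
  rng <- range(net$edges$lls)
  if (rng[1L] == rng[2L]) {
    stop_mda("all LLS scores are equal; min-max normalization is degenerate")
  }
  net$edges$lls <- (net$edges$lls - rng[1L]) / (rng[2L] - rng[1L])
  net$normalized <- TRUE
  net
}

# Symmetric normalized-LLS lookup environment keyed "g1\rg2" (both orders).
lls_lookup <- function(net) {
  env <- new.env(parent = emptyenv(), size = 2L * nrow(net$edges))
  for (i in seq_len(nrow(net$edges))) {
    g1 <- net$edges$gene1[i]; g2 <- net$edges$gene2[i]; v <- net$edges$lls[i]
    assign(paste(g1, g2, sep = "\r"), v, envir = env)
    assign(paste(g2, g1, sep = "\r"), v, envir = env)
  }
  env
}

#' Functional similarity of two genes
#'
#' 1 for a gene with itself; the normalized LLS when the network has the
#' edge; 0 otherwise (including genes absent from the network entirely).
#'
#' @param net a normalized [gene_network()] (see [normalize_lls()]).
#' @param g1,g2 gene ids.
#' @return similarity score in `[0, 1]`.
#' @export
gene_fs <- function(net, g1, g2) {
  if (!net$normalized) stop_mda("normalize the network first (normalize_lls)")
  if (g1 == g2) return(1)
  v <- mget(paste(g1, g2, sep = "\r"), envir = lls_lookup(net),
            ifnotfound = 0)[[1L]]
  v
}

# Best-match-average of two sets under a pairwise similarity function:
# (sum over b in B of max_a sim(a, b) + sum over a in A of max_b sim(a, b))
#   / (|B| + |A|).
bma_pair <- function(set_a, set_b, sim_fun) {
  best_in <- function(g, others) max(vapply(others, function(o) sim_fun(g, o),
                                            numeric(1)))
  (sum(vapply(set_b, best_in, numeric(1), others = set_a)) +
     sum(vapply(set_a, best_in, numeric(1), others = set_b))) /
    (length(set_b) + length(set_a))
}

# Generic BMA kernel over a named list of non-empty id sets.
bma_kernel <- function(sets, sim_fun, name) {
  ids <- names(sets)
  n <- length(ids)
  K <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      K[i, j] <- K[j, i] <- bma_pair(sets[[i]], sets[[j]], sim_fun)
    }
  }
  similarity_kernel(K, ids, name = name)
}

#' Disease functional similarity kernel from gene sets
#'
#' Scores two diseases by the best-match-average of their associated gene
#' sets under pairwise gene functional similarity ([gene_fs()]): each gene
#' of one set is matched to its most similar gene in the other set, the best
#' matches are summed from both directions, and the total is divided by the
#' combined set size. Identical sets score 1.
#'
#' @param net a normalized [gene_network()].
#' @param sets named list mapping each disease id to a non-empty character
#'   vector of gene ids.
#' @param ids disease catalog; each must have a gene set.
#' @return similarity kernel over `ids`, named `"functional"`.
#' @export
functional_kernel <- function(net, sets, ids = names(sets)) {
  if (!net$normalized) net <- normalize_lls(net)
  ids <- as.character(ids)
  missing <- setdiff(ids, names(sets))
  if (length(missing)) {
    stop_mda(sprintf("no gene set for disease '%s'", missing[1L]))
  }
  sets <- sets[ids]
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    stop_mda(sprintf("empty gene set for disease '%s'", ids[empty][1L]))
  }
  lut <- lls_lookup(net)
  sim <- function(g1, g2) {
    if (g1 == g2) 1
    else mget(paste(g1, g2, sep = "\r"), envir = lut, ifnotfound = 0)[[1L]]
  }
  bma_kernel(sets, sim, name = "functional")
}

#' miRNA functional similarity by best-match-average over diseases
#'
#' MISIM-style miRNA functional similarity: two miRNAs are similar when the
#' disease sets they are associated with are semantically similar. Uses the
#' same best-match-average form as [functional_kernel()], with genes
#' replaced by associated diseases and gene similarity by a disease
#' similarity kernel. Provided for when no precomputed miRNA functional
#' kernel file is available.
#'
#' @param assoc_sets named list mapping each miRNA id to a non-empty
#'   character vector of associated disease ids, all present in
#'   `disease_kernel`.
#' @param disease_kernel similarity kernel over diseases (typically
#'   [semantic_kernel()] output).
#' @return similarity kernel over the miRNAs, named `"functional"`.
#' @export
bma_functional_similarity <- function(assoc_sets, disease_kernel) {
  empty <- lengths(assoc_sets) == 0L
  if (any(empty)) {
    stop_mda(sprintf("miRNA '%s' has no associated disease",
                     names(assoc_sets)[empty][1L]))
  }
  unknown <- setdiff(unique(unlist(assoc_sets)), rownames(disease_kernel))
  if (length(unknown)) {
    stop_mda(sprintf("disease '%s' is missing from the disease kernel",
                     unknown[1L]))
  }
  sim <- function(d1, d2) disease_kernel[d1, d2]
  bma_kernel(assoc_sets, sim, name = "functional")
}

#' Read disease-to-gene set mappings from TSV
#'
#' File format: `disease_id<TAB>gene_id` per line, `#` comments ignored.
#'
#' @param path mapping file.
#' @return named list of character vectors (gene sets per disease).
#' @export
read_disease_gene_sets <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("disease", "gene"))
  lapply(split(tab$gene, tab$disease), unique)
}

#' Write disease-to-gene set mappings to TSV
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_disease_gene_sets <- function(sets, path) {
  lines <- unlist(lapply(names(sets), function(d) paste(d, sets[[d]], sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}
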