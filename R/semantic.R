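#' Disease DAG for semantic similarity
#'
#' A MeSH-style directed acyclic graph of disease terms, stored as a
#' child-to-parent edge list plus the semantic contribution factor `delta`.
#' Each disease's ancestors (including itself) form its annotation set; a
#' term's contribution to a disease decays by a factor `delta` per step up
#' the hierarchy.
#'
#' @param edges two-column data frame (or matrix) of `(child, parent)` term
#'   ids; every non-root node must appear as a child at least once.
#' @param delta semantic contribution factor in `(0, 1)`; 0.5 by default.
#' @return object of class `"disease_dag"` with elements `edges`, `nodes`,
#'   `delta` and the validated `igraph` graph.
#' @export
disease_dag <- function(edges, delta = 0.5) {
  check_scalar_number(delta, "delta")
  if (delta <= 0 || delta >= 1) stop_mda("`delta` must lie strictly in (0, 1)")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop_mda("DAG edge list needs (child, parent) columns")
  edges <- data.frame(child = as.character(edges[[1L]]),
                      parent = as.character(edges[[2L]]),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (!igraph::is_dag(g)) stop_mda("disease hierarchy contains a cycle")
  structure(list(edges = edges,
                 nodes = igraph::V(g)$name,
                 delta = delta,
                 graph = g),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("disease DAG: %d terms, %d edges, delta = %g\n",
              length(x$nodes), nrow(x$edges), x$delta))
  invisible(x)
}

#' Read a disease DAG from a TSV edge list
#'
#' File format: `child_id<TAB>parent_id` per line, `#` comments ignored;
#' root terms appear only in the parent column.
#'
#' @param path edge-list file.
#' @param delta semantic contribution factor.
#' @return a [disease_dag()].
#' @export
read_dag <- function(path, delta = 0.5) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("child", "parent"))
  disease_dag(tab, delta = delta)
}

#' Write a disease DAG edge list
#'
#' @param dag a [disease_dag()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dag <- function(dag, path) {
  writeLines(paste(dag$edges$child, dag$edges$parent, sep = "\t"), path)
  invisible(path)
}

# Ancestor set of `d` (including d itself), following child -> parent edges.
dag_ancestors <- function(dag, d) {
  ids <- igraph::subcomponent(dag$graph, d, mode = "out")
  igraph::V(dag$graph)$name[as.integer(ids)]
}

#' Semantic contributions of a disease's ancestor terms
#'
#' For a disease `d` with ancestor set `T_d` (ancestors of `d` plus `d`
#' itself), the contribution of term `t` is 1 for `t = d` and otherwise
#' `delta` times the largest contribution among the children of `t` that lie
#' in `T_d` — i.e. contributions decay by `delta` along the most direct path
#' from `d`.
#'
#' @param dag a [disease_dag()].
#' @param d a disease/term id present in the DAG.
#' @return named numeric vector over `T_d`, ordered with `d` first.
#' @export
semantic_contributions <- function(dag, d) {
  if (!d %in% dag$nodes) stop_mda(sprintf("disease '%s' is not in the DAG", d))
  anc <- dag_ancestors(dag, d)
  sub <- igraph::induced_subgraph(dag$graph, anc)
  # child -> parent edges: topological order visits children before parents,
  # so each term's children are already scored when it is reached.
  ord <- igraph::V(sub)$name[as.integer(igraph::topo_sort(sub, mode = "out"))]
  contrib <- stats::setNames(numeric(length(ord)), ord)
  el <- igraph::as_edgelist(sub)
  children_of <- split(el[, 1L], el[, 2L])
  contrib[[d]] <- 1
  for (t in ord) {
    if (t == d) next
    kids <- children_of[[t]]
    contrib[[t]] <- dag$delta * max(contrib[kids])
  }
  c(contrib[d], contrib[setdiff(names(contrib), d)])
}

#' Semantic value of a disease
#'
#' The sum of the semantic contributions of all terms in the disease's
#' ancestor set; always `>= 1` since the disease contributes 1 itself.
#'
#' @inheritParams semantic_contributions
#' @return scalar semantic value.
#' @export
semantic_value <- function(dag, d) sum(semantic_contributions(dag, d))

#' Disease semantic similarity kernel
#'
#' Similarity of two diseases from their shared ancestry: the summed
#' contributions of shared ancestor terms (from both diseases' viewpoints),
#' normalized by the sum of the two semantic values. Values lie in `[0, 1]`
#' with unit diagonal.
#'
#' @param dag a [disease_dag()].
#' @param ids disease catalog; every id must be a DAG node.
#' @return similarity kernel over `ids`, named `"semantic"`.
#' @examples
#' dag <- disease_dag(data.frame(child = c("d1", "d2", "p"),
#'                               parent = c("p", "p", "r")))
#' semantic_kernel(dag, c("d1", "d2"))["d1", "d2"]  # 3/7
#' @export
semantic_kernel <- function(dag, ids) {
  ids <- as.character(ids)
  missing <- setdiff(ids, dag$nodes)
  if (length(missing)) {
    stop_mda(sprintf("disease '%s' is not in the DAG", missing[1L]))
  }
  contribs <- lapply(ids, function(d) semantic_contributions(dag, d))
  dv <- vapply(contribs, sum, numeric(1))
  stopifnot(all(dv >= 1))  # d itself always contributes 1
  n <- length(ids)
  K <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      shared <- intersect(names(contribs[[i]]), names(contribs[[j]]))
      K[i, j] <- K[j, i] <-
        sum(contribs[[i]][shared] + contribs[[j]][shared]) / (dv[i] + dv[j])
    }
  }
  similarity_kernel(K, ids, name = "semantic")
}
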