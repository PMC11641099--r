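# Over-representation analysis of circRNA host genes against gene sets
# (hypergeometric upper tail, expressed-gene background, BH correction) and
# Jaccard clustering of significant terms.

#' Over-representation analysis
#'
#' For each gene set, tests whether the query genes over-represent the set
#' within the background universe: p = P[X >= k] for
#' X ~ Hypergeometric(N, K, n), with N the background size, K the set size
#' within the background, n the query size within the background and k the
#' query/set overlap. Query genes outside the background are dropped with a
#' warning; sets whose within-background size falls outside
#' `[min_size, max_size]` are excluded before testing; BH adjustment is over
#' the tested sets.
#'
#' @param query_genes Character vector (e.g. host genes of expressed
#'   circRNAs); duplicates are ignored.
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param background Character vector: the expressed-gene universe.
#' @param min_size,max_size Set-size bounds measured within the background
#'   (defaults 5 and 400).
#' @return Data frame `set_name, k, K, n, N, pvalue, padj`, sorted by `padj`
#'   then `set_name`.
#' @export
ora <- function(query_genes, gene_sets, background, min_size = 5, max_size = 400) {
  background <- unique(as.character(background))
  if (!length(background)) {
    circ_stop("empty background universe", "circRPL_value_error")
  }
  query <- unique(as.character(query_genes))
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the background dropped",
                    length(outside)), call. = FALSE)
    query <- intersect(query, background)
  }
  N <- length(background)
  n <- length(query)
  sets_bg <- lapply(gene_sets, function(s) intersect(unique(s), background))
  K <- vapply(sets_bg, length, 1L)
  keep <- K >= min_size & K <= max_size
  sets_bg <- sets_bg[keep]
  K <- K[keep]
  if (!length(sets_bg)) {
    return(data.frame(set_name = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), pvalue = numeric(),
                      padj = numeric(), stringsAsFactors = FALSE))
  }
  k <- vapply(sets_bg, function(s) length(intersect(s, query)), 1L)
  # upper tail P[X >= k]; k = 0 tail includes all outcomes -> p = 1
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(set_name = names(sets_bg), k = k, K = K, n = n, N = N,
                    pvalue = p, padj = bh_adjust(p), stringsAsFactors = FALSE)
  res <- res[order(res$padj, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cluster significant terms by gene overlap
#'
#' Builds an undirected graph on significant sets with an edge whenever the
#' Jaccard index of their within-background memberships reaches
#' `jaccard_cut`, takes connected components, and drops components with
#' fewer than `min_nodes` sets. Each surviving cluster is labelled by its
#' lexicographically smallest member.
#'
#' @param results An [ora()] result data frame.
#' @param gene_sets The gene-set list used for the ORA.
#' @param background The background universe used for the ORA.
#' @param jaccard_cut Jaccard threshold for an edge (default 0.5).
#' @param alpha Significance cut on `padj` (default 0.05).
#' @param min_nodes Minimum component size kept (default 3).
#' @return Data frame `cluster, set_name`, sorted by cluster then set.
#' @export
cluster_terms <- function(results, gene_sets, background, jaccard_cut = 0.5,
                          alpha = 0.05, min_nodes = 3) {
  sig <- results$set_name[results$padj < alpha]
  empty <- data.frame(cluster = character(), set_name = character(),
                      stringsAsFactors = FALSE)
  if (length(sig) == 0) return(empty)
  background <- unique(as.character(background))
  memb <- lapply(gene_sets[sig], function(s) intersect(unique(s), background))
  m <- length(sig)
  edges <- NULL
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        inter <- length(intersect(memb[[i]], memb[[j]]))
        uni <- length(union(memb[[i]], memb[[j]]))
        if (uni > 0 && inter / uni >= jaccard_cut) {
          edges <- rbind(edges, c(sig[i], sig[j]))
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, m, name = sig)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(matrix(match(edges, sig), ncol = 2)))
  }
  comp <- igraph::components(g)
  out <- empty
  for (cid in seq_len(comp$no)) {
    members <- sort(sig[comp$membership == cid])
    if (length(members) < min_nodes) next
    out <- rbind(out, data.frame(cluster = members[1], set_name = members,
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$cluster, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
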