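# Gene functional traits from the interaction network and copy counts:
# betweenness centrality, mean cosine similarity and duplication level.

#' Build a gene interaction network from an edge list
#'
#' Creates an undirected simple graph from a two-column edge list of gene
#' identifiers. Self-loops and duplicate edges are dropped (counts reported
#' as graph attributes `dropped_self` and `dropped_dup`). Genes known to be
#' in the dataset but absent from the edge list can be added as isolated
#' vertices.
#'
#' @param edge_list Two-column data frame (or matrix) of gene identifiers.
#' @param isolated_genes Optional identifiers to include as isolated vertices.
#' @return An [igraph][igraph::graph_from_data_frame] object.
#' @export
build_network <- function(edge_list, isolated_genes = NULL) {
  el <- as.data.frame(edge_list, stringsAsFactors = FALSE)
  if (ncol(el) < 2L) stopf("edge list needs two identifier columns")
  el <- el[, 1:2]
  el[] <- lapply(el, as.character)
  bad <- which(is.na(el[[1]]) | is.na(el[[2]]) | el[[1]] == "" | el[[2]] == "")
  if (length(bad)) {
    stopf("malformed edge row(s): %s",
          paste(utils::head(bad, 10), collapse = ", "))
  }
  verts <- union(union(el[[1]], el[[2]]), as.character(isolated_genes %||% character()))
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = verts))
  n_self <- sum(igraph::which_loop(g))
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  n_dup <- igraph::ecount(g) - n_self - igraph::ecount(gs)
  gs <- igraph::set_graph_attr(gs, "dropped_self", n_self)
  igraph::set_graph_attr(gs, "dropped_dup", n_dup)
}

#' Betweenness centrality of every gene
#'
#' Unweighted shortest-path (Brandes) betweenness, unnormalized, endpoints
#' excluded, computed per connected component. The trait enters downstream
#' regressions after standardization, so the scale is immaterial;
#' normalization is available via `normalized = TRUE`.
#'
#' @param network Graph from [build_network()].
#' @param normalized Divide by the number of vertex pairs per component?
#' @return Named numeric vector of betweenness values.
#' @export
network_betweenness <- function(network, normalized = FALSE) {
  igraph::betweenness(network, directed = FALSE, weights = NULL,
                      normalized = normalized)
}

#' Mean cosine similarity of every gene's neighbourhood
#'
#' Pairwise cosine similarity between genes u, v is
#' `|N(u) & N(v)| / sqrt(deg(u) deg(v))` on binary adjacency rows (0 when
#' either degree is 0; no implicit self-loop). Each gene's trait value is the
#' mean similarity to *all* other genes in the network, zeros included, also
#' across components. Computed with sparse matrix-vector products, so memory
#' stays proportional to the number of edges, never |V|^2.
#'
#' @param network Graph from [build_network()].
#' @return Named numeric vector of mean cosine similarities in \[0, 1\].
#' @export
mean_cosine <- function(network) {
  n <- igraph::vcount(network)
  nm <- igraph::V(network)$name
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  if (n == 1L) return(stats::setNames(0, nm))
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  deg <- Matrix::rowSums(A)
  dih <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  # sum_v S_uv = d_u^{-1/2} * (A (A d^{-1/2}))_u ; subtract S_uu = 1 (deg>0)
  w <- as.numeric(A %*% (A %*% dih))
  tot <- dih * w - as.numeric(deg > 0)
  mc <- tot / (n - 1)
  mc[deg == 0] <- 0
  stats::setNames(pmin(pmax(mc, 0), 1), nm)
}

#' Duplication level of every gene
#'
#' Mean copy count among the strains that carry the gene (so single-copy
#' genes score 1). With `mode = "extra"` the mean number of *extra* copies
#' (count - 1) is returned instead; the interaction-data convention is
#' ambiguous, so both are exposed.
#'
#' @param pm A `pangenome_matrix` with copy counts.
#' @param mode `"copies"` (default) or `"extra"`.
#' @return Named numeric vector; `NA` (with a warning) for genes absent from
#'   every strain.
#' @export
duplication_level <- function(pm, mode = c("copies", "extra")) {
  stopifnot(inherits(pm, "pangenome_matrix"))
  mode <- match.arg(mode)
  cnt <- pm$counts
  carriers <- colSums(cnt >= 1L)
  dup <- colSums(cnt) / carriers
  if (mode == "extra") dup <- dup - 1
  absent <- carriers == 0L
  if (any(absent)) {
    dup[absent] <- NA_real_
    warnf("%d gene(s) absent from every strain have undefined duplication",
          sum(absent))
  }
  stats::setNames(dup, pm$genes)
}

#' Assemble the gene trait table
#'
#' Joins betweenness, mean cosine similarity and duplication level for the
#' genes of a pangenome matrix. Genes missing from the network get `NA`
#' traits (callers typically drop them, mirroring genes without an
#' interaction-database match).
#'
#' @param network Graph from [build_network()].
#' @param pm A `pangenome_matrix`.
#' @param duplication_mode Passed to [duplication_level()].
#' @return Data frame `gene_id`, `betweenness`, `mean_cosine`, `duplication`.
#' @export
gene_traits <- function(network, pm, duplication_mode = "copies") {
  bt <- network_betweenness(network)
  mc <- mean_cosine(network)
  dup <- duplication_level(pm, mode = duplication_mode)
  data.frame(gene_id = pm$genes,
             betweenness = unname(bt[pm$genes]),
             mean_cosine = unname(mc[pm$genes]),
             duplication = unname(dup),
             stringsAsFactors = FALSE)
}
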