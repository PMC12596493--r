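# Node metrics, hub diseases, and hub-network coverage. All metrics are on
# the unweighted simple graph; odds ratios are display attributes only.

#' igraph view of a multimorbidity network
#'
#' @param net an `mm_network`.
#' @return an undirected [igraph::graph] with all nodes (including
#'   isolated ones) and edge attributes carried from the edge table.
#' @export
as_igraph <- function(net) {
  edges <- net$edges
  if (nrow(edges) == 0) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE) +
             igraph::vertices(net$nodes))
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' The seven node metrics
#'
#' Computes, for every node of the unweighted graph: degree, maximal clique
#' centrality (MCC: the sum over maximal cliques containing the node of
#' (clique size - 1)!), closeness centrality, local clustering
#' coefficient, betweenness centrality, PageRank (damping 0.85), and
#' eigencentrality.
#'
#' Disconnected-graph conventions: closeness is the within-component
#' closeness scaled by (component size - 1)/(n - 1), so it lies in [0, 1]
#' and is 0 for isolated nodes; betweenness counts only connected pairs;
#' clustering is 0 for nodes of degree < 2; eigencentrality is computed on
#' the largest connected component (max-normalised to 1) and 0 elsewhere;
#' PageRank uses the whole graph and sums to 1. An isolated node is its
#' own maximal (singleton) clique, so its MCC is 0! = 1.
#'
#' @param net an `mm_network`.
#' @return data.frame with columns `node`, `degree`, `mcc`, `closeness`,
#'   `clustering`, `betweenness`, `pagerank`, `eigencentrality`, ordered
#'   as `net$nodes`.
#' @export
node_metrics <- function(net) {
  g <- as_igraph(net)
  nv <- igraph::vcount(g)
  if (nv == 0) {
    return(data.frame(node = character(0), degree = integer(0),
                      mcc = numeric(0), closeness = numeric(0),
                      clustering = numeric(0), betweenness = numeric(0),
                      pagerank = numeric(0), eigencentrality = numeric(0)))
  }
  nodes <- igraph::V(g)$name
  deg <- igraph::degree(g)

  # MCC over maximal cliques (singletons count for isolated nodes only).
  mcc <- numeric(nv)
  cliques <- igraph::max_cliques(g)
  for (cl in cliques) {
    idx <- as.integer(cl)
    mcc[idx] <- mcc[idx] + factorial(length(idx) - 1)
  }

  # Closeness: within-component closeness scaled by (comp - 1)/(n - 1).
  dmat <- igraph::distances(g)
  closeness <- vapply(seq_len(nv), function(v) {
    d <- dmat[v, -v]
    d <- d[is.finite(d)]
    k <- length(d)
    if (k == 0 || nv == 1) return(0)
    (k / sum(d)) * (k / (nv - 1))
  }, numeric(1))

  clustering <- igraph::transitivity(g, type = "local", isolates = "zero")
  betweenness <- igraph::betweenness(g, directed = FALSE)
  pagerank <- igraph::page_rank(g, damping = 0.85)$vector

  eig <- numeric(nv)
  if (igraph::ecount(g) > 0) {
    comp <- igraph::components(g)
    big <- which.max(comp$csize)
    members <- which(comp$membership == big)
    sub <- igraph::induced_subgraph(g, members)
    ev <- igraph::eigen_centrality(sub)$vector  # max-normalised to 1
    eig[members] <- ev[match(igraph::V(sub)$name, nodes[members])]
  }

  data.frame(node = nodes, degree = as.integer(deg), mcc = mcc,
             closeness = closeness, clustering = clustering,
             betweenness = betweenness, pagerank = as.numeric(pagerank),
             eigencentrality = eig, stringsAsFactors = FALSE)
}

#' Hub diseases: top-k nodes by degree
#'
#' Ranks nodes by descending degree; ties at the cut are broken by
#' descending MCC, then ascending code, so the selection is deterministic.
#' Only nodes with degree > 0 are eligible; if fewer than `k` such nodes
#' exist, all of them are returned with a warning.
#'
#' @param net an `mm_network` with at least one edge.
#' @param k number of hubs (default 10).
#' @param metrics optional precomputed [node_metrics()] table.
#' @return character vector of hub codes, in rank order; attribute
#'   `tie_at_cut` flags whether the degree at the cut was tied.
#' @export
top_hubs <- function(net, k = 10, metrics = NULL) {
  if (nrow(net$edges) == 0) stop("network has no edges; no hubs defined")
  if (is.null(metrics)) metrics <- node_metrics(net)
  m <- metrics[metrics$degree > 0, , drop = FALSE]
  ord <- order(-m$degree, -m$mcc, m$node)
  m <- m[ord, , drop = FALSE]
  if (nrow(m) < k) {
    warning("only ", nrow(m), " nodes with degree > 0; returning all")
    k <- nrow(m)
  }
  tie <- nrow(m) > k && m$degree[k] == m$degree[k + 1]
  structure(m$node[seq_len(k)], tie_at_cut = isTRUE(tie))
}

#' Hub diseases network
#'
#' Subgraph induced on the hub set: nodes are the hubs, edges are the
#' parent edges with both endpoints among the hubs.
#'
#' @param net an `mm_network`.
#' @param hubs character vector of hub codes (subset of `net$nodes`).
#' @return an `mm_network` with `operation = "hub"`.
#' @export
hub_network <- function(net, hubs) {
  stopifnot(all(hubs %in% net$nodes))
  keep <- net$edges$x %in% hubs & net$edges$y %in% hubs
  edges <- net$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  new_mm_network(nodes = sort(hubs), edges = edges, operation = "hub",
                 label = paste0(net$stratum_label, "_hub"),
                 n_records = net$n_records, parents = net$stratum_label)
}

#' Hub diseases' associated network
#'
#' All parent edges with at least one hub endpoint; nodes are the
#' endpoints of those edges.
#'
#' @inheritParams hub_network
#' @return an `mm_network` with `operation = "hub_associated"`.
#' @export
hub_associated_network <- function(net, hubs) {
  stopifnot(all(hubs %in% net$nodes))
  keep <- net$edges$x %in% hubs | net$edges$y %in% hubs
  edges <- net$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  new_mm_network(nodes = sort(unique(c(edges$x, edges$y))), edges = edges,
                 operation = "hub_associated",
                 label = paste0(net$stratum_label, "_hub_associated"),
                 n_records = net$n_records, parents = net$stratum_label)
}

#' Coverage of a subnetwork against its parent
#'
#' Node, edge, and total-pattern-frequency counts of `sub` as percentages
#' of the parent complete network.
#'
#' @param sub,parent `mm_network` objects; `sub`'s edges must be a subset
#'   of `parent`'s.
#' @return list with `node_count`, `node_pct`, `edge_count`, `edge_pct`,
#'   `freq_total`, `freq_pct`.
#' @export
coverage <- function(sub, parent) {
  if (length(parent$nodes) == 0 || nrow(parent$edges) == 0) {
    stop("coverage undefined against an empty parent network")
  }
  ks <- pair_key(sub$edges$x, sub$edges$y)
  kp <- pair_key(parent$edges$x, parent$edges$y)
  stopifnot(all(ks %in% kp))
  list(
    node_count = length(sub$nodes),
    node_pct = pct_of(length(sub$nodes), length(parent$nodes)),
    edge_count = nrow(sub$edges),
    edge_pct = pct_of(nrow(sub$edges), nrow(parent$edges)),
    freq_total = sum(sub$edges$frequency),
    freq_pct = pct_of(sum(sub$edges$frequency),
                      sum(parent$edges$frequency))
  )
}
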