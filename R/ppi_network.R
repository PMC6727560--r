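# Protein-protein interaction graphs from STRING-style edge lists:
# confidence filtering, community detection, and topology-based ranking.
#
# Edges are kept when the combined confidence score is at least `min_score`
# (STRING's "minimum required score"); when per-channel scores are present,
# edges supported only by the text-mining channel are discarded. The graph
# is treated as unweighted for shortest-path centralities (hop counting is
# the convention) and weighted by the combined score for modularity.

.channel_cols <- c("neighborhood", "fusion", "cooccurence", "cooccurrence",
                   "coexpression", "experimental", "database", "textmining")

#' Read a STRING-style edge list
#'
#' Expects a TSV with two node columns (`node1`, `node2`, or the first two
#' columns), a `combined_score` column, and optional evidence-channel
#' columns. Scores may be on the 0-1 or 0-1000 scale; 0-1000 scores are
#' divided by 1000.
#'
#' @param path TSV path, or a data.frame already in memory.
#' @param min_score minimum combined score (0-1 scale), default 0.7; the
#'   boundary is inclusive (score = 0.7 is retained).
#' @param drop_textmining_only drop edges whose only supporting channel is
#'   text mining, default TRUE.
#' @return an `interaction_graph`: list with `graph` (an [igraph] object
#'   with edge attribute `combined_score`) and `edges` (the retained
#'   data.frame).
#' @export
read_string_edges <- function(path, min_score = 0.7,
                              drop_textmining_only = TRUE) {
  .check_number(min_score, "min_score", lower = 0, upper = 1)
  .check_flag(drop_textmining_only, "drop_textmining_only")
  tab <- if (is.data.frame(path)) path else
    utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, check.names = FALSE)
  node_cols <- intersect(c("node1", "node2"), names(tab))
  if (length(node_cols) < 2) node_cols <- names(tab)[1:2]
  if (!"combined_score" %in% names(tab))
    stop("edge table needs a combined_score column")
  score <- as.numeric(tab$combined_score)
  channels <- intersect(.channel_cols, names(tab))
  scale_cols <- c("combined_score", channels)
  if (any(score > 1)) {                       # 0-1000 scale
    if (any(score > 1000 | score < 0)) stop("scores outside both scales")
    for (cl in scale_cols) tab[[cl]] <- as.numeric(tab[[cl]]) / 1000
    score <- tab$combined_score
  } else if (any(score < 0)) stop("scores outside both scales")
  keep <- score >= min_score
  if (drop_textmining_only &&
      "textmining" %in% names(tab) && length(channels) > 1) {
    others <- setdiff(channels, "textmining")
    other_support <- rowSums(as.matrix(tab[, others, drop = FALSE]) > 0) > 0
    keep <- keep & !(tab$textmining > 0 & !other_support)
  }
  edges <- tab[keep, , drop = FALSE]
  # drop self-loops and duplicate unordered pairs
  a <- pmin(edges[[node_cols[1L]]], edges[[node_cols[2L]]])
  b <- pmax(edges[[node_cols[1L]]], edges[[node_cols[2L]]])
  ok <- a != b & !duplicated(paste(a, b))
  edges <- edges[ok, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[[node_cols[1L]]], to = edges[[node_cols[2L]]],
               combined_score = edges$combined_score),
    directed = FALSE)
  structure(list(graph = g, edges = edges), class = "interaction_graph")
}

#' Build an interaction graph from a plain edge data.frame
#' @param edges data.frame with `node1`, `node2`, optional `combined_score`.
#' @param ... passed to [read_string_edges()].
#' @return an `interaction_graph`.
#' @export
interaction_graph <- function(edges, ...) {
  if (!"combined_score" %in% names(edges)) edges$combined_score <- 1
  read_string_edges(edges, ...)
}

.as_igraph <- function(g) {
  if (inherits(g, "interaction_graph")) g$graph
  else if (igraph::is_igraph(g)) g
  else stop("expected an interaction_graph or igraph object")
}

#' Detect communities by modularity maximisation
#'
#' Louvain-style greedy optimisation (local moves followed by aggregation,
#' repeated to convergence), weighted by the combined score when present.
#'
#' @param g an `interaction_graph` or igraph object.
#' @param resolution resolution parameter, default 1.
#' @param seed integer seed (the local-move order is randomised).
#' @return list with `membership` (named community labels) and `modularity`.
#' @export
detect_communities <- function(g, resolution = 1.0, seed = 1) {
  ig <- .as_igraph(g)
  if (igraph::ecount(ig) < 1) stop("community detection needs >= 1 edge")
  w <- igraph::edge_attr(ig, "combined_score")
  if (is.null(w)) w <- rep(1, igraph::ecount(ig))
  cl <- with_seed(seed,
                  igraph::cluster_louvain(ig, weights = w,
                                          resolution = resolution))
  membership <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(membership),
                                    names(membership)),
       modularity = igraph::modularity(ig, membership, weights = w,
                                       resolution = resolution))
}

#' Degree, betweenness, closeness, and a combined rank
#'
#' Degree and shortest-path betweenness are unweighted (pair counting,
#' endpoints excluded). Closeness for node v is
#' `n_reachable(v) / sum of distances to reachable nodes`, which stays in
#' `[0, 1]` and is computed per connected component; isolated nodes get 0.
#' `combined_rank` ranks nodes by the mean of their three per-metric
#' descending ranks (ties share the mean rank), 1 = most central.
#'
#' @param g an `interaction_graph` or igraph object.
#' @return data.frame with `node`, `degree`, `betweenness`, `closeness`,
#'   `mean_rank`, `combined_rank`.
#' @export
centralities <- function(g) {
  ig <- .as_igraph(g)
  if (igraph::vcount(ig) == 0) stop("empty graph")
  deg <- igraph::degree(ig)
  btw <- igraph::betweenness(ig, weights = NA, directed = FALSE)
  D <- igraph::distances(ig, weights = NA)
  clo <- apply(D, 1L, function(d) {
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0) 0 else length(d) / sum(d)
  })
  rk <- function(x) rank(-x, ties.method = "average")
  mean_rank <- (rk(deg) + rk(btw) + rk(clo)) / 3
  data.frame(node = igraph::V(ig)$name, degree = unname(deg),
             betweenness = unname(btw), closeness = unname(clo),
             mean_rank = unname(mean_rank),
             combined_rank = unname(rank(mean_rank, ties.method = "average")),
             stringsAsFactors = FALSE)
}

#' Overlay bias labels and report set overlap and community composition
#'
#' @param g an `interaction_graph` or igraph object.
#' @param bias named vector of bias labels (`XX`, `XY`, `nb`) for (a subset
#'   of) the nodes; unlabelled nodes count as `nb`.
#' @param other_set gene identifiers to intersect with the node set (e.g. a
#'   co-expression module's members).
#' @param membership optional community membership from
#'   [detect_communities()]; computed on the fly otherwise.
#' @param seed seed used when communities must be computed.
#' @return list with `overlap` (size of node intersection with
#'   `other_set`), `shared_genes`, `composition` (community x bias count
#'   table), and `top_community` (community with the best mean combined
#'   rank).
#' @export
bias_overlay_and_overlap <- function(g, bias = NULL, other_set = character(0),
                                     membership = NULL, seed = 1) {
  ig <- .as_igraph(g)
  nodes <- igraph::V(ig)$name
  node_bias <- rep("nb", length(nodes))
  names(node_bias) <- nodes
  if (!is.null(bias)) {
    hit <- intersect(names(bias), nodes)
    node_bias[hit] <- bias[hit]
  }
  if (is.null(membership))
    membership <- detect_communities(g, seed = seed)$membership
  cent <- centralities(g)
  comm_rank <- tapply(cent$combined_rank, membership[cent$node], mean)
  shared <- intersect(nodes, other_set)
  list(overlap = length(shared), shared_genes = shared,
       composition = table(community = membership[nodes], bias = node_bias),
       top_community = as.integer(names(which.min(comm_rank))),
       node_bias = node_bias)
}

#' Write edge and centrality tables
#' @param g an `interaction_graph`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_edges_tsv <- function(g, path) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
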