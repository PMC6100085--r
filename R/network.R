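#' Construct a discrete Bayesian network
#'
#' A \code{bn_network} bundles a directed acyclic graph over named discrete
#' variables with per-node conditional probability tables (CPTs).  It is the
#' ground-truth container for simulation and the output container for
#' structure learning.
#'
#' @param nodes character vector of variable names (order is preserved and
#'   meaningful: all positional indexing follows it).
#' @param cardinalities integer vector, number of discrete states per node
#'   (each >= 2), parallel to \code{nodes}.
#' @param parent_sets named list (one entry per node) of character vectors of
#'   parent names; the induced directed graph must be acyclic.
#' @param cpts named list of CPT matrices, one per node.  The matrix for node
#'   \eqn{i} has \eqn{q_i} rows (one per parent configuration, lexicographic
#'   with the last parent fastest-varying) and \eqn{r_i} columns (child
#'   states); every row sums to 1 within 1e-9.  May be \code{NULL} for a
#'   structure-only network (e.g. the raw output of parent search).
#' @param states optional named list of state labels per node (defaults to
#'   \code{"s0" ... "s<r-1>"}).
#'
#' @return an object of class \code{bn_network}.
#' @export
bn_network <- function(nodes, cardinalities, parent_sets, cpts = NULL,
                       states = NULL) {
  nodes <- as.character(nodes)
  n <- length(nodes)
  if (n < 1L) stop("a network needs at least one node")
  if (anyDuplicated(nodes)) stop("duplicate node names")
  cardinalities <- as.integer(cardinalities)
  if (length(cardinalities) != n) stop("cardinalities/nodes length mismatch")
  if (any(cardinalities < 2L)) stop("every node needs at least 2 states")
  names(cardinalities) <- nodes
  parent_sets <- lapply(parent_sets, as.character)
  if (!setequal(names(parent_sets), nodes)) {
    stop("parent_sets must be named by the node set")
  }
  parent_sets <- parent_sets[nodes]
  for (v in nodes) {
    pa <- parent_sets[[v]]
    if (v %in% pa) stop("self-loop at node ", v)
    bad <- setdiff(pa, nodes)
    if (length(bad)) stop("unknown parent(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(pa)) stop("duplicate parents for node ", v)
  }
  if (is.null(states)) {
    states <- lapply(cardinalities, function(r) paste0("s", seq_len(r) - 1L))
  }
  states <- states[nodes]
  net <- structure(
    list(nodes = nodes, cardinalities = cardinalities,
         parent_sets = parent_sets, cpts = NULL, states = states),
    class = "bn_network")
  if (is.null(topological_order(net))) stop("parent structure is cyclic")
  if (!is.null(cpts)) {
    cpts <- cpts[nodes]
    for (v in nodes) {
      cpt <- as.matrix(cpts[[v]])
      q <- prod(cardinalities[parent_sets[[v]]])
      if (nrow(cpt) != q || ncol(cpt) != cardinalities[[v]]) {
        stop("CPT for ", v, " must be ", q, " x ", cardinalities[[v]])
      }
      if (any(abs(rowSums(cpt) - 1) > 1e-9)) {
        stop("CPT rows for ", v, " do not sum to 1")
      }
      cpts[[v]] <- cpt
    }
    net$cpts <- cpts
  }
  net
}

#' @export
print.bn_network <- function(x, ...) {
  st <- graph_stats(x)
  cat(sprintf("Discrete Bayesian network: %d nodes, %d edges (avg degree %.2f, max in-degree %d)\n",
              st$n_nodes, st$n_edges, st$avg_degree, st$max_in_degree))
  cat(sprintf("CPTs: %s\n", if (is.null(x$cpts)) "absent" else "present"))
  invisible(x)
}

#' Edge list of a network
#'
#' @param net a \code{bn_network}.
#' @return two-column character matrix (from, to), one row per directed edge.
#' @export
network_edges <- function(net) {
  from <- unlist(net$parent_sets, use.names = FALSE)
  to <- rep(net$nodes, vapply(net$parent_sets, length, 1L))
  cbind(from = from, to = to, deparse.level = 0)
}

#' Topological order of a network's DAG
#'
#' Kahn's algorithm over the parent relation; used both as validity check
#' (returns \code{NULL} on a cycle) and by the forward sampler.
#'
#' @param net a \code{bn_network}.
#' @return character vector of node names in a topological order, or
#'   \code{NULL} if the parent relation is cyclic.
#' @export
topological_order <- function(net) {
  nodes <- net$nodes
  indeg <- vapply(net$parent_sets, length, 1L)
  children <- lapply(nodes, function(v) {
    nodes[vapply(net$parent_sets, function(pa) v %in% pa, TRUE)]
  })
  names(children) <- nodes
  out <- character(0)
  ready <- nodes[indeg == 0L]
  while (length(ready)) {
    v <- ready[[1L]]; ready <- ready[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

#' Structural summary statistics of a network
#'
#' Reports node and edge counts, the average (total) degree
#' \eqn{2 |E| / |V|} and the maximum in-degree, the summary used to
#' characterise benchmark networks.
#'
#' @param net a \code{bn_network}.
#' @return list with \code{n_nodes}, \code{n_edges}, \code{avg_degree},
#'   \code{max_in_degree}.
#' @export
graph_stats <- function(net) {
  indeg <- vapply(net$parent_sets, length, 1L)
  n_edges <- sum(indeg)
  list(n_nodes = length(net$nodes),
       n_edges = n_edges,
       avg_degree = 2 * n_edges / length(net$nodes),
       max_in_degree = if (length(indeg)) max(indeg) else 0L)
}

# ---- PDAG ------------------------------------------------------------------

#' Construct a partially directed acyclic graph
#'
#' A PDAG mixes directed edges (established causal direction) and undirected
#' edges (adjacency whose orientation is unresolved).  The directed and
#' undirected sets are disjoint as unordered pairs and the directed subgraph
#' is acyclic.
#'
#' @param nodes character vector of node names.
#' @param directed two-column character matrix of (from, to) pairs, or NULL.
#' @param undirected two-column character matrix of unordered pairs, or NULL.
#' @return object of class \code{pdag}.
#' @export
pdag <- function(nodes, directed = NULL, undirected = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  directed <- normalize_edge_matrix(directed)
  undirected <- normalize_edge_matrix(undirected)
  if (nrow(undirected)) {
    # canonical order inside an undirected pair, drop duplicates
    undirected <- t(apply(undirected, 1L, sort))
    undirected <- unique(undirected)
    colnames(undirected) <- c("u", "v")
  }
  directed <- unique(directed)
  all_names <- c(directed, undirected)
  if (length(all_names) && !all(all_names %in% nodes)) {
    stop("edge endpoint not in node set")
  }
  if (nrow(directed) && any(directed[, 1L] == directed[, 2L])) {
    stop("self-loop in directed edges")
  }
  if (nrow(undirected) && any(undirected[, 1L] == undirected[, 2L])) {
    stop("self-loop in undirected edges")
  }
  if (nrow(directed) && nrow(undirected)) {
    dk <- pair_key(directed)
    uk <- pair_key(undirected)
    if (length(intersect(dk, uk))) {
      stop("pair present both directed and undirected")
    }
  }
  if (nrow(directed)) {
    dk <- pair_key(directed)
    if (anyDuplicated(dk)) stop("pair directed in both directions")
  }
  if (!edges_acyclic(nodes, directed)) stop("directed subgraph is cyclic")
  structure(list(nodes = nodes, directed = directed, undirected = undirected),
            class = "pdag")
}

normalize_edge_matrix <- function(m) {
  if (is.null(m) || length(m) == 0L) {
    return(matrix(character(0), 0L, 2L))
  }
  m <- matrix(as.character(m), ncol = 2L)
  m
}

pair_key <- function(m) {
  if (!nrow(m)) return(character(0))
  apply(m, 1L, function(e) paste(sort(e), collapse = "\r"))
}

# acyclicity of a directed edge list by Kahn's algorithm
edges_acyclic <- function(nodes, edges) {
  if (!nrow(edges)) return(TRUE)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges[, 2L])
  indeg[names(tab)] <- as.integer(tab)
  adj <- split(edges[, 2L], edges[, 1L])
  ready <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(ready)) {
    v <- ready[[1L]]; ready <- ready[-1L]
    seen <- seen + 1L
    for (ch in adj[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) ready <- c(ready, ch)
    }
  }
  seen == length(nodes)
}

#' @export
print.pdag <- function(x, ...) {
  cat(sprintf("PDAG: %d nodes, %d directed, %d undirected edges\n",
              length(x$nodes), nrow(x$directed), nrow(x$undirected)))
  invisible(x)
}

#' Forget edge directions: DAG skeleton
#'
#' @param net a \code{bn_network}.
#' @return a \code{pdag} whose edges are all undirected.
#' @export
dag_to_skeleton <- function(net) {
  e <- network_edges(net)
  pdag(net$nodes, directed = NULL, undirected = e)
}

#' Convert a network's DAG to a fully directed PDAG
#'
#' @param net a \code{bn_network}.
#' @return a \code{pdag} with every edge directed as in the DAG.
#' @export
dag_to_pdag <- function(net) {
  pdag(net$nodes, directed = network_edges(net), undirected = NULL)
}
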