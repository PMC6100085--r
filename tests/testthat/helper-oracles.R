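# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately brute-force and share no code with the package
# internals they check.

# Kendall-tau disagreement count by explicit pair enumeration.
kendall_oracle <- function(r1, r2) {
  n <- length(r1)
  if (n < 2L) return(0L)
  d <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      u <- r1[[i]]; v <- r1[[j]]           # u precedes v in r1
      if (match(u, r2) > match(v, r2)) d <- d + 1L
    }
  }
  d
}

# Acyclicity by permutation search: a digraph is a DAG iff some ordering of
# the nodes has all edges pointing forward.  Feasible for <= 5 nodes.
acyclic_oracle <- function(nodes, edges) {
  if (!nrow(edges)) return(TRUE)
  perms <- all_permutations(nodes)
  for (p in perms) {
    pos <- stats::setNames(seq_along(p), p)
    if (all(pos[edges[, 1L]] < pos[edges[, 2L]])) return(TRUE)
  }
  FALSE
}

all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[[i]], rest)
    }
  }
  out
}

# Exact K2 marginal likelihood g(X_i, pi_i) by integer factorial ratios;
# all intermediates stay far below 2^53 for the tiny datasets this runs on.
k2_exact_oracle <- function(data, node, parents) {
  r <- data$cardinalities[[node]]
  s <- data$values[, node]
  cfg <- if (length(parents)) {
    key <- apply(data$values[, parents, drop = FALSE], 1L, paste,
                 collapse = "/")
    match(key, unique(key))
  } else rep(1L, length(s))
  g <- 1
  for (j in unique(cfg)) {
    rows <- cfg == j
    nij <- sum(rows)
    nijk <- tabulate(s[rows] + 1L, nbins = r)
    # (r-1)! / (Nij + r - 1)! = 1 / prod(r : Nij + r - 1)
    denom <- prod(seq.int(r, nij + r - 1L))
    g <- g * prod(factorial(nijk)) / denom
  }
  g
}

# Total log score of an explicit DAG: sum of local scores of its parent sets.
dag_log_score <- function(data, parent_sets) {
  sum(vapply(names(parent_sets), function(v) {
    local_log_score(data, v, parent_sets[[v]])
  }, 0))
}

# All DAGs on the given nodes with in-degree <= max_parents, as parent-set
# lists, by filtering every directed graph (edge subsets of ordered pairs).
enumerate_dags <- function(nodes, max_parents = length(nodes) - 1L) {
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  np <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^np - 1L)) {
    take <- bitwAnd(mask, 2^(seq_len(np) - 1L)) > 0
    e <- as.matrix(pairs[take, , drop = FALSE])
    indeg <- table(factor(e[, 2L], levels = nodes))
    if (any(indeg > max_parents)) next
    if (!acyclic_oracle(nodes, e)) next
    ps <- lapply(nodes, function(v) e[e[, 2L] == v, 1L])
    names(ps) <- nodes
    out[[length(out) + 1L]] <- ps
  }
  out
}

# Strong-mechanism collider fixture: C = A^3 + A + B^3 + B + U(-1,1).
collider_continuous <- function(n, seed) {
  set.seed(seed)
  a <- runif(n, -1, 1)
  b <- runif(n, -1, 1)
  cc <- a^3 + a + b^3 + b + runif(n, -1, 1)
  continuous_dataset(cbind(A = a, B = b, C = cc))
}

# A DAG with an exact node and edge count: a chain plus skip-level edges.
chain_plus_net <- function(n_nodes, n_edges) {
  stopifnot(n_edges <= 2L * n_nodes - 3L)
  nodes <- paste0("v", seq_len(n_nodes))
  parents <- stats::setNames(rep(list(character(0)), n_nodes), nodes)
  added <- 0L
  for (i in 2:n_nodes) {
    if (added >= n_edges) break
    parents[[nodes[[i]]]] <- nodes[[i - 1L]]
    added <- added + 1L
  }
  for (i in 3:n_nodes) {
    if (added >= n_edges) break
    parents[[nodes[[i]]]] <- c(parents[[nodes[[i]]]], nodes[[i - 2L]])
    added <- added + 1L
  }
  stopifnot(added == n_edges)
  bn_network(nodes, rep(2L, n_nodes), parents)
}
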