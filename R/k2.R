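# K2 scoring: the Cooper-Herskovits Bayesian marginal likelihood of a
# node-and-parent-set local structure under uniform Dirichlet priors,
# evaluated in log space, plus the greedy per-node parent search that turns
# a topological order into a scored DAG.

#' Local K2 log score of one node given a parent set
#'
#' Computes \eqn{\ln g(X_i, \pi_i) = \sum_j [\ln\Gamma(r_i) -
#' \ln\Gamma(N_{ij} + r_i) + \sum_k \ln\Gamma(N_{ijk} + 1)]}, the log
#' marginal likelihood of the counts \eqn{N_{ijk}} (node \eqn{i} in state
#' \eqn{k} under the \eqn{j}-th parent configuration).  Parent
#' configurations never observed contribute zero.  The structure-prior
#' constant shared by all structures is dropped; log-gamma evaluation avoids
#' the factorial overflow that literal evaluation hits near counts of 170.
#'
#' @param data a \code{discrete_dataset}.
#' @param node column name of the scored node.
#' @param parents character vector of parent column names (may be empty).
#' @return the local log score (finite real).
#' @export
local_log_score <- function(data, node, parents = character(0)) {
  cols <- data$columns
  if (!node %in% cols) stop("unknown column: ", node)
  bad <- setdiff(parents, cols)
  if (length(bad)) stop("unknown column(s): ", paste(bad, collapse = ", "))
  if (node %in% parents) stop("node cannot be its own parent")
  r <- data$cardinalities[[node]]
  s <- data$values[, node]
  if (length(parents)) {
    cfg <- config_index_rows(data$values[, parents, drop = FALSE],
                             data$cardinalities[parents])
  } else {
    cfg <- rep(1L, length(s))
  }
  # compress to observed configurations: unobserved ones contribute 0
  uc <- match(cfg, unique(cfg))
  q_eff <- max(uc)
  cnt <- tabulate((uc - 1L) * r + s + 1L, nbins = q_eff * r)
  m <- matrix(cnt, nrow = q_eff, ncol = r, byrow = TRUE)
  nij <- rowSums(m)
  sum(lgamma(r) - lgamma(nij + r)) + sum(lgamma(m + 1))
}

#' Score cache for (node, parent set) queries
#'
#' Local scores depend only on the count table of \code{node} and
#' \code{parents}, so they are shared across all orders explored in a search
#' run; memoising them is the dominant cost saver of order-space search.
#'
#' @return an object of class \code{score_cache} with hit/miss counters.
#' @export
score_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$store <- new.env(parent = emptyenv())
  e$hits <- 0L
  e$misses <- 0L
  class(e) <- "score_cache"
  e
}

#' @export
print.score_cache <- function(x, ...) {
  cat(sprintf("Score cache: %d entries (%d hits, %d misses)\n",
              length(ls(x$store)), x$hits, x$misses))
  invisible(x)
}

cached_local_score <- function(cache, data, node, parents) {
  if (is.null(cache)) return(local_log_score(data, node, parents))
  key <- paste0(node, "|", paste(sort(parents), collapse = ","))
  hit <- get0(key, envir = cache$store, inherits = FALSE)
  if (!is.null(hit)) {
    cache$hits <- cache$hits + 1L
    return(hit)
  }
  cache$misses <- cache$misses + 1L
  val <- local_log_score(data, node, parents)
  assign(key, val, envir = cache$store)
  val
}

check_order <- function(order, columns) {
  order <- as.character(order)
  if (!identical(sort(order), sort(columns))) {
    stop("order must be a permutation of the data columns")
  }
  order
}

#' Greedy K2 parent search under a fixed order
#'
#' For each node, candidate parents are restricted to its predecessors in
#' \code{order}; the single predecessor giving the largest strict increase in
#' the local log score is added repeatedly until no addition improves the
#' score (gain must exceed 1e-12) or the in-degree cap \code{max_parents} is
#' reached.  Among tied candidates the one earliest in the order wins, which
#' makes the search deterministic.
#'
#' @param data a \code{discrete_dataset}.
#' @param order character vector: permutation of the data columns.
#' @param max_parents in-degree cap \eqn{\mu} on every parent set; default 4.
#' @param cache optional \code{score_cache} shared across calls.
#' @return list with \code{network} (a structure-only \code{bn_network}),
#'   \code{log_score} (the total, a sum of local scores) and \code{local}
#'   (named vector of per-node local log scores).
#' @export
k2_parent_search <- function(data, order, max_parents = 4L, cache = NULL) {
  order <- check_order(order, data$columns)
  stopifnot(max_parents >= 0L)
  locals <- stats::setNames(numeric(length(order)), order)
  parents <- stats::setNames(vector("list", length(order)), order)
  for (i in seq_along(order)) {
    v <- order[[i]]
    preds <- order[seq_len(i - 1L)]
    cur <- character(0)
    cur_score <- cached_local_score(cache, data, v, cur)
    repeat {
      if (length(cur) >= max_parents) break
      cand <- setdiff(preds, cur)
      if (!length(cand)) break
      best_gain <- 1e-12
      best_c <- NULL
      best_s <- NA_real_
      for (cc in cand) {           # order of preds = order in `order`
        s <- cached_local_score(cache, data, v, c(cur, cc))
        if (s - cur_score > best_gain) {
          best_gain <- s - cur_score
          best_c <- cc
          best_s <- s
        }
      }
      if (is.null(best_c)) break
      cur <- c(cur, best_c)
      cur_score <- best_s
    }
    parents[[v]] <- cur
    locals[[v]] <- cur_score
  }
  nodes <- data$columns                      # keep the dataset's node order
  net <- bn_network(nodes, data$cardinalities[nodes], parents[nodes])
  list(network = net, log_score = sum(locals), local = locals[nodes])
}

#' Total K2 score of an order
#'
#' The fitness function of the order search: the total log score of the
#' greedy K2 network built under \code{order}.
#'
#' @inheritParams k2_parent_search
#' @return the total log score (real scalar).
#' @export
score_order <- function(data, order, max_parents = 4L, cache = NULL) {
  k2_parent_search(data, order, max_parents, cache)$log_score
}

#' Fit CPTs to a network structure by smoothed count ratios
#'
#' Maximum-likelihood conditional frequencies with add-one (Laplace)
#' smoothing, used to round-trip learned structures through the network
#' serialisation formats.
#'
#' @param net a \code{bn_network} (structure used; CPTs replaced).
#' @param data a \code{discrete_dataset} whose columns cover the nodes.
#' @param smoothing pseudo-count added to every cell (default 1).
#' @return the network with fitted CPTs attached.
#' @export
fit_cpts <- function(net, data, smoothing = 1) {
  cpts <- lapply(net$nodes, function(v) {
    r <- net$cardinalities[[v]]
    pa <- net$parent_sets[[v]]
    q <- prod(net$cardinalities[pa])
    s <- data$values[, v]
    cfg <- if (length(pa)) {
      config_index_rows(data$values[, pa, drop = FALSE],
                        net$cardinalities[pa])
    } else rep(1L, length(s))
    cnt <- matrix(tabulate((cfg - 1L) * r + s + 1L, nbins = q * r),
                  nrow = q, ncol = r, byrow = TRUE) + smoothing
    cnt / rowSums(cnt)
  })
  names(cpts) <- net$nodes
  bn_network(net$nodes, net$cardinalities, net$parent_sets, cpts,
             states = net$states)
}
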