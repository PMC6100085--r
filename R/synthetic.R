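# Simulators: random ground-truth networks, forward (ancestral) sampling of
# discrete data, and continuous additive-noise data.  All randomness is
# confined to the calling function via a save/restore seed guard, so no
# global RNG state leaks between calls.

with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random ground-truth network
#'
#' Draws a DAG whose edges respect a hidden uniformly random permutation of
#' the nodes (each admissible earlier-to-later edge included independently
#' with probability \code{edge_prob}, truncated to \code{max_parents} per
#' node) and fills CPT rows with flat-Dirichlet draws.
#'
#' @param n_nodes number of variables.
#' @param max_parents cap on per-node in-degree.
#' @param edge_prob probability of each admissible edge.
#' @param seed integer seed; same seed, same network.
#' @param cardinality number of states per node (default 2).
#' @return a \code{bn_network} with CPTs.
#' @export
random_dag <- function(n_nodes, max_parents = 3L, edge_prob = 0.3,
                       seed = NULL, cardinality = 2L) {
  stopifnot(n_nodes >= 1L, edge_prob >= 0, edge_prob <= 1)
  with_seed_(seed, {
    nodes <- paste0("X", seq_len(n_nodes))
    perm <- sample(nodes)
    parents <- stats::setNames(vector("list", n_nodes), nodes)
    for (j in seq_len(n_nodes)) {
      earlier <- perm[seq_len(j - 1L)]
      pick <- earlier[stats::runif(length(earlier)) < edge_prob]
      if (length(pick) > max_parents) {
        pick <- sample(pick, max_parents)
      }
      parents[[perm[[j]]]] <- pick
    }
    cards <- rep(as.integer(cardinality), n_nodes)
    names(cards) <- nodes
    cpts <- lapply(nodes, function(v) {
      q <- prod(cards[parents[[v]]])
      m <- matrix(stats::rgamma(q * cards[[v]], 1), q, cards[[v]])
      m / rowSums(m)
    })
    names(cpts) <- nodes
    bn_network(nodes, cards, parents, cpts)
  })
}

#' Forward (ancestral) sampling of discrete data
#'
#' Visits nodes in a topological order and draws each from its CPT row given
#' the already-sampled parent configuration; rows are i.i.d. joint draws.
#'
#' @param net a \code{bn_network} with CPTs.
#' @param n_samples number of rows.
#' @param seed integer seed.
#' @return a \code{discrete_dataset} whose column order matches
#'   \code{net$nodes}.
#' @export
forward_sample <- function(net, n_samples, seed = NULL) {
  if (is.null(net$cpts)) stop("network has no CPTs")
  stopifnot(n_samples >= 1L)
  with_seed_(seed, {
    ord <- topological_order(net)
    out <- matrix(NA_integer_, n_samples, length(net$nodes),
                  dimnames = list(NULL, net$nodes))
    for (v in ord) {
      pa <- net$parent_sets[[v]]
      cpt <- net$cpts[[v]]
      r <- net$cardinalities[[v]]
      if (!length(pa)) {
        out[, v] <- sample.int(r, n_samples, replace = TRUE,
                               prob = cpt[1L, ]) - 1L
      } else {
        cfg <- config_index_rows(out[, pa, drop = FALSE],
                                 net$cardinalities[pa])
        for (j in sort(unique(cfg))) {
          rows <- which(cfg == j)
          out[rows, v] <- sample.int(r, length(rows), replace = TRUE,
                                     prob = cpt[j, ]) - 1L
        }
      }
    }
    discrete_dataset(out, columns = net$nodes,
                     cardinalities = net$cardinalities)
  })
}

# vectorized config_index over the rows of a 0-based state matrix
config_index_rows <- function(states0, cards) {
  j <- rep(0L, nrow(states0))
  for (i in seq_along(cards)) j <- j * cards[[i]] + states0[, i]
  j + 1L
}

#' Continuous additive-noise-model sampling from a DAG
#'
#' Every root node is a pure noise draw; every non-root is
#' \eqn{x_i = f_i(x_{pa(i)}) + \epsilon_i} with \eqn{f_i} a sum of per-parent
#' cubic-plus-linear terms whose coefficients are drawn once per call, and
#' \eqn{\epsilon_i} non-Gaussian noise independent across nodes.  Non-Gaussian
#' noise keeps the causal direction identifiable even when \eqn{f} is close
#' to linear.
#'
#' @param dag a \code{bn_network} (CPTs ignored; only the DAG is used).
#' @param n_samples number of rows.
#' @param noise noise family, \code{"uniform"} (on \code{[-1,1]} times the
#'   node's scale) or \code{"laplace"}.
#' @param noise_scale per-node noise amplitude, recycled; a 0 entry makes
#'   that node an exact function of its parents.
#' @param seed integer seed.
#' @return a \code{continuous_dataset}.
#' @export
anm_sample <- function(dag, n_samples, noise = c("uniform", "laplace"),
                       noise_scale = 1, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(n_samples >= 1L)
  nodes <- dag$nodes
  noise_scale <- rep_len(noise_scale, length(nodes))
  names(noise_scale) <- nodes
  with_seed_(seed, {
    # draw all mechanism coefficients first so noise streams do not shift
    # them when n_samples changes
    coefs <- lapply(nodes, function(v) {
      pa <- dag$parent_sets[[v]]
      if (!length(pa)) return(NULL)
      list(cubic = stats::runif(length(pa), 0.3, 1) *
             sample(c(-1, 1), length(pa), replace = TRUE),
           linear = stats::runif(length(pa), 0.3, 1) *
             sample(c(-1, 1), length(pa), replace = TRUE))
    })
    names(coefs) <- nodes
    draw_noise <- function(n, s) {
      if (s == 0) return(rep(0, n))
      u <- stats::runif(n)
      if (noise == "uniform") s * (2 * u - 1)
      else -s * sign(u - 0.5) * log(1 - 2 * abs(u - 0.5))
    }
    out <- matrix(NA_real_, n_samples, length(nodes),
                  dimnames = list(NULL, nodes))
    for (v in topological_order(dag)) {
      pa <- dag$parent_sets[[v]]
      eps <- draw_noise(n_samples, noise_scale[[v]])
      if (!length(pa)) {
        out[, v] <- eps
      } else {
        cf <- coefs[[v]]
        f <- rep(0, n_samples)
        for (i in seq_along(pa)) {
          x <- out[, pa[[i]]]
          f <- f + cf$cubic[[i]] * x^3 + cf$linear[[i]] * x
        }
        out[, v] <- f + eps
      }
    }
    continuous_dataset(out, columns = nodes)
  })
}

#' Small fixed example networks
#'
#' Hand-specified ground-truth networks with informative CPTs, used in the
#' documentation and as reproducible recovery benchmarks:
#' \describe{
#'   \item{collider3}{A -> C <- B, binary, graded (non-XOR) collider CPT.}
#'   \item{chain5}{A -> B -> C -> D -> E, binary, 0.85/0.15 transitions.}
#'   \item{tree5}{A -> B, A -> C, B -> D, C -> E, binary, 0.8/0.2 links.}
#' }
#'
#' @param name one of \code{"collider3"}, \code{"chain5"}, \code{"tree5"}.
#' @return a \code{bn_network} with CPTs.
#' @export
example_network <- function(name = c("collider3", "chain5", "tree5")) {
  name <- match.arg(name)
  flip <- function(p) matrix(c(p, 1 - p, 1 - p, p), 2L, 2L, byrow = TRUE)
  root <- matrix(c(0.5, 0.5), 1L)
  switch(name,
    collider3 = bn_network(
      c("A", "B", "C"), c(2L, 2L, 2L),
      list(A = character(0), B = character(0), C = c("A", "B")),
      list(A = root, B = root,
           C = matrix(c(0.9, 0.1,  0.6, 0.4,  0.3, 0.7,  0.1, 0.9),
                      4L, 2L, byrow = TRUE))),
    chain5 = bn_network(
      LETTERS[1:5], rep(2L, 5L),
      list(A = character(0), B = "A", C = "B", D = "C", E = "D"),
      list(A = root, B = flip(0.85), C = flip(0.85), D = flip(0.85),
           E = flip(0.85))),
    tree5 = bn_network(
      LETTERS[1:5], rep(2L, 5L),
      list(A = character(0), B = "A", C = "A", D = "B", E = "C"),
      list(A = root, B = flip(0.8), C = flip(0.8), D = flip(0.8),
           E = flip(0.8))))
}
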