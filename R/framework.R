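# End-to-end pipeline: learn a skeleton by order search + K2, optionally
# split high-dimensional problems into per-node neighborhood blocks, orient
# edges (ANM on continuous data, K2 directions on discrete data), and merge
# the partial PDAGs.

#' Framework configuration
#'
#' @param threshold_k dimension threshold: problems with fewer variables are
#'   solved whole, larger ones via the split/merge path (>= 2).
#' @param bso a \code{\link{bso_config}} for the order search.
#' @param max_parents in-degree cap for the K2 scorer.
#' @param alpha significance level of the ANM orientation stage.
#' @param max_set largest ANM candidate parent-set size.
#' @param n_permutations HSIC permutations.
#' @param discretize_bins equal-frequency bins used to discretise continuous
#'   data for the K2 skeleton phase.
#' @param seed integer master seed.
#' @return list of class \code{framework_config}.
#' @export
framework_config <- function(threshold_k = 50L, bso = bso_config(),
                             max_parents = 4L, alpha = 0.05, max_set = 3L,
                             n_permutations = 200L, discretize_bins = 3L,
                             seed = NULL) {
  if (threshold_k < 2L) stop("threshold_k must be at least 2")
  structure(list(threshold_k = as.integer(threshold_k), bso = bso,
                 max_parents = as.integer(max_parents), alpha = alpha,
                 max_set = as.integer(max_set),
                 n_permutations = as.integer(n_permutations),
                 discretize_bins = as.integer(discretize_bins), seed = seed),
            class = "framework_config")
}

#' Equal-frequency discretisation of a continuous dataset
#'
#' @param data a \code{continuous_dataset}.
#' @param bins number of bins per column.
#' @return a \code{discrete_dataset} with 0-based bin indices.
#' @export
discretize_dataset <- function(data, bins = 3L) {
  vals <- apply(data$values, 2L, function(x) {
    qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L)))
    if (length(qs) < 3L) qs <- unique(c(min(x) - 1, stats::median(x), max(x)))
    as.integer(cut(x, qs, include.lowest = TRUE, labels = FALSE)) - 1L
  })
  discrete_dataset(vals, columns = data$columns)
}

#' Learn a causal skeleton by order search plus greedy K2
#'
#' Runs \code{\link{bso_search}} for the best topological order, builds the
#' K2 network under that order, and forgets directions.
#'
#' @param data a \code{discrete_dataset}.
#' @param cfg a \code{\link{framework_config}}.
#' @param cache optional shared \code{\link{score_cache}}.
#' @return list with \code{skeleton} (a \code{pdag}), \code{network} (the
#'   directed K2 network), \code{order} and \code{score}.
#' @export
learn_skeleton <- function(data, cfg = framework_config(),
                           cache = score_cache()) {
  bso <- cfg$bso
  if (is.null(bso$seed)) bso$seed <- cfg$seed
  res <- bso_search(data, bso, cfg$max_parents, cache)
  fit <- k2_parent_search(data, res$order, cfg$max_parents, cache)
  list(skeleton = dag_to_skeleton(fit$network), network = fit$network,
       order = res$order, score = res$score)
}

#' Merge partial PDAGs
#'
#' Unions the edges of the parts.  A pair directed in any part and
#' undirected in others resolves to directed (information is preserved); a
#' pair directed both ways across parts is demoted to undirected and logged
#' as a conflict.  If the merged directed subgraph is cyclic, directed edges
#' are demoted reverse-chronologically (most recently contributed first)
#' until acyclicity is restored.
#'
#' @param parts list of \code{pdag}s.
#' @param nodes node set of the result (superset of every part's nodes).
#' @return a \code{pdag}; attribute \code{"conflicts"} lists demoted pairs.
#' @export
merge_pdags <- function(parts, nodes) {
  dir_from <- character(0); dir_to <- character(0)
  und <- matrix(character(0), 0L, 2L)
  for (p in parts) {
    if (!all(p$nodes %in% nodes)) stop("part has nodes outside the node set")
    if (nrow(p$directed)) {
      dir_from <- c(dir_from, p$directed[, 1L])
      dir_to <- c(dir_to, p$directed[, 2L])
    }
    if (nrow(p$undirected)) und <- rbind(und, p$undirected)
  }
  directed <- unique(cbind(dir_from, dir_to, deparse.level = 0))
  conflicts <- character(0)
  if (nrow(directed)) {
    keys <- pair_key(directed)
    dup <- keys[duplicated(keys)]
    if (length(dup)) {                      # both directions seen: demote
      conflicts <- unique(dup)
      demote <- directed[keys %in% conflicts, , drop = FALSE]
      und <- rbind(und, demote)
      directed <- directed[!keys %in% conflicts, , drop = FALSE]
    }
  }
  # undirected loses to directed on the same pair
  if (nrow(und) && nrow(directed)) {
    und <- und[!pair_key(und) %in% pair_key(directed), , drop = FALSE]
  }
  # cycle repair: demote the most recent directed edge lying on a cycle
  while (nrow(directed) && !edges_acyclic(nodes, directed)) {
    demoted <- FALSE
    for (i in rev(seq_len(nrow(directed)))) {
      if (reachable(directed, directed[i, 2L], directed[i, 1L])) {
        conflicts <- c(conflicts, pair_key(directed[i, , drop = FALSE]))
        und <- rbind(und, directed[i, , drop = FALSE])
        directed <- directed[-i, , drop = FALSE]
        demoted <- TRUE
        break
      }
    }
    if (!demoted) break                     # defensive; cannot normally occur
  }
  out <- pdag(nodes, directed = directed, undirected = und)
  attr(out, "conflicts") <- unique(conflicts)
  out
}

# is `to` reachable from `from` along the directed edge list?
reachable <- function(edges, from, to) {
  frontier <- from
  seen <- character(0)
  while (length(frontier)) {
    v <- frontier[[1L]]; frontier <- frontier[-1L]
    if (v == to) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    frontier <- c(frontier, edges[edges[, 1L] == v, 2L])
  }
  FALSE
}

orient_skeleton_anm <- function(cdata, skeleton, cfg) {
  subs <- split_skeleton(skeleton)
  parts <- list(skeleton)
  for (sub in subs) {
    parts[[length(parts) + 1L]] <-
      orient_subskeleton(cdata, sub, alpha = cfg$alpha,
                         max_set = cfg$max_set,
                         n_permutations = cfg$n_permutations)
  }
  merge_pdags(parts, skeleton$nodes)
}

#' Run the full structure-learning pipeline
#'
#' Low-dimensional problems (fewer variables than \code{threshold_k}) are
#' solved whole: order search + K2 gives the skeleton; on continuous data
#' every sub-skeleton is then oriented by ANM fits and the partial PDAGs
#' merged, while on discrete data the directions of the K2 network itself
#' are returned (the ANM mechanism is a continuous-data device).
#' High-dimensional problems are split into per-node neighborhood blocks
#' around a provisional reduced-budget skeleton; each block is re-learned
#' and oriented, and the block PDAGs merged.
#'
#' @param data a \code{discrete_dataset} or \code{continuous_dataset}.
#' @param cfg a \code{\link{framework_config}}.
#' @return a \code{pdag} over the data columns.
#' @export
k2bso_run <- function(data, cfg = framework_config()) {
  continuous <- inherits(data, "continuous_dataset")
  ddata <- if (continuous) discretize_dataset(data, cfg$discretize_bins)
           else data
  n <- length(ddata$columns)
  with_seed_(cfg$seed, {
    cfg_inner <- cfg
    cfg_inner$seed <- NULL
    cfg_inner$bso$seed <- NULL
    if (n < cfg$threshold_k) {
      res <- learn_skeleton(ddata, cfg_inner)
      if (!continuous) return(dag_to_pdag(res$network))
      return(orient_skeleton_anm(data, res$skeleton, cfg_inner))
    }
    # split path: provisional skeleton from a reduced-budget pass
    cheap <- cfg_inner
    cheap$bso$pop_size <- max(cheap$bso$n_clusters, 10L)
    cheap$bso$max_iteration <- min(cheap$bso$max_iteration, 20L)
    prov <- learn_skeleton(ddata, cheap)$skeleton
    blocks <- lapply(split_skeleton(prov), function(s) {
      sort(unique(c(s$target, s$neighbors)))
    })
    blocks <- unique(blocks[vapply(blocks, length, 1L) >= 2L])
    parts <- list()
    for (bl in blocks) {
      sub_d <- discrete_dataset(ddata$values[, bl, drop = FALSE],
                                columns = bl,
                                cardinalities = ddata$cardinalities[bl])
      res <- learn_skeleton(sub_d, cfg_inner)
      parts[[length(parts) + 1L]] <-
        if (continuous) {
          sub_c <- continuous_dataset(data$values[, bl, drop = FALSE],
                                      columns = bl)
          orient_skeleton_anm(sub_c, res$skeleton, cfg_inner)
        } else {
          dag_to_pdag(res$network)
        }
    }
    merge_pdags(parts, ddata$columns)
  })
}
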