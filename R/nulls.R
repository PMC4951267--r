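#' Sample one random connected gene set
#'
#' Random-walk growth: a uniformly random start node, then repeated addition
#' of a uniformly chosen node from the current set's neighborhood until the
#' set has `m` genes. The scheme guarantees connectivity but is not uniform
#' over all connected subgraphs of size `m`; it matches common practice for
#' connected-subgraph nulls. Uses R's global RNG, so seed with
#' [set.seed()] for reproducibility. A start node whose component is too
#' small is discarded and redrawn.
#'
#' @param net a [gene_network] (or `weighted_network`) with a connected
#'   component of at least `m` nodes
#' @param m target set size
#' @param adj optional precomputed adjacency list
#' @return character vector of `m` genes forming a connected set
#' @export
sample_connected_gene_set <- function(net, m, adj = NULL) {
  if (inherits(net, "weighted_network")) {
    if (is.null(adj)) adj <- net$adj
    net <- net$network
  }
  if (is.null(adj)) adj <- adjacency_list(net)
  stopifnot(m >= 1)
  comp <- igraph::components(as_igraph(net))
  if (max(comp$csize) < m)
    stop("no connected component of size >= ", m)
  big <- net$nodes[comp$membership %in% which(comp$csize >= m)]
  start <- big[[sample.int(length(big), 1L)]]
  members <- start
  frontier <- setdiff(adj[[start]], members)
  while (length(members) < m) {
    g <- frontier[[sample.int(length(frontier), 1L)]]
    members <- c(members, g)
    frontier <- setdiff(unique(c(frontier, adj[[g]])), members)
  }
  members
}

#' Null distribution of module scores for size-matched random modules
#'
#' Samples `N` random connected gene sets of size `m` with
#' [sample_connected_gene_set()] and scores each with [module_score()].
#'
#' @param weights a [weight_network()] result
#' @param m module size to match
#' @param N number of null samples (default 10000)
#' @param rng_seed integer seed making the draw reproducible
#' @return object of class `null_distribution` with `module_size`, `scores`
#'   (length `N`), and `rng_seed`
#' @export
null_distribution <- function(weights, m, N = 10000, rng_seed = 1L) {
  stopifnot(N >= 1)
  set.seed(rng_seed)
  scores <- vapply(seq_len(N), function(i) {
    module_score(sample_connected_gene_set(weights, m), weights)
  }, numeric(1))
  structure(list(module_size = m, scores = scores, rng_seed = rng_seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("null_distribution: m =", x$module_size, ", N =", length(x$scores),
      ", score quantiles:\n")
  print(stats::quantile(x$scores, c(.05, .5, .95)))
  invisible(x)
}

#' Empirical p-value of an observed module score
#'
#' Add-one rule: `p = (1 + #\{null >= observed\}) / (1 + N)`, so `p` lies in
#' `(0, 1]` and finite resampling can never report zero.
#'
#' @param observed observed module score
#' @param null a [null_distribution()] (or bare numeric vector of null
#'   scores)
#' @return the empirical p-value
#' @export
empirical_p <- function(observed, null) {
  scores <- if (inherits(null, "null_distribution")) null$scores else null
  if (length(scores) == 0L) stop("empty null distribution")
  (1 + sum(scores >= observed)) / (1 + length(scores))
}
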