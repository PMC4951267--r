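#' Greedy module search parameters
#'
#' Defaults reproduce the method's stated settings: neighborhood distance
#' `d = 2`, improvement rate `r = 0.1`, 80% overlap merging.
#'
#' @param d nonnegative integer neighborhood distance
#' @param r_improve minimum fractional score gain for a greedy addition
#' @param overlap_threshold overlap fraction at or above which two modules
#'   merge, in (0, 1]
#' @param max_module_size safety bound on module size (warning when hit)
#' @param distance_mode `"module"` (distance measured from the growing
#'   module) or `"seed"` (distance measured from the seed gene, capping the
#'   module radius at `d`)
#' @return a `search_params` list
#' @export
search_params <- function(d = 2, r_improve = 0.1, overlap_threshold = 0.8,
                          max_module_size = 50,
                          distance_mode = c("module", "seed")) {
  stopifnot(d >= 0, r_improve >= 0,
            overlap_threshold > 0, overlap_threshold <= 1,
            max_module_size >= 1)
  structure(list(d = d, r_improve = r_improve,
                 overlap_threshold = overlap_threshold,
                 max_module_size = max_module_size,
                 distance_mode = match.arg(distance_mode)),
            class = "search_params")
}

induced_edge_keys <- function(genes, wn) {
  if (length(genes) < 2L) return(character())
  keys <- unlist(lapply(genes, function(g) {
    nb <- wn$adj[[g]]
    nb <- nb[nb > g]          # each unordered pair once
    nb <- nb[nb %in% genes]
    if (length(nb)) edge_key(g, nb) else character()
  }))
  if (is.null(keys)) character() else keys
}

#' Module score
#'
#' The score of a connected gene set `g = (V, E)`:
#' `S_g = (sum of gene weights z_v + sum of edge weights Delta_k) / (m + n)`,
#' where `m = |V|`, `n = |E|`, and `E` is the edge set induced on the genes
#' by the working network.
#'
#' @param genes nonempty character vector of member genes
#' @param weights a [weight_network()] result
#' @return the scalar score
#' @export
module_score <- function(genes, weights) {
  genes <- unique(genes)
  if (length(genes) == 0L) stop("empty gene set")
  if (!all(genes %in% weights$network$nodes))
    stop("genes not in weighted network: ",
         paste(setdiff(genes, weights$network$nodes), collapse = ", "))
  keys <- induced_edge_keys(genes, weights)
  (sum(weights$z[genes]) + sum(weights$delta[keys])) /
    (length(genes) + length(keys))
}

new_module <- function(seed, genes, wn, score, trace) {
  genes <- sort(unique(genes))
  keys <- induced_edge_keys(genes, wn)
  edges <- if (length(keys)) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    m <- cbind(from = vapply(parts, `[[`, character(1), 1L),
               to = vapply(parts, `[[`, character(1), 2L))
    m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  } else matrix(character(), ncol = 2L,
                dimnames = list(NULL, c("from", "to")))
  structure(list(seed = seed, genes = genes, edges = edges,
                 score = score, trace = trace),
            class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat("gene_module (seed ", x$seed, "): ", length(x$genes), " genes, ",
      nrow(x$edges), " edges, score ", format(x$score, digits = 5), "\n",
      sep = "")
  invisible(x)
}

#' Greedy expansion of one seeded module
#'
#' Starting from a single seed gene, iteratively adds the neighboring gene
#' (within network distance `d` of the seed or of the growing module per
#' `distance_mode`, and adjacent to the module so connectivity is kept) whose
#' addition maximizes the module score. An addition is accepted only if it
#' improves the score by more than the improvement rate: multiplicatively
#' (`new > old * (1 + r)`) while the current score is positive, additively
#' (`new > old + r`) otherwise, since a fractional improvement is undefined
#' at or below zero. Ties go to the lexicographically smallest gene. The
#' search stops when no addition qualifies or the size bound is hit.
#'
#' @param seed a gene in the weighted network
#' @param weights a [weight_network()] result
#' @param params a [search_params()] list
#' @return a `gene_module` with fields `seed`, `genes`, `edges`, `score`,
#'   and `trace` (data.frame of added gene and score after each addition,
#'   starting with the seed; scores strictly increasing)
#' @export
greedy_expand <- function(seed, weights, params = search_params()) {
  if (!seed %in% weights$network$nodes)
    stop("seed not in network: ", seed)
  allowed <- NULL                      # NULL = no distance restriction
  if (params$distance_mode == "seed")
    allowed <- nodes_within_distance(weights$network, seed, params$d)
  members <- seed
  sum_w <- unname(weights$z[seed])
  n_edges <- 0L
  score <- sum_w / 1
  trace <- list(list(gene = seed, score = score))
  frontier <- setdiff(weights$adj[[seed]], members)

  repeat {
    if (length(members) >= params$max_module_size) {
      warning("module hit max_module_size (", params$max_module_size,
              ") at seed ", seed)
      break
    }
    cand <- frontier
    if (params$d == 0) cand <- character()
    if (!is.null(allowed)) cand <- cand[cand %in% allowed]
    if (length(cand) == 0L) break
    cand <- sort(cand)
    new_scores <- vapply(cand, function(g) {
      nb <- weights$adj[[g]]
      nb <- nb[nb %in% members]
      (sum_w + weights$z[[g]] + sum(weights$delta[edge_key(g, nb)])) /
        (length(members) + 1L + n_edges + length(nb))
    }, numeric(1))
    best <- which.max(new_scores)     # ties: first of sorted = smallest gene
    new_score <- new_scores[[best]]
    ok <- if (score > 0) new_score > score * (1 + params$r_improve)
          else new_score > score + params$r_improve
    if (!ok || is.na(ok)) break
    g <- cand[[best]]
    nb <- weights$adj[[g]]
    nb_in <- nb[nb %in% members]
    sum_w <- sum_w + weights$z[[g]] + sum(weights$delta[edge_key(g, nb_in)])
    n_edges <- n_edges + length(nb_in)
    members <- c(members, g)
    score <- new_score
    trace[[length(trace) + 1L]] <- list(gene = g, score = score)
    frontier <- setdiff(unique(c(frontier, nb)), members)
  }

  trace_df <- data.frame(
    gene = vapply(trace, `[[`, character(1), "gene"),
    score = vapply(trace, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  new_module(seed, members, weights, score, trace_df)
}

#' Run the greedy search from every seed
#'
#' One [greedy_expand()] per network node, seeds taken in sorted order, so
#' repeated runs are byte-identical.
#'
#' @param weights a [weight_network()] result
#' @param params a [search_params()] list
#' @return list of `gene_module` objects, one per node
#' @export
search_all_seeds <- function(weights, params = search_params()) {
  seeds <- sort(weights$network$nodes)
  if (length(seeds) == 0L) stop("empty network")
  lapply(seeds, greedy_expand, weights = weights, params = params)
}

module_set_key <- function(mod) paste(mod$genes, collapse = "\r")

#' Merge overlapping modules
#'
#' While any pair of modules overlaps by at least `threshold` (overlap
#' measured as `|A intersect B| / min(|A|, |B|)`), the pair with the highest
#' overlap (ties broken lexicographically on the member gene sets) is
#' replaced by its union, with the union's score recomputed from the weight
#' tables (the score is not additive under union). Terminates at a fixpoint
#' where all pairs are below the threshold.
#'
#' @param modules list of `gene_module` objects
#' @param weights a [weight_network()] result
#' @param threshold overlap fraction in (0, 1]
#' @return list of merged `gene_module` objects (duplicated gene sets
#'   collapsed), sorted by seed
#' @export
merge_overlapping <- function(modules, weights, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  # collapse exact duplicates first
  keys <- vapply(modules, module_set_key, character(1))
  modules <- modules[!duplicated(keys)]
  repeat {
    k <- length(modules)
    if (k < 2L) break
    best <- NULL; best_ov <- -Inf
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      a <- modules[[i]]$genes; b <- modules[[j]]$genes
      ov <- length(intersect(a, b)) / min(length(a), length(b))
      if (ov > best_ov + 1e-15) {
        best_ov <- ov; best <- c(i, j)
      } else if (abs(ov - best_ov) <= 1e-15 && !is.null(best)) {
        # tie: lexicographically smallest pair of gene-set keys
        cur <- c(module_set_key(modules[[best[1L]]]),
                 module_set_key(modules[[best[2L]]]))
        new <- sort(c(module_set_key(modules[[i]]),
                      module_set_key(modules[[j]])))
        if (new[1L] < sort(cur)[1L] ||
            (new[1L] == sort(cur)[1L] && new[2L] < sort(cur)[2L]))
          best <- c(i, j)
      }
    }
    if (best_ov < threshold) break
    a <- modules[[best[1L]]]; b <- modules[[best[2L]]]
    genes <- union(a$genes, b$genes)
    merged <- new_module(min(a$seed, b$seed), genes, weights,
                         module_score(genes, weights), trace = NULL)
    modules <- c(modules[-best], list(merged))
    keys <- vapply(modules, module_set_key, character(1))
    modules <- modules[!duplicated(keys)]
  }
  modules[order(vapply(modules, `[[`, character(1), "seed"))]
}

#' Is a module's gene set connected in the working network?
#' @param genes character vector of genes
#' @param net a [gene_network]
#' @return logical
#' @export
is_connected_set <- function(genes, net) {
  if (length(genes) <= 1L) return(TRUE)
  sub_edges <- net$edges[net$edges[, 1L] %in% genes &
                           net$edges[, 2L] %in% genes, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    as.data.frame(sub_edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = genes))
  igraph::is_connected(g)
}
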