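#' Undirected gene interaction network
#'
#' A simple undirected graph over gene identifiers: no self-loops, no
#' duplicated edges, every edge endpoint a member of the node set. Direction
#' and interaction-type annotations in input files are discarded; node
#' identifiers are case-sensitive strings and no symbol aliasing is attempted.
#'
#' @param edges two-column character matrix or data.frame of endpoint pairs;
#'   self-loops are dropped and duplicates (regardless of endpoint order)
#'   collapsed, with a message giving the number of dropped records.
#' @param nodes optional character vector of additional (possibly isolated)
#'   nodes; endpoints are always included.
#' @return An object of class `gene_network` with elements `nodes` (sorted
#'   character vector) and `edges` (two-column character matrix, each row
#'   sorted, rows ordered lexicographically).
#' @export
gene_network <- function(edges = NULL, nodes = character()) {
  nodes <- as.character(nodes)
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(), ncol = 2L,
                 dimnames = list(NULL, c("from", "to")))
    return(new_gene_network(sort(unique(nodes)), em))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("edges must have two columns")
  a <- as.character(edges[, 1L]); b <- as.character(edges[, 2L])
  n_in <- length(a)
  keep <- a != b
  lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_drop <- (n_in - sum(keep)) + sum(dup)
  if (n_drop > 0L)
    message("gene_network: dropped ", n_drop,
            " self-loop/duplicate edge record(s)")
  lo <- lo[!dup]; hi <- hi[!dup]
  o <- order(lo, hi)
  em <- cbind(from = lo[o], to = hi[o])
  new_gene_network(sort(unique(c(nodes, a, b))), em)
}

new_gene_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Number of nodes and edges
#' @param net a `gene_network`
#' @return integer count
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Convert a gene_network to an igraph graph
#' @param net a `gene_network`
#' @return an undirected [igraph::igraph] graph
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}

#' Read an undirected edge list
#'
#' Reads a two-column tab-separated edge list or a SIF file (`node relation
#' node ...`; the relation field is ignored, and any targets beyond the first
#' each form an edge with the source). Self-loops and duplicate edges are
#' dropped with a message.
#'
#' @param path file path
#' @param format `"tsv"` (two tab-separated identifier columns) or `"sif"`
#' @param header for `"tsv"`, skip the first line
#' @return a [gene_network]
#' @export
read_edge_list <- function(path, format = c("tsv", "sif"), header = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "tsv" && header && length(lines) > 0L) lines <- lines[-1L]
  keep <- nzchar(trimws(lines))
  line_no <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("empty edge-list file: ", path)
    return(gene_network())
  }
  pairs <- vector("list", length(lines))
  singletons <- character()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    f <- if (grepl("\t", ln)) strsplit(ln, "\t", fixed = TRUE)[[1]]
         else strsplit(trimws(ln), "[[:space:]]+")[[1]]
    f <- f[nzchar(f)]
    if (format == "tsv") {
      if (length(f) < 2L)
        stop("malformed edge-list line ", line_no[i], ": ", ln)
      pairs[[i]] <- cbind(f[1L], f[2L])
    } else {
      if (length(f) == 1L) {
        singletons <- c(singletons, f)           # isolated node
      } else if (length(f) == 2L) {
        stop("malformed SIF line ", line_no[i],
             " (source + relation but no target): ", ln)
      } else {
        pairs[[i]] <- cbind(f[1L], f[3:length(f)])
      }
    }
  }
  gene_network(do.call(rbind, pairs), nodes = singletons)
}

#' Merge networks into one
#'
#' Union of node and edge sets; associative and commutative, idempotent.
#'
#' @param ... `gene_network` objects, or a single list of them
#' @return a [gene_network]
#' @export
merge_networks <- function(...) {
  nets <- list(...)
  if (length(nets) == 1L && !inherits(nets[[1L]], "gene_network"))
    nets <- nets[[1L]]
  if (length(nets) == 0L) stop("at least one network required")
  stopifnot(all(vapply(nets, inherits, logical(1), "gene_network")))
  gene_network(do.call(rbind, lapply(nets, `[[`, "edges")),
               nodes = unlist(lapply(nets, `[[`, "nodes")))
}

#' Largest connected component of an induced subgraph
#'
#' Induces the subgraph on `keep` (intersected with the network's nodes) and
#' returns its largest connected component; among equally large components the
#' one containing the lexicographically smallest node wins.
#'
#' @param net a `gene_network`
#' @param keep character vector of genes to retain
#' @return a [gene_network]
#' @export
induced_largest_component <- function(net, keep) {
  keep <- intersect(net$nodes, keep)
  if (length(keep) == 0L) {
    warning("no overlap between network nodes and `keep`; empty network")
    return(gene_network())
  }
  in_keep <- net$edges[, 1L] %in% keep & net$edges[, 2L] %in% keep
  sub <- gene_network(net$edges[in_keep, , drop = FALSE], nodes = keep)
  g <- as_igraph(sub)
  comp <- igraph::components(g)
  best_size <- max(comp$csize)
  cand <- which(comp$csize == best_size)
  if (length(cand) > 1L) {
    # tie: component containing the lexicographically smallest member node
    first_member <- vapply(cand, function(ci)
      min(sub$nodes[comp$membership == ci]), character(1))
    cand <- cand[order(first_member)[1L]]
  }
  members <- sub$nodes[comp$membership == cand[1L]]
  in_comp <- sub$edges[, 1L] %in% members
  gene_network(sub$edges[in_comp, , drop = FALSE], nodes = members)
}

#' Nodes within a network distance of a source set
#'
#' All nodes whose shortest-path distance to any source node is at most `d`
#' (the source nodes themselves included).
#'
#' @param net a `gene_network`
#' @param source character vector of source genes (must be network nodes)
#' @param d nonnegative integer distance bound
#' @return sorted character vector of gene identifiers
#' @export
nodes_within_distance <- function(net, source, d) {
  stopifnot(d >= 0)
  missing <- setdiff(source, net$nodes)
  if (length(missing) > 0L)
    stop("source genes not in network: ", paste(missing, collapse = ", "))
  if (d == 0) return(sort(unique(source)))
  g <- as_igraph(net)
  hits <- igraph::ego(g, order = d, nodes = source, mode = "all")
  sort(unique(c(source, unlist(lapply(hits, function(v) v$name)))))
}

#' Adjacency list of a network
#' @param net a `gene_network`
#' @return named list mapping each node to its sorted neighbor vector
#' @keywords internal
adjacency_list <- function(net) {
  adj <- vector("list", length(net$nodes))
  names(adj) <- net$nodes
  for (i in seq_along(adj)) adj[[i]] <- character()
  if (nrow(net$edges) > 0L) {
    sp1 <- split(net$edges[, 2L], net$edges[, 1L])
    sp2 <- split(net$edges[, 1L], net$edges[, 2L])
    for (nm in names(sp1)) adj[[nm]] <- c(adj[[nm]], sp1[[nm]])
    for (nm in names(sp2)) adj[[nm]] <- c(adj[[nm]], sp2[[nm]])
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  adj
}

edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Write a network as a two-column TSV edge list
#' @param net a `gene_network`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
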