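#' Univariate Cox p-value for one gene
#'
#' Two-sided Wald p-value for a single continuous expression covariate in a
#' proportional-hazards fit (Efron tie handling). The covariate is z-scored
#' first by default so hazard ratios are per standard deviation. Degenerate
#' inputs (constant expression, fewer than two events) give `p = 1` with a
#' flag instead of an error.
#'
#' @param expression numeric vector
#' @param time nonnegative survival times, aligned with `expression`
#' @param event 0/1 event indicators
#' @param standardize z-score the covariate before fitting
#' @return list with `p` (two-sided Wald), `coef` (log hazard ratio) and
#'   `flagged`
#' @export
cox_univariate_p <- function(expression, time, event, standardize = TRUE) {
  stopifnot(length(expression) == length(time),
            length(time) == length(event))
  if (sum(event) < 2 || stats::sd(expression) == 0)
    return(list(p = 1, coef = NA_real_, flagged = TRUE))
  x <- if (standardize) as.numeric(scale(expression)) else expression
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  s <- summary(fit)$coefficients
  list(p = unname(s[1, "Pr(>|z|)"]), coef = unname(s[1, "coef"]),
       flagged = FALSE)
}

#' Prognostic gene weight
#'
#' Inverse-normal transform of the Cox significance: `z = qnorm(1 - p)`, so
#' the weight grows as the survival association strengthens and is standard
#' normal under the null. `p` is clamped to `[1e-16, 1 - 1e-16]` to keep the
#' weight finite.
#'
#' @param p_i univariate Cox p-value(s)
#' @return numeric weight(s)
#' @export
gene_weight <- function(p_i) {
  p <- pmin(pmax(p_i, 1e-16), 1 - 1e-16)
  stats::qnorm(1 - p)
}

#' Fisher z transformation of a correlation
#'
#' `z = 0.5 * log((1 + r) / (1 - r))`, with `r` clamped to
#' `[-1 + 1e-15, 1 - 1e-15]`.
#'
#' @param r Pearson correlation(s)
#' @return transformed value(s)
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
}

#' Differential co-expression between two stages
#'
#' Absolute difference of the Fisher-transformed stage-wise correlations,
#' standardized by `sqrt(1/(n_p - 3) + 1/(n_c - 3))` — the standard
#' two-sample statistic for a difference of transformed correlations. Large
#' values mean a gene pair's co-regulation changed between stages; the
#' statistic is symmetric under exchanging the stages.
#'
#' @param r_prog,r_cancer Pearson correlations in the two stages
#' @param n_p,n_c stage sample sizes (each >= 4)
#' @return nonnegative differential co-expression weight(s)
#' @export
delta_coexpression <- function(r_prog, r_cancer, n_p, n_c) {
  if (n_p < 4) stop("progression stage too small (n_p = ", n_p, ", need >= 4)")
  if (n_c < 4) stop("cancer stage too small (n_c = ", n_c, ", need >= 4)")
  abs(fisher_z(r_prog) - fisher_z(r_cancer)) /
    sqrt(1 / (n_p - 3) + 1 / (n_c - 3))
}

#' Weight a network with prognostic and differential co-expression scores
#'
#' Every node receives the inverse-normal Cox weight computed on the cancer
#' samples' survival data; every edge receives the differential
#' co-expression weight contrasting correlations in the progression and
#' cancer stages.
#'
#' @param net a [gene_network] whose nodes all appear in the study's genes
#' @param study an [expression_study] with survival data on cancer samples
#' @param standardize z-score expression before the Cox fit
#' @return object of class `weighted_network`: the network plus
#'   `gene_weights` (gene, p, z, flagged), `edge_weights` (gene1, gene2,
#'   r_prog, r_cancer, z_prog, z_cancer, delta), sample counts `n_p`, `n_c`,
#'   and internal lookup tables used by the search
#' @export
weight_network <- function(net, study, standardize = TRUE) {
  missing <- setdiff(net$nodes, study$genes)
  if (length(missing) > 0L)
    stop("network genes missing from expression study: ",
         paste(missing, collapse = ", "))
  prog <- stage_samples(study, "progression")
  cans <- stage_samples(study, "cancer")
  surv_ok <- !is.na(study$meta$time) & !is.na(study$meta$event)
  surv_samples <- intersect(cans, study$meta$sample[surv_ok])
  if (length(surv_samples) < 2L)
    stop("cancer samples lack survival data")
  n_p <- length(prog); n_c <- length(cans)

  mm <- study$meta[match(surv_samples, study$meta$sample), ]
  gw <- lapply(net$nodes, function(g) {
    cox_univariate_p(study$values[g, surv_samples], mm$time, mm$event,
                     standardize = standardize)
  })
  p_i <- vapply(gw, `[[`, numeric(1), "p")
  gene_weights <- data.frame(
    gene = net$nodes, p = p_i, z = gene_weight(p_i),
    flagged = vapply(gw, `[[`, logical(1), "flagged"),
    stringsAsFactors = FALSE)

  e <- net$edges
  r_one <- function(cols) {
    if (nrow(e) == 0L) return(numeric())
    vapply(seq_len(nrow(e)), function(k)
      stats::cor(study$values[e[k, 1L], cols], study$values[e[k, 2L], cols]),
      numeric(1))
  }
  r_prog <- r_one(prog); r_cancer <- r_one(cans)
  edge_weights <- data.frame(
    gene1 = e[, 1L], gene2 = e[, 2L],
    r_prog = r_prog, r_cancer = r_cancer,
    z_prog = fisher_z(r_prog), z_cancer = fisher_z(r_cancer),
    delta = if (nrow(e) > 0L)
      delta_coexpression(r_prog, r_cancer, n_p, n_c) else numeric(),
    stringsAsFactors = FALSE)

  z_lookup <- stats::setNames(gene_weights$z, gene_weights$gene)
  delta_lookup <- stats::setNames(edge_weights$delta,
                                  edge_key(e[, 1L], e[, 2L]))
  structure(list(network = net,
                 gene_weights = gene_weights,
                 edge_weights = edge_weights,
                 n_p = n_p, n_c = n_c,
                 z = z_lookup, delta = delta_lookup,
                 adj = adjacency_list(net)),
            class = "weighted_network")
}

#' Construct a weighted network from explicit weight tables
#'
#' Wraps a network with user-supplied gene and edge weights, for workflows
#' where weights are precomputed (or, in tests, chosen directly).
#'
#' @param net a [gene_network]
#' @param gene_weights data.frame with columns `gene`, `z` (and optionally
#'   `p`); must cover every node
#' @param edge_weights data.frame with columns `gene1`, `gene2`, `delta`;
#'   must cover every edge
#' @param n_p,n_c stage sample sizes the edge weights were computed from
#'   (optional bookkeeping)
#' @return a `weighted_network`
#' @export
as_weighted_network <- function(net, gene_weights, edge_weights,
                                n_p = NA_integer_, n_c = NA_integer_) {
  stopifnot(all(c("gene", "z") %in% names(gene_weights)))
  if (!all(net$nodes %in% gene_weights$gene))
    stop("gene_weights must cover every node")
  if (nrow(net$edges) > 0L) {
    stopifnot(all(c("gene1", "gene2", "delta") %in% names(edge_weights)))
    have <- edge_key(edge_weights$gene1, edge_weights$gene2)
    need <- edge_key(net$edges[, 1L], net$edges[, 2L])
    if (!all(need %in% have)) stop("edge_weights must cover every edge")
    delta_lookup <- stats::setNames(edge_weights$delta, have)[need]
  } else {
    delta_lookup <- stats::setNames(numeric(), character())
  }
  gw <- gene_weights[match(net$nodes, gene_weights$gene), , drop = FALSE]
  structure(list(network = net, gene_weights = gw,
                 edge_weights = edge_weights,
                 n_p = n_p, n_c = n_c,
                 z = stats::setNames(gw$z, gw$gene),
                 delta = delta_lookup,
                 adj = adjacency_list(net)),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("weighted_network:", length(x$network$nodes), "nodes,",
      nrow(x$network$edges), "edges (n_p =", x$n_p,
      ", n_c =", x$n_c, ")\n")
  invisible(x)
}

#' Write a weighted network's node and edge tables as TSV
#' @param wn a `weighted_network`
#' @param node_path,edge_path output paths
#' @return invisibly, the two paths
#' @export
write_weight_tables <- function(wn, node_path, edge_path) {
  utils::write.table(wn$gene_weights, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(wn$edge_weights, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(nodes = node_path, edges = edge_path))
}
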