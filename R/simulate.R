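#' Configuration for the synthetic three-stage study generator
#'
#' Defaults mirror the scale of a staged carcinogenesis expression study:
#' 15 normal, 23 progression and 69 survival-annotated cancer samples, a
#' 22-gene planted module that is differentially expressed versus normal,
#' equicorrelated at `rho_P = 0.7` in the progression stage and fully
#' decorrelated (`rho_C = 0`) in the cancer stage, and survival generated
#' from an exponential proportional-hazards model with log hazard ratio
#' `ln 2` per standard deviation of the planted module's mean expression.
#'
#' @param n_genes number of genes / network nodes
#' @param n_normal,n_prog,n_cancer per-stage sample counts
#' @param planted_module_size number of planted genes
#' @param within_module_corr_prog,within_module_corr_cancer equicorrelation
#'   of planted genes in the progression / cancer stage, in \[0, 1)
#' @param deg_log2_effect mean log2 shift of planted genes in the
#'   progression and cancer stages (same direction in both, making them
#'   consistent DEGs by construction)
#' @param hazard_log_hr_per_sd log hazard ratio per SD of the planted
#'   module's mean expression
#' @param baseline_hazard exponential baseline hazard rate (events per time
#'   unit; default 0.02/month, median survival around 35 months)
#' @param censoring_rate target fraction of censored cancer samples, in
#'   \[0, 1)
#' @param network_model `"barabasi_albert"` (preferential attachment;
#'   `attach_param` = edges per new node) or `"erdos_renyi"`
#'   (`attach_param` = edge probability)
#' @param attach_param network model parameter, see `network_model`
#' @param rng_seed integer master seed; all generator randomness derives
#'   from it
#' @return a `sim_config` list
#' @export
sim_config <- function(n_genes = 300,
                       n_normal = 15, n_prog = 23, n_cancer = 69,
                       planted_module_size = 22,
                       within_module_corr_prog = 0.7,
                       within_module_corr_cancer = 0.0,
                       deg_log2_effect = 1.0,
                       hazard_log_hr_per_sd = log(2),
                       baseline_hazard = 0.02,
                       censoring_rate = 0.3,
                       network_model = c("barabasi_albert", "erdos_renyi"),
                       attach_param = 2,
                       rng_seed = 1L) {
  network_model <- match.arg(network_model)
  stopifnot(planted_module_size >= 2,
            planted_module_size <= n_genes,
            within_module_corr_prog >= 0, within_module_corr_prog < 1,
            within_module_corr_cancer >= 0, within_module_corr_cancer < 1,
            baseline_hazard > 0,
            censoring_rate >= 0, censoring_rate < 1,
            n_normal >= 2, n_prog >= 4, n_cancer >= 4)
  structure(list(n_genes = n_genes, n_normal = n_normal, n_prog = n_prog,
                 n_cancer = n_cancer,
                 planted_module_size = planted_module_size,
                 within_module_corr_prog = within_module_corr_prog,
                 within_module_corr_cancer = within_module_corr_cancer,
                 deg_log2_effect = deg_log2_effect,
                 hazard_log_hr_per_sd = hazard_log_hr_per_sd,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 network_model = network_model,
                 attach_param = attach_param,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

sim_gene_names <- function(n) sprintf("G%04d", seq_len(n))

#' Generate a synthetic interaction network with a planted connected module
#'
#' A connected background graph (preferential attachment or Erdos-Renyi made
#' connected) on `n_genes` nodes, with the planted genes additionally wired
#' as a random spanning tree plus extra random intra-module edges so the
#' planted module is guaranteed connected.
#'
#' @param config a [sim_config()]
#' @return a [gene_network] with attribute `planted_genes`
#' @export
generate_network <- function(config) {
  set.seed(config$rng_seed)
  n <- config$n_genes
  g <- if (config$network_model == "barabasi_albert") {
    igraph::sample_pa(n, m = config$attach_param, directed = FALSE)
  } else {
    igraph::sample_gnp(n, config$attach_param)
  }
  igraph::V(g)$name <- sim_gene_names(n)
  base_edges <- igraph::as_edgelist(g, names = TRUE)
  nodes <- sim_gene_names(n)
  # connect any stray components (Erdos-Renyi can be disconnected)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    anchor <- nodes[comp$membership == which.max(comp$csize)][1L]
    extra <- vapply(setdiff(seq_len(comp$no), which.max(comp$csize)),
                    function(ci) nodes[comp$membership == ci][1L],
                    character(1))
    base_edges <- rbind(base_edges, cbind(extra, anchor))
  }
  planted <- sort(sample(nodes, config$planted_module_size))
  # random spanning tree over planted genes
  perm <- sample(planted)
  tree <- cbind(perm[-1L],
                vapply(seq.int(2L, length(perm)), function(i)
                  perm[sample.int(i - 1L, 1L)], character(1)))
  # extra random intra-module pairs (about one per planted gene)
  k <- length(planted)
  pairs <- t(utils::combn(planted, 2L))
  extra_idx <- sample.int(nrow(pairs), min(nrow(pairs), k))
  net <- gene_network(rbind(base_edges, tree, pairs[extra_idx, ]),
                      nodes = nodes)
  attr(net, "planted_genes") <- planted
  net
}

equicorr_block <- function(n_genes, n_samples, rho) {
  shared <- matrix(rep(stats::rnorm(n_samples), each = n_genes),
                   nrow = n_genes)
  noise <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes)
  sqrt(rho) * shared + sqrt(1 - rho) * noise
}

#' Generate synthetic staged expression data
#'
#' Background genes are i.i.d. standard normal in every stage. Planted genes
#' are equicorrelated Gaussian blocks (`rho_P` in progression, `rho_C` in
#' cancer, independent in normal) with their means shifted by
#' `deg_log2_effect` in the progression and cancer stages, so they are
#' consistent DEGs by construction. Clinical covariates `age` and `sex`
#' (independent of everything else) are attached to cancer samples so
#' multivariate survival machinery can be exercised.
#'
#' @param config a [sim_config()]
#' @param net a network from [generate_network()] (carries the planted
#'   gene set)
#' @return an [expression_study] with attribute `planted_genes`; survival
#'   columns still empty (see [generate_survival()])
#' @export
generate_expression <- function(config, net) {
  planted <- attr(net, "planted_genes")
  if (is.null(planted)) stop("network carries no planted_genes attribute")
  set.seed(config$rng_seed + 1L)
  genes <- net$nodes
  ns <- c(normal = config$n_normal, progression = config$n_prog,
          cancer = config$n_cancer)
  samples <- c(sprintf("N%03d", seq_len(ns[["normal"]])),
               sprintf("P%03d", seq_len(ns[["progression"]])),
               sprintf("C%03d", seq_len(ns[["cancer"]])))
  stage <- rep(names(ns), ns)
  values <- matrix(stats::rnorm(length(genes) * length(samples)),
                   nrow = length(genes),
                   dimnames = list(genes, samples))
  p_idx <- match(planted, genes)
  rho <- c(normal = 0, progression = config$within_module_corr_prog,
           cancer = config$within_module_corr_cancer)
  for (st in names(ns)) {
    cols <- stage == st
    values[p_idx, cols] <- equicorr_block(length(p_idx), sum(cols), rho[[st]])
    if (st != "normal")
      values[p_idx, cols] <- values[p_idx, cols] + config$deg_log2_effect
  }
  meta <- data.frame(sample = samples, stage = stage,
                     time = NA_real_, event = NA_integer_,
                     age = NA_real_, sex = NA_character_,
                     stringsAsFactors = FALSE)
  cc <- stage == "cancer"
  meta$age[cc] <- round(stats::rnorm(sum(cc), 65, 8), 1)
  meta$sex[cc] <- sample(c("female", "male"), sum(cc), replace = TRUE)
  study <- expression_study(values, meta)
  attr(study, "planted_genes") <- planted
  study
}

#' Generate survival outcomes for the cancer samples
#'
#' Event times follow an exponential proportional-hazards model with linear
#' predictor `beta * standardized planted-module mean expression`; censoring
#' is independent uniform on `(0, c_max)` with `c_max` tuned numerically so
#' the expected censored fraction matches `censoring_rate`.
#'
#' @param config a [sim_config()]
#' @param study study from [generate_expression()] (carries the planted
#'   gene set)
#' @param planted_genes override for the planted gene set
#' @return the study with `time` and `event` filled in for cancer samples
#' @export
generate_survival <- function(config, study,
                              planted_genes = attr(study, "planted_genes")) {
  if (is.null(planted_genes)) stop("planted gene set unknown")
  set.seed(config$rng_seed + 2L)
  cc <- study$meta$stage == "cancer"
  if (!any(cc)) stop("no cancer samples")
  lp <- config$hazard_log_hr_per_sd *
    as.numeric(scale(colMeans(study$values[planted_genes, cc, drop = FALSE])))
  h <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(sum(cc), rate = h)
  if (config$censoring_rate == 0) {
    time <- t_event; event <- rep(1L, sum(cc))
  } else {
    # P(censor) under C ~ U(0, cm): mean_i [(1 - exp(-h_i cm)) / (h_i cm)]
    cens_frac <- function(cm) mean((1 - exp(-h * cm)) / (h * cm))
    cm <- stats::uniroot(function(cm) cens_frac(cm) - config$censoring_rate,
                         lower = 1e-9 / config$baseline_hazard,
                         upper = 1e9 / config$baseline_hazard,
                         tol = 1e-10)$root
    t_cens <- stats::runif(sum(cc), 0, cm)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  study$meta$time[cc] <- time
  study$meta$event[cc] <- event
  study
}

#' Generate a complete synthetic study
#'
#' Network, staged expression, and survival in one call; fully deterministic
#' given the config's `rng_seed`.
#'
#' @param config a [sim_config()]
#' @return list of class `sim_study`: `study` ([expression_study]),
#'   `network` ([gene_network]), `truth` (planted genes + config)
#' @export
simulate_study <- function(config = sim_config()) {
  net <- generate_network(config)
  study <- generate_expression(config, net)
  study <- generate_survival(config, study)
  structure(list(study = study, network = net,
                 truth = list(planted_genes = attr(net, "planted_genes"),
                              config = config)),
            class = "sim_study")
}

#' Write a simulated study to disk
#'
#' Emits the standard expression TSV + metadata TSV + edge-list TSV, plus a
#' ground-truth JSON (planted genes and generator parameters) for test
#' harnesses.
#'
#' @param sim a [simulate_study()] result
#' @param dir output directory (created if needed)
#' @return invisibly, named vector of the four paths
#' @export
write_sim_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expr = file.path(dir, "expression.tsv"),
             meta = file.path(dir, "metadata.tsv"),
             network = file.path(dir, "network.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression_study(sim$study, paths[["expr"]], paths[["meta"]])
  write_edge_list(sim$network, paths[["network"]])
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
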