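#' Pipeline parameter defaults
#'
#' @param fdr_threshold,fc_threshold DEG gates
#' @param d,r_improve,overlap_threshold,distance_mode,max_module_size greedy
#'   search settings (see [search_params()])
#' @param alpha_null empirical-p screen threshold (default 0.1)
#' @param alpha_os training-cohort overall-survival screen threshold
#'   (default 0.1)
#' @param null_n null samples per module size
#' @param null_seed integer seed for the null sampler
#' @param restrict_up,restrict_down optional gene lists intersected with the
#'   consistent up-/down-regulated DEGs before network projection (stands in
#'   for externally curated functional gene sets); `NULL` keeps all
#'   consistent DEGs
#' @param split eigengene split rule, `"median"` or `"sign"`
#' @return a `pipeline_params` list
#' @export
pipeline_params <- function(fdr_threshold = 0.01, fc_threshold = 1.5,
                            d = 2, r_improve = 0.1, overlap_threshold = 0.8,
                            distance_mode = "module", max_module_size = 50,
                            alpha_null = 0.1, alpha_os = 0.1,
                            null_n = 1000, null_seed = 1L,
                            restrict_up = NULL, restrict_down = NULL,
                            split = "median") {
  structure(list(fdr_threshold = fdr_threshold, fc_threshold = fc_threshold,
                 d = d, r_improve = r_improve,
                 overlap_threshold = overlap_threshold,
                 distance_mode = distance_mode,
                 max_module_size = max_module_size,
                 alpha_null = alpha_null, alpha_os = alpha_os,
                 null_n = null_n, null_seed = as.integer(null_seed),
                 restrict_up = restrict_up, restrict_down = restrict_down,
                 split = split),
            class = "pipeline_params")
}

# small deterministic polynomial hash of a deparsed object, for provenance
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the module-discovery pipeline end to end
#'
#' Differential expression (progression-vs-normal and cancer-vs-normal) ->
#' consistent DEGs -> projection onto the interaction network and largest
#' connected component -> gene/edge weighting -> seeded greedy search ->
#' overlap merging -> size-matched random-connected-module null screen ->
#' eigengene log-rank screen on the training cohort -> report.
#'
#' @param study an [expression_study] with all three stages and survival on
#'   cancer samples
#' @param network a [gene_network]
#' @param params a [pipeline_params()] list
#' @param out_dir optional directory; when given, every intermediate (DEG
#'   tables, consistent gene sets, working subnetwork, weight tables,
#'   modules, null scores, report JSON) is persisted there
#' @return object of class `pipeline_report`: `counts`, `modules`
#'   (data.frame: module_id, seed, n_genes, n_edges, score, empirical_p,
#'   os_logrank_p, pass_null, pass_os, genes), `module_objects`,
#'   `provenance`
#' @export
run_pipeline <- function(study, network, params = pipeline_params(),
                         out_dir = NULL) {
  persist <- !is.null(out_dir)
  if (persist) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_tsv <- function(x, name) if (persist)
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  deg_prog <- call_degs(study, "progression", "normal",
                        params$fdr_threshold, params$fc_threshold)
  deg_cancer <- call_degs(study, "cancer", "normal",
                          params$fdr_threshold, params$fc_threshold)
  save_tsv(deg_prog, "degs_progression.tsv")
  save_tsv(deg_cancer, "degs_cancer.tsv")
  cons <- consistent_degs(deg_prog, deg_cancer)
  if (!is.null(params$restrict_up))
    cons$up <- intersect(cons$up, params$restrict_up)
  if (!is.null(params$restrict_down))
    cons$down <- intersect(cons$down, params$restrict_down)
  keep <- c(cons$up, cons$down)
  save_tsv(data.frame(gene = keep,
                      direction = rep(c("up", "down"),
                                      c(length(cons$up), length(cons$down)))),
           "consistent_degs.tsv")
  lcc <- if (length(keep) > 0L) {
    suppressWarnings(induced_largest_component(network, keep))
  } else {
    gene_network()
  }
  if (persist) write_edge_list(lcc, file.path(out_dir, "lcc_edges.tsv"))
  # a weak study can leave no workable subnetwork; that is an empty result,
  # not an invalid input
  degenerate <- n_nodes(lcc) == 0L
  if (degenerate)
    warning("pipeline: no consistent DEGs land in the network; ",
            "reporting zero modules")
  if (!degenerate) {
    wn <- weight_network(lcc, study)
    if (persist) write_weight_tables(wn,
                                     file.path(out_dir, "gene_weights.tsv"),
                                     file.path(out_dir, "edge_weights.tsv"))
    sp <- search_params(d = params$d, r_improve = params$r_improve,
                        overlap_threshold = params$overlap_threshold,
                        max_module_size = params$max_module_size,
                        distance_mode = params$distance_mode)
    raw <- search_all_seeds(wn, sp)
    merged <- merge_overlapping(raw, wn, params$overlap_threshold)
  } else {
    raw <- list()
    merged <- list()
  }

  sizes <- sort(unique(vapply(merged, function(m) length(m$genes),
                              integer(1))))
  nulls <- lapply(sizes, function(m)
    null_distribution(wn, m, N = params$null_n,
                      rng_seed = params$null_seed + m))
  names(nulls) <- as.character(sizes)
  if (persist && length(nulls) > 0L) {
    null_tab <- do.call(rbind, lapply(nulls, function(nd)
      data.frame(m = nd$module_size, score = nd$scores)))
    save_tsv(null_tab, "null_scores.tsv")
  }

  emp_p <- vapply(merged, function(mod)
    empirical_p(mod$score, nulls[[as.character(length(mod$genes))]]),
    numeric(1))
  pass_null <- emp_p < params$alpha_null

  os_p <- rep(NA_real_, length(merged))
  for (i in which(pass_null)) {
    ms <- module_survival(merged[[i]], study, split = params$split)
    os_p[i] <- if (is.null(ms)) NA_real_ else ms$logrank$p
  }
  pass_os <- pass_null & !is.na(os_p) & os_p < params$alpha_os

  mod_tab <- data.frame(
    module_id = sprintf("M%03d", seq_along(merged)),
    seed = vapply(merged, `[[`, character(1), "seed"),
    n_genes = vapply(merged, function(m) length(m$genes), integer(1)),
    n_edges = vapply(merged, function(m) nrow(m$edges), integer(1)),
    score = vapply(merged, `[[`, numeric(1), "score"),
    empirical_p = emp_p,
    os_logrank_p = os_p,
    pass_null = pass_null,
    pass_os = pass_os,
    genes = vapply(merged, function(m) paste(m$genes, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE)
  save_tsv(mod_tab, "modules.tsv")

  report <- structure(list(
    counts = list(
      degs_prog_up = sum(deg_prog$direction == "up"),
      degs_prog_down = sum(deg_prog$direction == "down"),
      degs_cancer_up = sum(deg_cancer$direction == "up"),
      degs_cancer_down = sum(deg_cancer$direction == "down"),
      consistent_up = length(cons$up),
      consistent_down = length(cons$down),
      lcc_nodes = n_nodes(lcc),
      lcc_edges = n_edges(lcc),
      modules_found = length(raw),
      modules_after_merge = length(merged),
      modules_passing_null = sum(pass_null),
      modules_passing_os = sum(pass_os)),
    modules = mod_tab,
    module_objects = merged,
    consistent = cons,
    provenance = list(
      params = unclass(params),
      config_hash = config_hash(unclass(params)),
      null_seed = params$null_seed,
      package_version = as.character(utils::packageVersion("progmodnet")))),
    class = "pipeline_report")
  if (persist)
    write_report_json(report, file.path(out_dir, "report.json"))
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  for (nm in names(x$counts)) cat("  ", nm, ": ", x$counts[[nm]], "\n",
                                  sep = "")
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Deterministic serialization (fixed 10 significant digits), so identical
#' configurations and seeds give byte-identical report files.
#'
#' @param report a `pipeline_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report_json <- function(report, path) {
  out <- list(counts = report$counts,
              modules = report$modules,
              provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(10),
                       na = "null")
  invisible(path)
}

#' Evaluate modules on an independent cohort
#'
#' For each module: drop genes absent from the cohort (skipping, with a
#' warning, modules that lose more than half their genes), compute the
#' eigengene over the cohort's cancer samples, median-split, and run the
#' log-rank test and (when covariates are given) the stepwise Cox analysis.
#'
#' @param modules list of `gene_module` objects (or character gene vectors)
#' @param cohort an [expression_study] with survival data
#' @param covariate_terms optional metadata columns for the stepwise Cox fit
#' @param split eigengene split rule
#' @return named list of [module_survival()] results (NULL entries for
#'   skipped modules)
#' @export
evaluate_on_cohort <- function(modules, cohort, covariate_terms = NULL,
                               split = "median") {
  if (inherits(modules, "gene_module")) modules <- list(modules)
  res <- lapply(modules, function(mod)
    module_survival(mod, cohort, covariate_terms = covariate_terms,
                    split = split))
  names(res) <- vapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    if (inherits(m, "gene_module")) paste0("seed_", m$seed)
    else sprintf("module_%d", i)
  }, character(1))
  res
}
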