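#' Two-sample t test for one gene
#'
#' Welch's unequal-variance form by default; the pooled-variance Student form
#' is available via `var_equal`. Degenerate inputs (both groups with zero
#' variance) yield `t = 0`, `p = 1` with a flag rather than an error, so
#' whole-matrix scans survive flat genes.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2)
#' @param var_equal use the pooled-variance form
#' @return list with `t_stat` (sign of `mean(a) - mean(b)`), `p_value`
#'   (two-sided) and `flagged` (degenerate-variance indicator)
#' @export
welch_t_test <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0)
    return(list(t_stat = 0, p_value = 1, flagged = TRUE))
  fit <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t_stat = unname(fit$statistic), p_value = fit$p.value,
       flagged = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; input order is preserved and the adjusted values
#' are monotone nondecreasing in p-value rank.
#'
#' @param p_values numeric vector of p-values in \[0, 1\]
#' @return numeric vector of adjusted values, same order as input
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes between two stages
#'
#' Per-gene two-sample t test between two stages, BH-adjusted, with a gene
#' called `up`/`down` only when both the FDR gate and the fold-change gate
#' pass. Data are log2, so "fold change > `fc_threshold`" is evaluated as
#' `|mean_a - mean_b| > log2(fc_threshold)` (the anti-logged group-mean
#' difference).
#'
#' @param study an [expression_study]
#' @param group_a,group_b stage labels; `log2_fc = mean(group_a) -
#'   mean(group_b)`, so direction `up` means higher in `group_a`
#' @param fdr_threshold FDR gate (default 0.01)
#' @param fc_threshold fold-change gate on the anti-logged scale (default 1.5)
#' @param var_equal passed to [welch_t_test()]
#' @return data.frame with columns `gene`, `t_stat`, `p_value`, `fdr`,
#'   `log2_fc`, `direction` (`up`/`down`/`ns`), `flagged`; one row per gene
#'   in the study's gene order
#' @export
call_degs <- function(study, group_a, group_b,
                      fdr_threshold = 0.01, fc_threshold = 1.5,
                      var_equal = FALSE) {
  for (g in c(group_a, group_b)) {
    n <- sum(study$meta$stage == g)
    if (n < 2L) stop("stage `", g, "` has ", n, " samples (need >= 2)")
  }
  ia <- study$meta$stage == group_a
  ib <- study$meta$stage == group_b
  res <- lapply(seq_along(study$genes), function(i) {
    welch_t_test(study$values[i, ia], study$values[i, ib],
                 var_equal = var_equal)
  })
  t_stat <- vapply(res, `[[`, numeric(1), "t_stat")
  p_value <- vapply(res, `[[`, numeric(1), "p_value")
  flagged <- vapply(res, `[[`, logical(1), "flagged")
  log2_fc <- rowMeans(study$values[, ia, drop = FALSE]) -
    rowMeans(study$values[, ib, drop = FALSE])
  fdr <- bh_fdr(p_value)
  sig <- fdr < fdr_threshold & abs(log2_fc) > log2(fc_threshold)
  direction <- ifelse(!sig, "ns", ifelse(log2_fc > 0, "up", "down"))
  data.frame(gene = study$genes, t_stat = t_stat, p_value = p_value,
             fdr = fdr, log2_fc = unname(log2_fc), direction = direction,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Consistent DEGs across two contrasts
#'
#' Genes called in the same direction in both contrasts (each versus normal):
#' the paper's "consistent DEG" notion.
#'
#' @param prog_table,cancer_table DEG tables from [call_degs()] over the same
#'   gene universe
#' @return list with character-vector elements `up` and `down` (disjoint)
#' @export
consistent_degs <- function(prog_table, cancer_table) {
  if (!setequal(prog_table$gene, cancer_table$gene)) {
    nd <- length(union(setdiff(prog_table$gene, cancer_table$gene),
                       setdiff(cancer_table$gene, prog_table$gene)))
    stop("gene universes differ (symmetric difference: ", nd, " genes)")
  }
  up <- intersect(prog_table$gene[prog_table$direction == "up"],
                  cancer_table$gene[cancer_table$direction == "up"])
  down <- intersect(prog_table$gene[prog_table$direction == "down"],
                    cancer_table$gene[cancer_table$direction == "down"])
  list(up = sort(up), down = sort(down))
}
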