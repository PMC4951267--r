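#' Staged expression study with survival metadata
#'
#' The pipeline's main input: a genes x samples matrix of log2 expression
#' values plus per-sample metadata assigning each sample a stage label
#' (`normal`, `progression`, `cancer`) and, for cancer samples, overall
#' survival time, an event indicator, and optional covariates.
#'
#' @param values numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers)
#' @param meta data.frame with one row per sample: columns `sample`, `stage`,
#'   and optionally `time`, `event` plus free covariate columns. Row order
#'   must cover exactly the matrix columns.
#' @return an object of class `expression_study` with elements `genes`,
#'   `samples`, `values`, `meta`
#' @export
expression_study <- function(values, meta) {
  stopifnot(is.matrix(values), is.numeric(values))
  genes <- rownames(values); samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(genes)) stop("duplicated gene identifiers")
  if (anyDuplicated(samples)) stop("duplicated sample identifiers")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!all(c("sample", "stage") %in% names(meta)))
    stop("metadata must have `sample` and `stage` columns")
  if (!setequal(meta$sample, samples))
    stop("metadata samples do not match expression columns")
  meta <- meta[match(samples, meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  bad <- setdiff(unique(meta$stage), c("normal", "progression", "cancer"))
  if (length(bad) > 0L)
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  if (!"time" %in% names(meta)) meta$time <- NA_real_
  if (!"event" %in% names(meta)) meta$event <- NA_integer_
  structure(list(genes = genes, samples = samples,
                 values = values, meta = meta),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", length(x$genes), "genes x",
      length(x$samples), "samples\n")
  print(table(x$meta$stage))
  invisible(x)
}

#' Samples belonging to a stage
#' @param study an `expression_study`
#' @param stage one of `"normal"`, `"progression"`, `"cancer"`
#' @return character vector of sample identifiers
#' @export
stage_samples <- function(study, stage) {
  study$samples[study$meta$stage == stage]
}

#' Read an expression study from TSV files
#'
#' The expression table has gene identifiers in the first column and one
#' column per sample; the metadata table is keyed by sample identifier with
#' columns `stage`, `time`, `event` and free covariate columns.
#'
#' @param expr_path expression TSV path
#' @param meta_path metadata TSV path
#' @return an [expression_study]
#' @export
read_expression_study <- function(expr_path, meta_path) {
  expr <- utils::read.delim(expr_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  values <- as.matrix(expr[, -1L, drop = FALSE])
  rownames(values) <- as.character(expr[[1L]])
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!"sample" %in% names(meta)) names(meta)[1L] <- "sample"
  meta$sample <- as.character(meta$sample)
  expression_study(values, meta)
}

#' Write an expression study to TSV files
#' @param study an `expression_study`
#' @param expr_path,meta_path output paths
#' @return invisibly, a list of the two paths
#' @export
write_expression_study <- function(study, expr_path, meta_path) {
  expr <- data.frame(gene = study$genes, study$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(expr, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(expr = expr_path, meta = meta_path))
}
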