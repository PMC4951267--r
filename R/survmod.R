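#' Module eigengene and patient stratification
#'
#' First principal component of the module's expression submatrix across
#' patients, after standardizing each gene row. The component's sign is
#' chosen so it correlates positively with the mean standardized module
#' expression, and patients are split into two groups: at the eigengene
#' median (ties to `low`; balanced groups) or by the sign of the eigengene.
#'
#' @param module_expr numeric matrix, module genes x samples (>= 2 genes,
#'   >= 3 samples, no constant gene row)
#' @param split `"median"` or `"sign"`
#' @return object of class `eigengene_result`: `em` (named per-sample
#'   scores, unit norm), `orientation_sign` (+1/-1), `group` (named factor
#'   `high`/`low`), `var_explained`
#' @export
eigengene <- function(module_expr, split = c("median", "sign")) {
  split <- match.arg(split)
  stopifnot(is.matrix(module_expr))
  if (nrow(module_expr) < 2L) stop("need >= 2 module genes")
  if (ncol(module_expr) < 3L) stop("need >= 3 samples")
  sds <- apply(module_expr, 1L, stats::sd)
  if (any(sds == 0)) stop("constant gene row(s): ",
                          paste(rownames(module_expr)[sds == 0],
                                collapse = ", "))
  xs <- (module_expr - rowMeans(module_expr)) / sds
  sv <- svd(xs)
  em <- sv$v[, 1L]
  sign <- 1
  avg <- colMeans(xs)
  ccor <- stats::cor(em, avg)
  if (!is.na(ccor) && ccor < 0) { em <- -em; sign <- -1 }
  names(em) <- colnames(module_expr)
  grp <- if (split == "median") {
    ifelse(em > stats::median(em), "high", "low")
  } else {
    ifelse(em > 0, "high", "low")
  }
  structure(list(em = em, orientation_sign = sign,
                 group = factor(grp, levels = c("low", "high")),
                 var_explained = sv$d[1L]^2 / sum(sv$d^2)),
            class = "eigengene_result")
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square (1 df).
#'
#' @param time survival times
#' @param event 0/1 event indicators
#' @param group two-level grouping, aligned with `time`
#' @return list with `chi2` and `p`
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("log-rank test needs exactly two groups, got ",
         nlevels(droplevels(group)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Kaplan-Meier curves as a step-function table
#'
#' @inheritParams logrank_test
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `surv`, `lower`, `upper`
#' @export
km_curves <- function(time, event, group) {
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = data.frame(time, event, group))
  strata <- rep(names(fit$strata), fit$strata)
  data.frame(group = sub("^group=", "", strata),
             time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv, lower = fit$lower, upper = fit$upper,
             stringsAsFactors = FALSE)
}

#' Cox proportional-hazards fit with a tidy coefficient table
#'
#' Partial-likelihood fit with Efron tie handling; Wald confidence
#' intervals and p-values per coefficient.
#'
#' @param covariates data.frame of covariates
#' @param time,event survival outcome, aligned with `covariates` rows
#' @param terms character vector of column names to include
#' @return data.frame with columns `term`, `coef`, `hr`, `ci_low`,
#'   `ci_high`, `p`
#' @export
cox_fit <- function(covariates, time, event, terms) {
  stopifnot(length(terms) >= 1L, all(terms %in% names(covariates)))
  if (sum(event) < 2) stop("need >= 2 events")
  df <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (any(!is.finite(stats::coef(fit))) || any(abs(stats::coef(fit)) > 50))
    stop("Cox fit did not converge; coefficients: ",
         paste(format(stats::coef(fit), digits = 3), collapse = ", "))
  s <- summary(fit)
  data.frame(term = rownames(s$coefficients),
             coef = unname(s$coefficients[, "coef"]),
             hr = unname(s$conf.int[, "exp(coef)"]),
             ci_low = unname(s$conf.int[, "lower .95"]),
             ci_high = unname(s$conf.int[, "upper .95"]),
             p = unname(s$coefficients[, "Pr(>|z|)"]),
             stringsAsFactors = FALSE)
}

#' Stepwise Cox analysis of a module's eigengene group and clinical terms
#'
#' Each candidate clinical term is first screened univariately (whole-term
#' likelihood-ratio p from its single-term Cox model); terms passing
#' `alpha_in` enter the multivariate fit alongside the eigengene group. Both
#' the univariate and multivariate coefficient tables are returned.
#'
#' @param covariates data.frame containing the candidate terms
#' @param time,event survival outcome
#' @param candidate_terms character vector of clinical covariate columns
#' @param em_group two-level factor from [eigengene()]
#' @param alpha_in univariate entry threshold (default 0.05)
#' @return list with `univariate` (per-term screen: term, p, plus per-
#'   coefficient rows), `selected` terms, and `multivariate` table
#' @export
stepwise_cox <- function(covariates, time, event, candidate_terms,
                         em_group, alpha_in = 0.05) {
  covariates <- as.data.frame(covariates)
  covariates$em_group <- em_group
  all_terms <- c(candidate_terms, "em_group")
  uni_p <- vapply(all_terms, function(tm) {
    df <- cbind(data.frame(.time = time, .event = event), covariates)
    fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", tm))
    fit <- survival::coxph(fml, data = df, ties = "efron")
    unname(summary(fit)$logtest["pvalue"])
  }, numeric(1))
  uni_tables <- do.call(rbind, lapply(all_terms, function(tm) {
    tab <- cox_fit(covariates, time, event, tm)
    tab$screen_term <- tm
    tab$screen_p <- uni_p[[tm]]
    tab
  }))
  selected <- candidate_terms[uni_p[candidate_terms] < alpha_in]
  multi <- cox_fit(covariates, time, event, c(selected, "em_group"))
  list(univariate = uni_tables, selected = selected, multivariate = multi)
}

#' Pool per-cohort effects with fixed- and random-effect models
#'
#' Fixed effect: inverse-variance weighted mean. Random effect:
#' DerSimonian-Laird, with the tau^2 moment estimator truncated at zero
#' (so homogeneous cohorts reduce the random-effect model to the fixed one).
#'
#' @param log_hr per-cohort log hazard ratios (>= 2 cohorts)
#' @param variance per-cohort sampling variances (positive)
#' @return object of class `meta_pooled`: `fixed` and `random` (each a list
#'   with `log_hr`, `se`, `ci_low`, `ci_high`, `p` on the log scale),
#'   `tau2`, `Q`, `k`
#' @export
pool_effects <- function(log_hr, variance) {
  stopifnot(length(log_hr) == length(variance), length(log_hr) >= 2L,
            all(variance > 0))
  k <- length(log_hr)
  one <- function(th, se) {
    z <- th / se
    list(log_hr = th, se = se,
         ci_low = th - stats::qnorm(0.975) * se,
         ci_high = th + stats::qnorm(0.975) * se,
         p = 2 * stats::pnorm(-abs(z)))
  }
  w <- 1 / variance
  th_f <- sum(w * log_hr) / sum(w)
  Q <- sum(w * (log_hr - th_f)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (variance + tau2)
  th_r <- sum(wr * log_hr) / sum(wr)
  structure(list(fixed = one(th_f, sqrt(1 / sum(w))),
                 random = one(th_r, sqrt(1 / sum(wr))),
                 tau2 = tau2, Q = Q, k = k),
            class = "meta_pooled")
}

#' Eigengene-based survival analysis of one module in one cohort
#'
#' Summarizes the module by its eigengene over the cohort's cancer samples
#' with survival data, stratifies patients, and runs the log-rank test (and,
#' when clinical covariates are supplied, the stepwise Cox analysis). Module
#' genes absent from the cohort are dropped; the module is skipped with a
#' warning if more than half its genes are missing.
#'
#' @param module a `gene_module` (or bare character vector of genes)
#' @param study an [expression_study] whose cancer samples carry survival
#'   data
#' @param covariate_terms optional character vector of metadata columns to
#'   screen in the stepwise Cox fit
#' @param split passed to [eigengene()]
#' @param min_gene_fraction skip threshold on the fraction of module genes
#'   present (default 0.5)
#' @return object of class `module_survival`: `genes_used`, `n_dropped`,
#'   `eigengene`, `logrank` (`chi2`, `p`), `km`, and `cox` (NULL without
#'   covariates), or NULL if the module was skipped
#' @export
module_survival <- function(module, study, covariate_terms = NULL,
                            split = "median", min_gene_fraction = 0.5) {
  genes <- if (inherits(module, "gene_module")) module$genes else module
  present <- intersect(genes, study$genes)
  if (length(present) < 2L ||
      length(present) < min_gene_fraction * length(genes)) {
    warning("module skipped: only ", length(present), " of ",
            length(genes), " genes present in cohort")
    return(NULL)
  }
  ok <- study$meta$stage == "cancer" &
    !is.na(study$meta$time) & !is.na(study$meta$event)
  samples <- study$samples[ok]
  if (length(samples) < 3L) stop("too few cancer samples with survival data")
  eg <- eigengene(study$values[present, samples, drop = FALSE], split = split)
  mm <- study$meta[match(samples, study$meta$sample), ]
  lr <- logrank_test(mm$time, mm$event, eg$group)
  km <- km_curves(mm$time, mm$event, eg$group)
  cox <- NULL
  if (!is.null(covariate_terms)) {
    cox <- stepwise_cox(mm[, covariate_terms, drop = FALSE],
                        mm$time, mm$event, covariate_terms, eg$group)
  }
  structure(list(genes_used = present,
                 n_dropped = length(genes) - length(present),
                 eigengene = eg, logrank = lr, km = km, cox = cox),
            class = "module_survival")
}
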