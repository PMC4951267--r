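test_that("eigengene matches the direct eigen-decomposition oracle", {
  set.seed(14)
  for (rep in 1:10) {
    ng <- sample(3:10, 1); ns <- sample(6:20, 1)
    x <- matrix(rnorm(ng * ns), ng, ns,
                dimnames = list(paste0("g", 1:ng), paste0("s", 1:ns)))
    eg <- eigengene(x)
    want <- eigengene_oracle(x)
    if (sum(unname(eg$em) * want) < 0) want <- -want  # sign convention only
    expect_equal(unname(eg$em), want, tolerance = 1e-8)
  }
})

test_that("eigengene orientation, grouping, and degenerate input behave", {
  set.seed(15)
  # rank-1 limit: all genes share one profile up to vanishing noise
  profile <- rnorm(12)
  x <- matrix(rep(profile, each = 5), 5, 12) + rnorm(60, sd = 1e-4)
  dimnames(x) <- list(paste0("g", 1:5), paste0("s", 1:12))
  eg <- eigengene(x)
  expect_gt(abs(cor(eg$em, profile)), 0.9999)
  expect_gt(cor(eg$em, colMeans((x - rowMeans(x)) / apply(x, 1, sd))), 0)
  # negating the matrix flips the orientation but not the magnitude
  eg_neg <- eigengene(-x)
  expect_equal(abs(eg_neg$em), abs(eg$em), tolerance = 1e-8)
  # median split balances groups to within one sample, ties to low
  expect_lte(abs(sum(eg$group == "high") - sum(eg$group == "low")), 1)
  expect_error(eigengene(matrix(1, 3, 5)), "constant")
  expect_error(eigengene(x[1, , drop = FALSE]), ">= 2")
  expect_error(eigengene(x[, 1:2]), ">= 3")
})

test_that("log-rank test agrees with the hand O-E/V tally and is symmetric", {
  # identical survival experience in both groups
  tied <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 1, 1, 1),
                       rep(c("a", "b"), each = 3))
  expect_equal(tied$chi2, 0, tolerance = 1e-12)
  expect_equal(tied$p, 1)
  # toy fixture against the hand tally
  toy <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  want <- logrank_oracle(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(toy$chi2, want$chi2, tolerance = 1e-6)
  expect_equal(toy$p, want$p, tolerance = 1e-6)
  # label swap changes nothing
  set.seed(16)
  s <- sim_surv(rnorm(40))
  grp <- sample(c("x", "y"), 40, replace = TRUE)
  a <- logrank_test(s$time, s$event, grp)
  b <- logrank_test(s$time, s$event, ifelse(grp == "x", "y", "x"))
  expect_equal(a$chi2, b$chi2)
  expect_error(logrank_test(s$time, s$event, rep("one", 40)), "two groups")
})

test_that("log-rank and Cox agree with independent oracles on random fixtures", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 60
    x <- rnorm(n)
    s <- sim_surv(0.5 * x)
    s$time <- s$time + runif(n, 0, 1e-6)   # no ties
    grp <- ifelse(x > median(x), "hi", "lo")
    ours <- logrank_test(s$time, s$event, grp)
    want <- logrank_oracle(s$time, s$event, grp)
    expect_equal(ours$chi2, want$chi2, tolerance = 1e-6)
    fit <- cox_fit(data.frame(x = x), s$time, s$event, "x")
    expect_equal(fit$coef, cox_oracle_coef(x, s$time, s$event),
                 tolerance = 1e-6)
  }
})

test_that("Cox fits cover the null and recover planted hazard ratios", {
  set.seed(18)
  # null coverage: CI contains 1 in at least 90% of simulations
  cover <- replicate(100, {
    n <- 300
    x <- rnorm(n)
    s <- sim_surv(rep(0, n))
    fit <- cox_fit(data.frame(x = x), s$time, s$event, "x")
    fit$ci_low <= 1 && 1 <= fit$ci_high
  })
  expect_gte(mean(cover), 0.9)
  # planted binary covariate with HR 2
  set.seed(19)
  n <- 500
  z <- rbinom(n, 1, 0.5)
  s <- sim_surv(log(2) * z)
  fit <- cox_fit(data.frame(z = z), s$time, s$event, "z")
  expect_gt(fit$hr, 1.6)
  expect_lt(fit$hr, 2.5)
  # duplicating observations preserves the estimate (up to the Efron tie
  # correction the duplication itself introduces) and shrinks p
  dup <- cox_fit(data.frame(z = rep(z, 2)), rep(s$time, 2),
                 rep(s$event, 2), "z")
  expect_equal(dup$hr, fit$hr, tolerance = 1e-2)
  expect_lt(dup$p, fit$p)
  expect_error(cox_fit(data.frame(z = z), s$time, rep(0L, n), "z"),
               "events")
})

test_that("Cox estimates the planted module log-HR within sampling error", {
  set.seed(20)
  hits <- replicate(100, {
    n <- 150
    x <- rnorm(n)
    beta <- log(2)
    s <- sim_surv(beta * x)
    fit <- cox_fit(data.frame(x = x), s$time, s$event, "x")
    se <- (log(fit$ci_high) - log(fit$ci_low)) / (2 * qnorm(0.975))
    abs(fit$coef - beta) <= 3 * se
  })
  expect_gte(mean(hits), 0.95)
})

test_that("stepwise Cox screens terms univariately before the joint fit", {
  set.seed(21)
  n <- 250
  stage <- rbinom(n, 1, 0.4)          # prognostic clinical term
  age <- rnorm(n, 65, 8)              # noise terms
  sex <- rbinom(n, 1, 0.5)
  em_raw <- rnorm(n)                  # module summary, prognostic
  s <- sim_surv(0.8 * stage + 0.6 * em_raw)
  em_group <- factor(ifelse(em_raw > median(em_raw), "high", "low"),
                     levels = c("low", "high"))
  covs <- data.frame(stage = stage, age = age, sex = sex)
  sw <- stepwise_cox(covs, s$time, s$event, c("stage", "age", "sex"),
                     em_group)
  expect_true("stage" %in% sw$selected)
  expect_false(any(c("age", "sex") %in% sw$selected))
  expect_setequal(sw$multivariate$term, c("stage", "em_grouphigh"))
  # alpha_in = 1 lets everything in
  sw_all <- stepwise_cox(covs, s$time, s$event, c("stage", "age", "sex"),
                         em_group, alpha_in = 1)
  expect_length(sw_all$selected, 3)
  # no candidate passing leaves the eigengene group alone
  sw_none <- stepwise_cox(covs, s$time, s$event, c("age", "sex"), em_group,
                          alpha_in = 1e-12)
  expect_identical(sw_none$multivariate$term, "em_grouphigh")
})

test_that("meta-pooling matches closed forms and the metafor reference", {
  # identical cohorts: pooled mean, variance / k, no heterogeneity
  id <- pool_effects(rep(0.7, 3), rep(0.25, 3))
  expect_equal(id$fixed$log_hr, 0.7)
  expect_equal(id$fixed$se, sqrt(0.25 / 3))
  expect_equal(id$tau2, 0)
  expect_equal(id$random$log_hr, id$fixed$log_hr, tolerance = 1e-10)
  expect_equal(id$random$se, id$fixed$se, tolerance = 1e-10)
  # equal weights average
  eq <- pool_effects(c(0, 2), c(1, 1))
  expect_equal(eq$fixed$log_hr, 1)
  # homogeneous effects (Q <= df) collapse random onto fixed
  hom <- pool_effects(c(0.5, 0.52, 0.48), c(0.3, 0.3, 0.3))
  expect_equal(hom$tau2, 0)
  expect_equal(hom$random$log_hr, hom$fixed$log_hr, tolerance = 1e-10)
  # heterogeneous cohorts against the reference implementation
  skip_if_not_installed("metafor")
  set.seed(23)
  y <- rnorm(6, 0.4, 0.6)
  v <- runif(6, 0.05, 0.4)
  got <- pool_effects(y, v)
  fe <- metafor::rma(yi = y, vi = v, method = "FE")
  dl <- metafor::rma(yi = y, vi = v, method = "DL")
  expect_equal(got$fixed$log_hr, as.numeric(fe$beta), tolerance = 1e-8)
  expect_equal(got$fixed$se, fe$se, tolerance = 1e-8)
  expect_equal(got$tau2, dl$tau2, tolerance = 1e-8)
  expect_equal(got$random$log_hr, as.numeric(dl$beta), tolerance = 1e-8)
  expect_equal(got$random$se, dl$se, tolerance = 1e-8)
  expect_error(pool_effects(0.5, 0.2))
})

test_that("module survival drops missing genes and skips depleted modules", {
  set.seed(24)
  sim <- simulate_study(sim_config(n_genes = 40, planted_module_size = 6,
                                   rng_seed = 24))
  study <- sim$study
  genes <- sim$truth$planted_genes
  full <- module_survival(genes, study)
  expect_s3_class(full, "module_survival")
  expect_equal(full$n_dropped, 0)
  expect_true(full$logrank$p > 0 && full$logrank$p <= 1)
  expect_true(all(c("group", "time", "surv") %in% names(full$km)))
  # one absent gene: proceed on the remainder
  cohort <- study
  keep <- setdiff(study$genes, genes[1])
  cohort <- expression_study(study$values[keep, ], study$meta)
  part <- module_survival(genes, cohort)
  expect_equal(part$n_dropped, 1)
  expect_setequal(part$genes_used, genes[-1])
  # > 50% missing: skipped with a warning
  tiny <- expression_study(study$values[setdiff(study$genes, genes[1:4]), ],
                           study$meta)
  expect_warning(skipped <- module_survival(genes, tiny), "skipped")
  expect_null(skipped)
})
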