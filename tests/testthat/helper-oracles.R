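# Independent oracles and small fixture builders used across the suite.

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} (n/j) p_(j),
# capped at 1, mapped back to input order (direct O(n^2) definition)
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(n), function(i) min((n / (i:n)) * ps[i:n]), numeric(1))
  qs <- pmin(qs, 1)
  q <- numeric(n)
  q[o] <- qs
  q
}

# Hand log-rank tally: observed-minus-expected with hypergeometric variance
logrank_oracle <- function(time, event, group) {
  group <- factor(group)
  g1 <- levels(group)[1L]
  o1 <- e1 <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & group == g1)
    d <- sum(time == t & event == 1)
    o1 <- o1 + sum(time == t & event == 1 & group == g1)
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (o1 - e1)^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# Partial-likelihood score root for a single continuous covariate with no
# tied event times (where Breslow, Efron and the exact likelihood coincide)
cox_oracle_coef <- function(x, time, event) {
  score <- function(b) {
    r <- exp(b * x)
    sum(vapply(which(event == 1), function(i) {
      risk <- time >= time[i]
      x[i] - sum(x[risk] * r[risk]) / sum(r[risk])
    }, numeric(1)))
  }
  stats::uniroot(score, c(-30, 30), tol = 1e-12)$root
}

# First principal component via direct eigen-decomposition of the
# sample crossproduct of the row-standardized matrix
eigengene_oracle <- function(x) {
  xs <- (x - rowMeans(x)) / apply(x, 1L, stats::sd)
  ev <- eigen(crossprod(xs), symmetric = TRUE)
  v1 <- ev$vectors[, 1L]
  if (stats::cor(v1, colMeans(xs)) < 0) v1 <- -v1
  v1
}

# Arbitrary weighted toy network from explicit z and delta values
toy_weighted_network <- function(edges, z, delta) {
  net <- gene_network(edges, nodes = names(z))
  ew <- data.frame(gene1 = net$edges[, 1L], gene2 = net$edges[, 2L],
                   stringsAsFactors = FALSE)
  ew$delta <- delta[paste(ew$gene1, ew$gene2, sep = "-")]
  stopifnot(!anyNA(ew$delta))
  as_weighted_network(net, data.frame(gene = names(z), z = unname(z),
                                      stringsAsFactors = FALSE), ew)
}

# Random connected 8-node weighted graph for greedy-search property tests
random_weighted_graph <- function(n = 8L, p_edge = 0.45) {
  nodes <- sprintf("N%02d", seq_len(n))
  repeat {
    pairs <- t(utils::combn(nodes, 2L))
    sel <- stats::runif(nrow(pairs)) < p_edge
    if (!any(sel)) next
    net <- gene_network(pairs[sel, , drop = FALSE], nodes = nodes)
    comp <- igraph::components(as_igraph(net))
    if (comp$no == 1L) break
  }
  z <- stats::setNames(stats::rnorm(n, 0, 2), nodes)
  ew <- data.frame(gene1 = net$edges[, 1L], gene2 = net$edges[, 2L],
                   delta = abs(stats::rnorm(nrow(net$edges), 1, 2)),
                   stringsAsFactors = FALSE)
  as_weighted_network(net, data.frame(gene = nodes, z = unname(z),
                                      stringsAsFactors = FALSE), ew)
}

# Tiny three-stage study built by hand (values chosen per test)
toy_study <- function(values, stage, time = NULL, event = NULL) {
  samples <- colnames(values)
  meta <- data.frame(sample = samples, stage = stage,
                     stringsAsFactors = FALSE)
  if (!is.null(time)) meta$time <- time
  if (!is.null(event)) meta$event <- event
  expression_study(values, meta)
}

# Exponential proportional-hazards survival draw for oracle fixtures
sim_surv <- function(lp, base = 0.05, cens = 0.3) {
  n <- length(lp)
  h <- base * exp(lp)
  t_ev <- stats::rexp(n, h)
  t_c <- stats::rexp(n, base * cens / (1 - cens))
  list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
}
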