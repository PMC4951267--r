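test_that("module_score averages node and edge weights over m + n", {
  z <- c(A = 1, B = 2, C = 1)
  wn <- toy_weighted_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")),
                             z, c("A-B" = 3, "B-C" = 2, "A-C" = 2))
  expect_equal(module_score("B", wn), 2)            # m=1, n=0
  expect_equal(module_score(c("A", "B"), wn), (1 + 2 + 3) / 3)
  expect_equal(module_score(c("A", "B", "C"), wn), (4 + 7) / 6)
  # triangle with uniform weights
  wn2 <- toy_weighted_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")),
                              c(A = 1, B = 1, C = 1),
                              c("A-B" = 2, "B-C" = 2, "A-C" = 2))
  expect_equal(module_score(c("A", "B", "C"), wn2), 9 / 6)
  expect_error(module_score(character(), wn), "empty")
  expect_error(module_score("ZZ", wn), "ZZ")
})

test_that("greedy expansion takes forced steps and stops at the improvement rate", {
  # isolated seed: no candidates
  iso <- toy_weighted_network(cbind("A", "B"),
                              c(A = 1, B = 5, C = 2), c("A-B" = 6))
  mod_c <- greedy_expand("C", iso)
  expect_identical(mod_c$genes, "C")
  expect_equal(mod_c$score, 2)
  # one forced step: (1+5+6)/3 = 4 > 1 * 1.1
  mod_a <- greedy_expand("A", iso, search_params(r_improve = 0.1))
  expect_setequal(mod_a$genes, c("A", "B"))
  expect_equal(mod_a$score, 4)
  expect_equal(mod_a$trace$score, c(1, 4))
  # a too-demanding improvement rate stops immediately
  mod_inf <- greedy_expand("A", iso, search_params(r_improve = Inf))
  expect_identical(mod_inf$genes, "A")
  # d = 0 returns the bare seed
  mod_d0 <- greedy_expand("A", iso, search_params(d = 0))
  expect_identical(mod_d0$genes, "A")
  expect_error(greedy_expand("NOPE", iso), "NOPE")
})

test_that("negative-score modules use the additive improvement margin", {
  wn <- toy_weighted_network(cbind("A", "B"), c(A = -2, B = -1.95),
                             c("A-B" = 0.01))
  # score(A) = -2; adding B gives (-3.94)/3 = -1.3133 > -2 + 0.1
  mod <- greedy_expand("A", wn, search_params(r_improve = 0.1))
  expect_setequal(mod$genes, c("A", "B"))
  # with a large additive margin the step is refused
  mod2 <- greedy_expand("A", wn, search_params(r_improve = 1))
  expect_identical(mod2$genes, "A")
})

test_that("greedy modules are connected, locally maximal, and trace-consistent", {
  set.seed(123)
  for (rep in 1:25) {
    wn <- random_weighted_graph(8)
    params <- search_params(r_improve = 0, distance_mode = "module")
    for (seed in wn$network$nodes) {
      mod <- suppressWarnings(greedy_expand(seed, wn, params))
      expect_true(is_connected_set(mod$genes, wn$network))
      # recomputed score equals the incremental trace score, every step
      for (k in seq_len(nrow(mod$trace))) {
        expect_equal(module_score(mod$trace$gene[1:k], wn),
                     mod$trace$score[k], tolerance = 1e-12)
      }
      expect_true(all(diff(mod$trace$score) > 0))
      # local maximum: no eligible single addition increases the score
      if (length(mod$genes) < 8) {
        frontier <- setdiff(unique(unlist(wn$adj[mod$genes])), mod$genes)
        for (g in frontier) {
          expect_lte(module_score(c(mod$genes, g), wn), mod$score + 1e-12)
        }
      }
    }
  }
})

test_that("seed-distance mode caps the module radius at d", {
  # path A-B-C-D-E with ever-better additions
  z <- c(A = 0.5, B = 1, C = 2, D = 4, E = 8)
  edges <- rbind(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E"))
  wn <- toy_weighted_network(edges, z,
                             c("A-B" = 5, "B-C" = 5, "C-D" = 5, "D-E" = 5))
  free <- greedy_expand("A", wn, search_params(r_improve = 0,
                                               distance_mode = "module"))
  expect_setequal(free$genes, c("A", "B", "C", "D", "E"))
  capped <- greedy_expand("A", wn, search_params(d = 2, r_improve = 0,
                                                 distance_mode = "seed"))
  expect_setequal(capped$genes, c("A", "B", "C"))
})

test_that("search over all seeds is exhaustive and deterministic", {
  set.seed(9)
  wn <- random_weighted_graph(8)
  mods1 <- search_all_seeds(wn)
  mods2 <- search_all_seeds(wn)
  expect_length(mods1, 8)
  expect_identical(vapply(mods1, `[[`, character(1), "seed"),
                   sort(wn$network$nodes))
  expect_identical(mods1, mods2)
})

test_that("overlap merging unions above the threshold and reaches a fixpoint", {
  genes <- sprintf("g%02d", 1:12)
  full <- t(utils::combn(genes, 2))
  z <- setNames(rep(1, 12), genes)
  delta <- setNames(rep(1, nrow(full)), paste(full[, 1], full[, 2], sep = "-"))
  wn <- toy_weighted_network(full, z, delta)
  as_mod <- function(gs) {
    structure(list(seed = gs[1], genes = sort(gs),
                   edges = NULL, score = module_score(gs, wn), trace = NULL),
              class = "gene_module")
  }
  # overlap exactly 8/10 = 0.8 triggers the >= rule
  a <- as_mod(genes[1:10])
  b <- as_mod(c(genes[1:8], genes[11:12]))
  merged <- merge_overlapping(list(a, b), wn, 0.8)
  expect_length(merged, 1)
  expect_setequal(merged[[1]]$genes, genes)
  expect_equal(merged[[1]]$score, module_score(genes, wn))
  # disjoint modules are untouched
  d1 <- as_mod(genes[1:4]); d2 <- as_mod(genes[5:8])
  expect_length(merge_overlapping(list(d1, d2), wn, 0.8), 2)
  # nested modules collapse to the single union
  n1 <- as_mod(genes[1:3]); n2 <- as_mod(genes[1:6]); n3 <- as_mod(genes[1:9])
  nested <- merge_overlapping(list(n1, n2, n3), wn, 0.8)
  expect_length(nested, 1)
  expect_setequal(nested[[1]]$genes, genes[1:9])
  # below threshold nothing merges
  c1 <- as_mod(genes[1:5]); c2 <- as_mod(c(genes[1:2], genes[6:8]))
  expect_length(merge_overlapping(list(c1, c2), wn, 0.8), 2)
  # fixpoint: no remaining pair at or above the threshold
  set.seed(77)
  mods <- lapply(1:8, function(i) as_mod(sample(genes, sample(3:8, 1))))
  out <- merge_overlapping(mods, wn, 0.6)
  if (length(out) > 1) {
    for (i in seq_len(length(out) - 1)) for (j in seq((i + 1), length(out))) {
      ov <- length(intersect(out[[i]]$genes, out[[j]]$genes)) /
        min(length(out[[i]]$genes), length(out[[j]]$genes))
      expect_lt(ov, 0.6)
    }
  }
})

test_that("max_module_size is a warned safety stop", {
  genes <- sprintf("h%02d", 1:10)
  full <- t(utils::combn(genes, 2))
  wn <- toy_weighted_network(full, setNames(rep(1, 10), genes),
                             setNames(rep(50, nrow(full)),
                                      paste(full[, 1], full[, 2], sep = "-")))
  expect_warning(mod <- greedy_expand(genes[1], wn,
                                      search_params(r_improve = 0,
                                                    max_module_size = 4)),
                 "max_module_size")
  expect_length(mod$genes, 4)
})
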