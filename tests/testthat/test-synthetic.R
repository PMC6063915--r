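test_that("generators are deterministic under a fixed seed", {
  cfg <- synthetic_config(n_genes = 300, n_sets = 8,
                          set_size_range = c(5, 20),
                          n_planted_de_sets = 2, effect_size = 1.5,
                          background_edge_prob = 0.01,
                          planted_links = list(list("SET_1", "SET_2", 4)),
                          rng_seed = 42)
  a <- generate_synthetic_dataset(cfg)
  b <- generate_synthetic_dataset(cfg)
  expect_identical(a$gene_sets, b$gene_sets)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  expect_identical(as.data.frame(a$network), as.data.frame(b$network))
  # a different seed must change the draw
  cfg2 <- cfg; cfg2$rng_seed <- 43L
  expect_false(identical(generate_expression(cfg2, a$gene_sets)$matrix$values,
                         a$matrix$values))
})

test_that("gene set generation honours sizes, overlap and edge cases", {
  empty <- generate_gene_sets(synthetic_config(n_genes = 50, n_sets = 0))
  expect_length(empty$sets, 0)

  fixed <- generate_gene_sets(synthetic_config(n_genes = 100, n_sets = 5,
                                               set_size_range = c(10, 10),
                                               rng_seed = 3))
  expect_length(fixed$sets, 5)
  expect_true(all(lengths(fixed$sets) == 10))
  # overlap 0 with capacity -> pairwise disjoint
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(fixed$sets[[i]], fixed$sets[[j]]), 0)

  expect_error(synthetic_config(n_genes = 5, n_sets = 2,
                                set_size_range = c(2, 10)),
               "exceeds the gene universe")

  overlapping <- generate_gene_sets(
    synthetic_config(n_genes = 200, n_sets = 6, set_size_range = c(20, 20),
                     set_overlap_fraction = 0.5, rng_seed = 5))
  shared <- combn(6, 2, function(ij)
    length(intersect(overlapping$sets[[ij[1]]], overlapping$sets[[ij[2]]])))
  expect_gt(mean(shared), 0)
})

test_that("expression generation plants the configured shifts", {
  cfg <- synthetic_config(n_genes = 400, n_sets = 10,
                          set_size_range = c(15, 15),
                          n_planted_de_sets = 3, effect_size = 3,
                          noise_sd = 0.4, rng_seed = 9)
  gs <- generate_gene_sets(cfg)
  out <- generate_expression(cfg, gs)
  truth <- out$truth
  expect_length(truth$planted_de_set_names, 3)
  # every planted DE gene belongs to at least one planted set
  planted_members <- unique(unlist(gs$sets[truth$planted_de_set_names]))
  expect_true(all(truth$de_gene_list %in% planted_members))

  v <- out$matrix$values
  grp <- out$matrix$samples$group
  diff <- rowMeans(v[, grp == "test"]) - rowMeans(v[, grp == "reference"])
  for (s in truth$planted_de_set_names) {
    sgn <- if (truth$planted_up_or_down[[s]] == "up") 1 else -1
    expect_equal(mean(diff[gs$sets[[s]]]), sgn * 3 * 0.4,
                 tolerance = 0.25)
  }
  # non-DE genes carry no shift
  expect_lt(abs(mean(diff[setdiff(rownames(v), truth$de_gene_list)])), 0.05)

  bad <- cfg; bad$planted_set_names <- c("SET_01", "NOPE")
  expect_error(generate_expression(bad, gs), "NOPE")
})

test_that("network generation matches its stated edge model", {
  gs0 <- generate_gene_sets(synthetic_config(n_genes = 60, n_sets = 2,
                                             set_size_range = c(10, 10),
                                             rng_seed = 1))
  empty <- generate_network(synthetic_config(n_genes = 60, n_sets = 2,
                                             set_size_range = c(10, 10),
                                             rng_seed = 1), gs0)
  expect_equal(nrow(empty), 0)

  # binomial moment bound on the background edge count
  p <- 0.02; n <- 150
  cfg <- synthetic_config(n_genes = n, n_sets = 2,
                          set_size_range = c(10, 10),
                          background_edge_prob = p, rng_seed = 7)
  net <- generate_network(cfg, gs0)
  npairs <- n * (n - 1) / 2
  expect_lt(abs(nrow(net) - p * npairs),
            4 * sqrt(npairs * p * (1 - p)))
  expect_true(all(net$gene_a != net$gene_b))
  expect_false(any(duplicated(paste(net$gene_a, net$gene_b))))
  expect_true(all(net$score >= 500))

  # planted links guarantee cross-set support
  cfgp <- synthetic_config(n_genes = 60, n_sets = 2,
                           set_size_range = c(10, 10),
                           planted_links = list(list("SET_1", "SET_2", 5)),
                           rng_seed = 2)
  gsp <- generate_gene_sets(cfgp)
  netp <- generate_network(cfgp, gsp)
  a <- gsp$sets$SET_1; b <- gsp$sets$SET_2
  cross <- (netp$gene_a %in% a & netp$gene_b %in% b) |
    (netp$gene_a %in% b & netp$gene_b %in% a)
  expect_gte(sum(cross), 5)

  expect_error(synthetic_config(n_genes = 60, n_sets = 2,
                                set_size_range = c(10, 10),
                                planted_links = list(list("SET_1", "SET_1", 3))),
               "itself")
  expect_error(generate_network(
    synthetic_config(n_genes = 60, n_sets = 2, set_size_range = c(10, 10),
                     planted_links = list(list("SET_1", "GHOST", 3)),
                     rng_seed = 1), gsp),
    "GHOST")
})
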