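toy_network <- function(edges) {
  interaction_network(data.frame(gene_a = vapply(edges, `[[`, "", 1),
                                 gene_b = vapply(edges, `[[`, "", 2),
                                 score = rep(900L, length(edges)),
                                 stringsAsFactors = FALSE))
}

test_that("candidate links require perturbed endpoints on distinct sets", {
  res <- make_results(sets = c("A", "B"),
                      members = list(c("u", "w"), "v"),
                      leading = list("u", "v"))
  net <- toy_network(list(c("u", "v"), c("w", "v")))
  cand <- build_candidate_links(res, perturbed = c("u", "v"), net)
  expect_length(cand, 1)
  expect_identical(cand[[1]]$set_a, "A")
  expect_identical(cand[[1]]$set_b, "B")
  # edge (w,v) contributes nothing: w is not perturbed
  expect_equal(nrow(cand[[1]]$support), 1)
  expect_identical(cand[[1]]$support$gene_a_side, "U")
  expect_true(cand[[1]]$support$in_le_a && cand[[1]]$support$in_le_b)

  none <- build_candidate_links(res, c("u", "v"), toy_network(list()))
  expect_length(none, 0)
})

test_that("a shared gene may serve either side but never links a set to itself", {
  # h belongs to both sets; its only perturbed partner v belongs to A only,
  # so the edge (h, v) must be read as v on the A side and h on the B side
  res <- make_results(sets = c("A", "B"),
                      members = list(c("v", "h"), c("h", "m")),
                      leading = list(c("v", "h"), "h"))
  net <- toy_network(list(c("h", "v")))
  cand <- build_candidate_links(res, perturbed = c("h", "v"), net)
  expect_length(cand, 1)
  sup <- cand[[1]]$support
  expect_identical(sup$gene_a_side, "V")
  expect_identical(sup$gene_b_side, "H")
  expect_true(sup$in_le_a && sup$in_le_b)
})

test_that("coverage and the parsimony score follow their definitions", {
  cand <- make_candidates(list(c(1, 2), c(2, 3)))
  expect_equal(coverage(cand[0]), 0)
  expect_equal(coverage(cand[1]), 2)
  expect_equal(coverage(cand), 3)          # e2 counted once
  expect_gte(coverage(cand), coverage(cand[1]))  # monotone
  expect_equal(bpn_score(cand[0], 1), 0)
  expect_equal(bpn_score(cand, 1), 3 - 2)
  expect_equal(bpn_score(cand, 0), coverage(cand))
})

test_that("beta = 0 gives uniform marginals of one half", {
  cand <- make_candidates(list(c(1, 2), c(2, 3), c(4)))
  cfg <- bpn_config(burn_in_steps = 0, mcmc_steps = 1e5, thin = 1,
                    inverse_temperature = 0, rng_seed = 17)
  fit <- mcmc_bpn(cand, cfg)
  expect_true(all(abs(fit$links$probability - 0.5) < 0.01))
})

test_that("sampler marginals match exact enumeration on small instances", {
  set.seed(71)
  edge_sets <- lapply(1:8, function(i) sample(1:15, sample(1:5, 1)))
  cand <- make_candidates(edge_sets, n_edges = 15)
  exact <- oracle_enumeration(edge_sets, lambda = 1.5, beta = 1)
  cfg <- bpn_config(burn_in_steps = 1e4, mcmc_steps = 5e5, thin = 5,
                    link_penalty = 1.5, inverse_temperature = 1,
                    rng_seed = 29)
  fit <- mcmc_bpn(cand, cfg)
  expect_lt(max(abs(fit$links$probability - exact)), 0.02)
  # reproducibility under an identical seed
  fit2 <- mcmc_bpn(cand, cfg)
  expect_identical(fit$links$probability, fit2$links$probability)
  expect_error(mcmc_bpn(cand[0], cfg), "no candidate links")
})

test_that("model properties hold under exact enumeration", {
  # larger unique coverage -> strictly larger marginal (two candidates)
  two <- list(c(1, 2, 3), c(4))
  m <- oracle_enumeration(two, lambda = 2, beta = 1)
  expect_gt(m[1], m[2])
  # increasing lambda never increases any marginal
  sets <- list(c(1, 2), c(2, 3), c(4, 5, 6))
  grid <- lapply(c(0.5, 1.5, 3), function(l)
    oracle_enumeration(sets, lambda = l, beta = 1))
  expect_true(all(grid[[2]] <= grid[[1]] + 1e-12))
  expect_true(all(grid[[3]] <= grid[[2]] + 1e-12))
})

test_that("thresholding is inclusive and components are deterministic", {
  cand <- make_candidates(list(c(1, 2, 3), c(4, 5), c(6)))
  cfg <- bpn_config(burn_in_steps = 1e3, mcmc_steps = 1e5, thin = 1,
                    link_penalty = 1, rng_seed = 3)
  fit <- mcmc_bpn(cand, cfg)
  tau <- fit$links$probability[[2]]
  pn <- threshold_bpn(fit, tau)
  expect_true(paste(fit$links$set_a[[2]], fit$links$set_b[[2]]) %in%
                paste(pn$links$set_a, pn$links$set_b))  # boundary retained
  all_links <- threshold_bpn(fit, 0)
  expect_equal(nrow(all_links$links), 3)
  expect_equal(all_links$n_components, 3)  # disjoint set pairs
  expect_error(threshold_bpn(fit, 1.2), "\\[0, 1\\]")

  # direction labels propagate from enrichment results
  res <- make_results(sets = c(cand[[1]]$set_a, cand[[1]]$set_b),
                      members = list("x", "y"), leading = list("x", "y"),
                      direction = c("up", "down"))
  pn2 <- threshold_bpn(fit, 0, results = res)
  expect_identical(
    pn2$nodes$direction[pn2$nodes$set == cand[[1]]$set_a], "up")
})

test_that("quantile thresholds count possible links and keep ties", {
  cand <- make_candidates(list(c(1, 2), c(3, 4), c(5)), n_sets = 4)
  cfg <- bpn_config(burn_in_steps = 1e3, mcmc_steps = 5e4, thin = 1,
                    link_penalty = 1, rng_seed = 11)
  fit <- mcmc_bpn(cand, cfg)
  # 4 sets -> 6 possible links; top 50% -> 3 retained (all candidates)
  tau <- quantile_threshold(fit, 0.5)
  expect_equal(nrow(threshold_bpn(fit, tau)$links), 3)
  expect_lte(quantile_threshold(fit, 1), min(fit$links$probability))
  taus <- vapply(c(0.2, 0.5, 1), function(f) quantile_threshold(fit, f),
                 numeric(1))
  sizes <- vapply(taus, function(t) nrow(threshold_bpn(fit, t)$links),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("link reports count leading-edge support", {
  cand <- make_candidates(list(c(1, 2, 3)))
  cand[[1]]$support$in_le_b[2] <- FALSE
  rep1 <- link_report(cand[[1]])
  expect_equal(rep1$n_support, 3)
  expect_equal(rep1$n_leading_edge_support, 2)   # "2 of 3"
  cand[[1]]$support$in_le_a <- FALSE
  expect_equal(link_report(cand[[1]])$n_leading_edge_support, 0)
})

test_that("SIF and GraphML writers emit the thresholded network", {
  cand <- make_candidates(list(c(1, 2), c(3)))
  fit <- mcmc_bpn(cand, bpn_config(burn_in_steps = 1e3, mcmc_steps = 2e4,
                                   thin = 1, link_penalty = 0.5,
                                   rng_seed = 2))
  pn <- threshold_bpn(fit, 0)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(pn, sif)
  expect_length(readLines(sif), 2)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(pn, gml)
  doc <- xml2::read_xml(gml)   # must be well-formed XML
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='node']")), 4)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='edge']")), 2)
})
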