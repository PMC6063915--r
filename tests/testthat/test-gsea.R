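ranked_fixture <- function() {
  # genes g1..g5 with SNR (3, 2, 1, -1, -2)
  data.frame(gene = paste0("g", 1:5), snr = c(3, 2, 1, -1, -2),
             rank = 1:5, stringsAsFactors = FALSE)
}

test_that("SNR ranking applies the sd floor and deterministic ordering", {
  v <- rbind(
    gA = c(1, 1, 1, 0, 0, 0),   # zero sds, ref mean 0 -> floors 0.2, 0.2
    gB = c(2, 4, 3, 1, 1, 1),   # test mean 3 sd sqrt(1); wait values (2,4,3)
    gC = c(0, 0, 0, 1, 1, 1))
  colnames(v) <- paste0("s", 1:6)
  mat <- make_matrix(v)
  contr <- contrast(sample_group("test", paste0("s", 1:3)),
                    sample_group("ref", paste0("s", 4:6)))
  rl <- snr_ranking(mat, contr)
  expect_equal(rl$snr[rl$gene == "gA"], 1 / (0.2 + 0.2))
  expect_equal(rl$snr[rl$gene == "gC"], -1 / (0.2 + 0.2))
  expect_identical(rl$rank, 1:3)
  # per-gene rank equals the gene's 1-based position in the descending list
  expect_identical(rl$gene[order(-rl$snr, rl$gene)], rl$gene)

  # hand example with 2 samples per group
  v2 <- rbind(gX = c(2, 4, 1, 1))
  colnames(v2) <- paste0("s", 1:4)
  contr2 <- contrast(sample_group("t", c("s1", "s2")),
                     sample_group("r", c("s3", "s4")))
  rl2 <- snr_ranking(make_matrix(v2), contr2)
  expect_equal(rl2$snr, 2 / (sqrt(2) + 0.2), tolerance = 1e-12)

  # swapping groups negates every SNR and reverses the order
  swapped <- snr_ranking(mat, contrast(contr$reference, contr$test))
  expect_equal(sort(swapped$snr), sort(-rl$snr))
  expect_identical(swapped$gene, rev(rl$gene))
})

test_that("enrichment score reproduces the hand-worked running sums", {
  rl <- ranked_fixture()
  one <- enrichment_score(rl, "g1")
  expect_equal(one$running_sum, c(1, 0.75, 0.5, 0.25, 0))
  expect_equal(one$es, 1.0)
  expect_identical(one$leading_edge$gene, "g1")

  last <- enrichment_score(rl, "g5")
  expect_equal(last$es, -1.0)
  expect_identical(last$leading_edge$gene, "g5")

  both <- enrichment_score(rl, c("g1", "g5"))
  expect_equal(both$running_sum,
               c(0.6, 0.6 - 1/3, 0.6 - 2/3, -0.4, 0), tolerance = 1e-12)
  expect_equal(both$es, 0.6)
  expect_identical(both$leading_edge$gene, "g1")

  expect_error(enrichment_score(rl, "zz"), "no member")
  expect_error(enrichment_score(rl, paste0("g", 1:5)), "whole ranked list")
})

test_that("R and C++ enrichment scores agree with the brute-force oracle", {
  set.seed(19)
  for (i in 1:200) {
    N <- sample(5:50, 1)
    k <- sample(1:(N - 1), 1)
    snr <- sort(rnorm(N), decreasing = TRUE)
    rl <- data.frame(gene = sprintf("g%03d", 1:N), snr = snr, rank = 1:N)
    members <- sample(rl$gene, k)
    p <- sample(c(0, 1, 2), 1)
    expected <- oracle_es(snr, rl$gene %in% members, p)
    expect_equal(enrichment_score(rl, members, p)$es, expected,
                 tolerance = 1e-12)
    pos <- sort(which(rl$gene %in% members))
    expect_equal(bpnet:::cpp_es(pos, abs(snr[pos])^p, N), expected,
                 tolerance = 1e-12)
  }
})

test_that("ES stays within [-1, 1] and is scale-free at exponent 0", {
  set.seed(23)
  for (i in 1:50) {
    N <- sample(10:40, 1)
    snr <- sort(rnorm(N, sd = 3), decreasing = TRUE)
    rl <- data.frame(gene = sprintf("g%03d", 1:N), snr = snr, rank = 1:N)
    members <- sample(rl$gene, sample(2:(N - 2), 1))
    es <- enrichment_score(rl, members, 1)$es
    expect_lte(abs(es), 1)
    rl2 <- rl; rl2$snr <- rl$snr * 7   # monotone rescale of magnitudes
    expect_equal(enrichment_score(rl, members, 0)$es,
                 enrichment_score(rl2, members, 0)$es, tolerance = 1e-12)
  }
})

test_that("permutation p-values are seeded, floored and sign-conditioned", {
  rl <- ranked_fixture()
  cfg <- gsea_config(min_set_size = 1, n_permutations = 400, rng_seed = 5)
  # ES = +1 beats every same-signed null (max possible score)
  p <- permutation_p(rl, 1.0, 1, cfg)
  set.seed(5)
  null_es <- bpnet:::cpp_es_null(5, 1, abs(rl$snr), 400)
  expect_equal(p, (1 + sum(null_es >= 1)) / (1 + sum(null_es > 0)))
  expect_identical(permutation_p(rl, 1.0, 1, cfg),
                   permutation_p(rl, 1.0, 1, cfg))
  expect_lte(p, 1)
})

test_that("bh_fdr implements the step-up formula", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.2, 1.7)), "\\[0, 1\\]")
  set.seed(41)
  for (i in 1:25) {
    p <- runif(sample(1:60, 1))
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, method = "BH"))  # independent oracle
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("run_gsea filters by effective size and orders results", {
  set.seed(3)
  v <- matrix(rnorm(6 * 40, mean = 8), 40, 6,
              dimnames = list(sprintf("G%02d", 1:40), paste0("s", 1:6)))
  mat <- make_matrix(v, groups = rep(c("r", "t"), each = 3))
  contr <- contrast(sample_group("t", paste0("s", 4:6)),
                    sample_group("r", paste0("s", 1:3)))
  coll <- gene_set_collection(list(
    tiny = sprintf("G%02d", 1:9),            # 9 members -> excluded
    ok_a = sprintf("G%02d", 1:10),
    ok_b = sprintf("G%02d", 11:25)))
  res <- run_gsea(mat, contr, coll, gsea_config(n_permutations = 100,
                                                rng_seed = 2))
  expect_setequal(res$set, c("ok_a", "ok_b"))
  expect_identical(res$result_rank, 1:2)
  expect_true(all(res$direction == ifelse(res$es > 0, "up", "down")))
  ord <- order(res$q, res$p, -abs(res$es), res$set)
  expect_identical(ord, 1:2)

  expect_error(run_gsea(mat, contr,
                        gene_set_collection(list(tiny = c("G01", "G02"))),
                        gsea_config(n_permutations = 50)),
               "size filter")

  # permuting sample order within groups leaves ES unchanged
  v2 <- v[, c(2, 3, 1, 6, 4, 5)]
  res2 <- run_gsea(make_matrix(v2), contr, coll,
                   gsea_config(n_permutations = 100, rng_seed = 2))
  expect_equal(res2$es[match(res$set, res2$set)], res$es)
})

test_that("leading_edge_union collects exactly the significant leading edges", {
  res <- make_results(sets = c("S1", "S2", "S3"),
                      members = list(c("a", "b", "x"), c("b", "c"), c("z")),
                      leading = list(c("a", "b"), c("b", "c"), "z"),
                      q = c(0.001, 0.01, 0.5))
  expect_setequal(leading_edge_union(res, 0.01), c("a", "b", "c"))
  expect_identical(leading_edge_union(res, 1e-9), character(0))
  # gene in a significant set but outside all leading edges is not perturbed
  expect_false("x" %in% leading_edge_union(res, 0.01))
})
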