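# Independent oracles used by the module and acceptance tests. These
# deliberately recompute everything from first principles (full prefix
# sums, naive pair scans, exhaustive enumeration) and never call the
# package's optimized code paths.

# Brute-force running-sum enrichment score: build the entire N-step prefix
# sum and take the extremum of largest magnitude (ties resolve positive).
oracle_es <- function(snr, hit, p = 1) {
  N <- length(snr)
  k <- sum(hit)
  w <- abs(snr)^p
  W <- sum(w[hit])
  if (W <= 0) {
    w[hit] <- 1
    W <- k
  }
  run <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + if (hit[i]) w[i] / W else -1 / (N - k)
    run[i] <- acc
  }
  if (max(run) >= abs(min(run)) - 1e-12) max(run) else min(run)
}

# Naive agglomerative clustering: linkage distances recomputed from the
# original distance matrix by explicit loops over member pairs; same
# lexicographic tie rule as the implementation contract.
oracle_linkage <- function(d, linkage) {
  labels <- rownames(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), function(i) labels[i])
  heights <- numeric(0)
  clades <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      vals <- c()
      for (a in clusters[[i]]) for (b in clusters[[j]])
        vals <- c(vals, d[a, b])
      dd <- switch(linkage, single = min(vals), complete = max(vals),
                   average = mean(vals))
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
      better <- is.null(best) || dd < best$d ||
        (dd == best$d && (key[1] < best$key[1] ||
                          (key[1] == best$key[1] && key[2] < best$key[2])))
      if (better) best <- list(d = dd, key = key, i = i, j = j)
    }
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    heights <- c(heights, best$d)
    clades <- c(clades, list(sort(merged)))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(heights = heights, clades = clades)
}

clade_family <- function(tree) {
  sets <- bpnet:::node_leaf_sets(tree)
  lapply(sets, sort)
}

# Exhaustive Gibbs enumeration over all 2^k link subsets: exact posterior
# marginals for pi(S) ~ exp(beta * (|union of edge sets| - lambda * |S|)).
oracle_enumeration <- function(edge_sets, lambda, beta) {
  k <- length(edge_sets)
  marg <- numeric(k)
  Z <- 0
  for (mask in 0:(2^k - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    cov <- length(unique(unlist(edge_sets[sel])))
    wgt <- exp(beta * (cov - lambda * length(sel)))
    Z <- Z + wgt
    marg[sel] <- marg[sel] + wgt
  }
  marg / Z
}

# Wilcoxon-statistic AUROC of scores for positives vs negatives.
oracle_auroc <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg))
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Minimal hand-built EnrichmentResults row set for BPN tests.
make_results <- function(sets, members, leading, direction = NULL,
                         q = NULL) {
  n <- length(sets)
  out <- data.frame(result_rank = seq_len(n), set = sets,
                    category = "manual", size = lengths(members),
                    es = rep(0.5, n), p = rep(0.001, n),
                    q = if (is.null(q)) rep(0.001, n) else q,
                    direction = if (is.null(direction)) rep("up", n)
                                else direction,
                    stringsAsFactors = FALSE)
  out$leading_edge <- lapply(leading, function(g)
    data.frame(gene = g, snr = rep(1, length(g)),
               rank = seq_along(g), stringsAsFactors = FALSE))
  out$members <- members
  class(out) <- c("EnrichmentResults", "data.frame")
  out
}

# Hand-built CandidateLinks from a list of edge-id vectors.
make_candidates <- function(edge_sets, n_edges = max(unlist(edge_sets)),
                            n_sets = length(edge_sets) + 1L) {
  cand <- lapply(seq_along(edge_sets), function(i)
    list(set_a = sprintf("A%02d", i), set_b = sprintf("B%02d", i),
         support = data.frame(
           gene_a_side = paste0("u", edge_sets[[i]]),
           gene_b_side = paste0("v", edge_sets[[i]]),
           edge_id = edge_sets[[i]],
           in_le_a = TRUE, in_le_b = TRUE,
           stringsAsFactors = FALSE)))
  structure(cand, class = "CandidateLinks", n_edges = as.integer(n_edges),
            n_sets = as.integer(n_sets))
}

# Small deterministic expression matrix from an explicit value matrix.
make_matrix <- function(values, groups = NULL) {
  samples <- data.frame(sample_id = colnames(values),
                        stringsAsFactors = FALSE)
  if (!is.null(groups)) samples$group <- groups
  expression_matrix(values, samples)
}
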