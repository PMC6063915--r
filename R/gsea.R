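# Gene set enrichment analysis implemented from first principles:
# signal-to-noise ranking, weighted Kolmogorov-Smirnov running-sum
# enrichment score, gene-set permutation null, Benjamini-Hochberg FDR,
# leading-edge extraction and the perturbed-gene union.

#' GSEA configuration
#'
#' Defaults follow standard GSEA practice for small-replicate microarray
#' contrasts: gene sets restricted to 10-500 effective members, 5000
#' gene-set permutations, the weighted (exponent 1) running-sum statistic,
#' and an inclusive significance boundary q <= 0.01.
#'
#' @param min_set_size,max_set_size Effective set size filter bounds
#'   (inclusive).
#' @param n_permutations Number of random gene sets per null distribution.
#' @param weight_exponent Exponent p applied to |SNR| in the running sum
#'   (0 = classic unweighted Kolmogorov-Smirnov statistic).
#' @param q_threshold Significance boundary on BH q-values (inclusive).
#' @param rng_seed Integer seed for the permutation stream, or `NULL` to use
#'   the current RNG state.
#' @return A list of class `GseaConfig`.
#' @export
gsea_config <- function(min_set_size = 10L, max_set_size = 500L,
                        n_permutations = 5000L, weight_exponent = 1,
                        q_threshold = 0.01, rng_seed = NULL) {
  stopifnot(min_set_size >= 1L, min_set_size <= max_set_size,
            n_permutations >= 1L, weight_exponent >= 0,
            q_threshold >= 0, q_threshold <= 1)
  structure(list(min_set_size = as.integer(min_set_size),
                 max_set_size = as.integer(max_set_size),
                 n_permutations = as.integer(n_permutations),
                 weight_exponent = weight_exponent,
                 q_threshold = q_threshold,
                 rng_seed = rng_seed),
            class = "GseaConfig")
}

#' Rank genes by signal-to-noise ratio
#'
#' SNR = (mean_test - mean_ref) / (sd_test' + sd_ref') where each group's
#' standard deviation is floored at 20% of the absolute group mean (at 0.2
#' when the group mean is zero) -- the variance stabilization required for
#' 2-3 replicate groups. Ties in SNR break by gene id so the ranking is a
#' deterministic total order.
#'
#' @param mat A gene-level `ExpressionMatrix`.
#' @param contrast A `Contrast`; both groups need >= 2 samples.
#' @param sd_denominator `"n-1"` (sample sd, default) or `"n"`.
#' @return A `RankedList` data.frame with columns gene, snr, rank
#'   (1-based position in the full descending list).
#' @export
snr_ranking <- function(mat, contrast, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  check_group_in_matrix(mat, contrast$test)
  check_group_in_matrix(mat, contrast$reference)
  group_stats <- function(members) {
    x <- mat$values[, members, drop = FALSE]
    n <- length(members)
    if (n < 2L) stop("SNR needs >= 2 samples per group")
    m <- rowMeans(x)
    ss <- rowSums((x - m)^2)
    s <- sqrt(ss / (if (sd_denominator == "n-1") n - 1L else n))
    floor_ <- ifelse(m == 0, 0.2, 0.2 * abs(m))
    list(mean = m, sd = pmax(s, floor_))
  }
  a <- group_stats(contrast$test$members)
  b <- group_stats(contrast$reference$members)
  snr <- (a$mean - b$mean) / (a$sd + b$sd)
  genes <- rownames(mat$values)
  ord <- order(-snr, genes)
  out <- data.frame(gene = genes[ord], snr = snr[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("RankedList", "data.frame")
  out
}

#' Weighted running-sum enrichment score for one gene set
#'
#' Walking the ranked list, each set member ("hit") at position i adds
#' |snr_i|^p / sum_hits |snr|^p and every non-member subtracts 1/(N - k).
#' The enrichment score is the running-sum value of maximal absolute
#' deviation from zero (signed; an exact tie resolves to the positive
#' extremum). The leading edge is the set members at or before the maximum
#' (ES > 0) or at or after the minimum (ES < 0). If every hit weight is
#' zero the unweighted statistic (equal hit increments) is used.
#'
#' @param ranked A `RankedList`.
#' @param set_members Character vector of genes; the intersection with the
#'   ranked list must be non-empty and strictly smaller than the list.
#' @param weight_exponent Exponent p on |SNR|.
#' @return List with elements `es`, `running_sum` (length N), and
#'   `leading_edge` (data.frame gene, snr, rank).
#' @export
enrichment_score <- function(ranked, set_members, weight_exponent = 1) {
  N <- nrow(ranked)
  hit <- ranked$gene %in% set_members
  k <- sum(hit)
  if (k == 0L) stop("gene set has no member in the ranked list")
  if (k == N) stop("gene set covers the whole ranked list")
  w <- abs(ranked$snr)^weight_exponent
  w[!hit] <- 0
  W <- sum(w[hit])
  if (W <= 0) {
    w[hit] <- 1
    W <- k
  }
  inc <- ifelse(hit, w / W, -1 / (N - k))
  running <- cumsum(inc)
  mx <- max(running)
  mn <- min(running)
  # near-exact ties between the extrema resolve to the positive one
  if (mx >= abs(mn) - 1e-12) {
    es <- mx
    cut <- which.max(running)
    le <- which(hit & seq_len(N) <= cut)
  } else {
    es <- mn
    cut <- which.min(running)
    le <- which(hit & seq_len(N) >= cut)
  }
  list(es = es,
       running_sum = running,
       leading_edge = data.frame(gene = ranked$gene[le],
                                 snr = ranked$snr[le],
                                 rank = ranked$rank[le],
                                 stringsAsFactors = FALSE))
}

#' Gene-set permutation p-value for an observed enrichment score
#'
#' Null scores come from `n_permutations` random gene sets of the same size
#' drawn uniformly without replacement from the ranked genes. Following the
#' standard GSEA convention the p-value is one-sided conditional on the
#' observed direction, with a +1 pseudocount so p is never zero:
#' p = (1 + #same-signed nulls at least as extreme) / (1 + #same-signed
#' nulls). Dividing by all permutations instead would bound p near 0.5 and
#' destroy null uniformity.
#'
#' @param ranked A `RankedList`.
#' @param observed_es Observed enrichment score.
#' @param set_size Effective set size (members present in the list).
#' @param config A `GseaConfig` (uses n_permutations, weight_exponent,
#'   rng_seed).
#' @return Nominal p-value in (0, 1].
#' @export
permutation_p <- function(ranked, observed_es, set_size, config = gsea_config()) {
  N <- nrow(ranked)
  stopifnot(set_size >= 1L, set_size < N)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  wfull <- abs(ranked$snr)^config$weight_exponent
  null_es <- cpp_es_null(N, as.integer(set_size), wfull,
                         config$n_permutations)
  permutation_p_from_null(observed_es, null_es)
}

permutation_p_from_null <- function(observed_es, null_es) {
  same <- sign(null_es) == sign(observed_es)
  extreme <- same & abs(null_es) >= abs(observed_es)
  (1 + sum(extreme)) / (1 + sum(same))
}

#' Benjamini-Hochberg step-up q-values
#'
#' q_(i) = min over j >= i of m * p_(j) / j on the ascending-sorted
#' p-values, capped at 1 and mapped back to the input order.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  ord <- order(pvalues)
  q_sorted <- rev(cummin(rev(m * pvalues[ord] / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

#' Run gene set enrichment analysis for one contrast
#'
#' Ranks genes by SNR, filters sets to effective size within
#' `[min_set_size, max_set_size]`, scores each surviving set, computes
#' gene-set permutation p-values (a fresh seeded null per set), applies BH
#' FDR across all tested sets, and ranks results by (q asc, p asc, |ES|
#' desc, name asc).
#'
#' @param mat A gene-level `ExpressionMatrix`.
#' @param contr A `Contrast`.
#' @param collection A non-empty `GeneSetCollection`.
#' @param config A `GseaConfig`.
#' @return An `EnrichmentResults` data.frame with columns result_rank, set,
#'   category, size, es, p, q, direction, and list-columns `leading_edge`
#'   (data.frame gene/snr/rank per set) and `members` (effective members).
#' @export
run_gsea <- function(mat, contr, collection, config = gsea_config()) {
  if (!length(collection$sets)) stop("empty gene set collection")
  ranked <- snr_ranking(mat, contr)
  N <- nrow(ranked)
  eff <- lapply(collection$sets, function(g) intersect(g, ranked$gene))
  sizes <- lengths(eff)
  keep <- sizes >= config$min_set_size & sizes <= config$max_set_size &
    sizes < N
  if (!any(keep))
    stop("no gene set survives the size filter [", config$min_set_size,
         ", ", config$max_set_size, "]")
  eff <- eff[keep]
  sizes <- sizes[keep]
  set_names <- names(eff)

  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  wfull <- abs(ranked$snr)^config$weight_exponent
  perm_config <- config
  perm_config$rng_seed <- NULL  # one stream for all sets, seeded once above

  es <- numeric(length(eff))
  pval <- numeric(length(eff))
  le <- vector("list", length(eff))
  for (i in seq_along(eff)) {
    sc <- enrichment_score(ranked, eff[[i]], config$weight_exponent)
    es[[i]] <- sc$es
    le[[i]] <- sc$leading_edge
    null_es <- cpp_es_null(N, sizes[[i]], wfull, config$n_permutations)
    pval[[i]] <- permutation_p_from_null(sc$es, null_es)
  }
  qval <- bh_fdr(pval)
  ord <- order(qval, pval, -abs(es), set_names)
  out <- data.frame(result_rank = seq_along(ord),
                    set = set_names[ord],
                    category = unname(collection$category[set_names[ord]]),
                    size = sizes[ord],
                    es = es[ord],
                    p = pval[ord],
                    q = qval[ord],
                    direction = ifelse(es[ord] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out$leading_edge <- le[ord]
  out$members <- unname(eff[ord])
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResults", "data.frame")
  attr(out, "contrast") <- contr$name
  out
}

#' Union of leading edges over significant gene sets
#'
#' A gene is "perturbed" if it participates in the leading edge of at least
#' one gene set with q at or below the threshold.
#'
#' @param results An `EnrichmentResults` table.
#' @param q_threshold Inclusive significance boundary.
#' @return Character vector of perturbed genes (sorted).
#' @export
leading_edge_union <- function(results, q_threshold = 0.01) {
  sig <- results$q <= q_threshold
  if (!any(sig)) return(character(0))
  sort(unique(unlist(lapply(results$leading_edge[sig], `[[`, "gene"))))
}

#' Write enrichment results as TSV
#'
#' Columns: rank, set, category, size, ES, p, q, direction, leading_edge
#' (comma-separated gene list).
#'
#' @param results An `EnrichmentResults` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  tab <- data.frame(rank = results$result_rank, set = results$set,
                    category = results$category, size = results$size,
                    ES = results$es, p = results$p, q = results$q,
                    direction = results$direction,
                    leading_edge = vapply(results$leading_edge, function(d)
                      paste(d$gene, collapse = ","), character(1)),
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write enrichment results as JSON for machine consumption
#'
#' Per-set records carry rank, category, size, ES, p, q, direction and the
#' full leading edge (gene, SNR, rank).
#'
#' @param results An `EnrichmentResults` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_json <- function(results, path) {
  recs <- lapply(seq_len(nrow(results)), function(i) list(
    rank = results$result_rank[[i]], set = results$set[[i]],
    category = results$category[[i]], size = results$size[[i]],
    es = results$es[[i]], p = results$p[[i]], q = results$q[[i]],
    direction = results$direction[[i]],
    leading_edge = results$leading_edge[[i]]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
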