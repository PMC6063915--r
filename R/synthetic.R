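# Synthetic data with known planted structure: log-scale expression for a
# two-condition contrast with planted differentially-expressed gene sets,
# gene-set collections with controllable overlap, and interaction networks
# with planted excess connectivity between chosen set pairs over an
# Erdos-Renyi background. Every downstream stage is testable against the
# recorded truth without external downloads.

#' Configuration for the synthetic data generators
#'
#' The expression model is additive Gaussian on the log2 scale: per-gene
#' baseline means drawn once from Normal(8, 2) (RMA-style intensities),
#' replicate noise Normal(0, noise_sd). Genes in planted DE sets are
#' shifted in the test group by `effect_size * noise_sd` with a
#' seed-determined sign per set.
#'
#' @param n_genes Size of the gene universe.
#' @param n_replicates_per_group Replicates per condition (default 3,
#'   matching triplicate microarray designs; 2 emulates the short group
#'   that gets a mean-imputed third replicate).
#' @param n_sets Number of gene sets.
#' @param set_size_range Integer `(min, max)` set sizes, within
#'   `[1, n_genes]`.
#' @param set_overlap_fraction Fraction of each set drawn from a shared
#'   core pool (0 = pairwise disjoint while the universe lasts).
#' @param n_planted_de_sets Number of sets carrying a planted shift.
#' @param planted_set_names Optional explicit planted set names (otherwise
#'   sampled); must exist in the generated collection.
#' @param effect_size Planted shift in units of `noise_sd`.
#' @param noise_sd Replicate noise standard deviation (log2 units).
#' @param background_edge_prob Erdos-Renyi background edge probability.
#' @param planted_links List of `list(set_i, set_j, extra_edges)` triples:
#'   extra cross-set edges planted on top of the background.
#' @param rng_seed Single integer seed governing all three generators.
#' @return A validated list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_genes, n_sets,
                             set_size_range = c(10L, 50L),
                             n_replicates_per_group = 3L,
                             set_overlap_fraction = 0,
                             n_planted_de_sets = 0L,
                             planted_set_names = NULL,
                             effect_size = 0,
                             noise_sd = 0.5,
                             background_edge_prob = 0,
                             planted_links = list(),
                             rng_seed = 1L) {
  set_size_range <- as.integer(set_size_range)
  stopifnot(n_genes >= 1, n_sets >= 0, length(set_size_range) == 2L,
            set_size_range[[1L]] >= 1L,
            set_size_range[[1L]] <= set_size_range[[2L]],
            n_replicates_per_group >= 2L,
            set_overlap_fraction >= 0, set_overlap_fraction <= 1,
            n_planted_de_sets >= 0, n_planted_de_sets <= n_sets,
            noise_sd > 0,
            background_edge_prob >= 0, background_edge_prob <= 1)
  if (set_size_range[[2L]] > n_genes)
    stop("set_size_range maximum exceeds the gene universe (",
         set_size_range[[2L]], " > ", n_genes, ")")
  planted_links <- lapply(planted_links, function(pl) {
    if (length(pl) != 3L)
      stop("each planted link must be list(set_i, set_j, extra_edges)")
    pl <- list(as.character(pl[[1L]]), as.character(pl[[2L]]),
               as.integer(pl[[3L]]))
    if (identical(pl[[1L]], pl[[2L]]))
      stop("planted link between a set and itself: ", pl[[1L]])
    if (is.na(pl[[3L]]) || pl[[3L]] < 1L)
      stop("planted link needs a positive extra_edges count")
    pl
  })
  structure(list(n_genes = as.integer(n_genes),
                 n_sets = as.integer(n_sets),
                 set_size_range = set_size_range,
                 n_replicates_per_group = as.integer(n_replicates_per_group),
                 set_overlap_fraction = set_overlap_fraction,
                 n_planted_de_sets = as.integer(n_planted_de_sets),
                 planted_set_names = planted_set_names,
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 background_edge_prob = background_edge_prob,
                 planted_links = planted_links,
                 rng_seed = as.integer(rng_seed)),
            class = "SyntheticConfig")
}

synthetic_gene_ids <- function(n) {
  sprintf("G%0*d", nchar(as.character(n)), seq_len(n))
}

# Each generator seeds its own sub-stream from the single rng_seed so that
# standalone calls are deterministic; generate_synthetic_dataset() chains
# them with the same offsets.
seed_offset <- c(sets = 0L, expression = 1L, network = 2L)

#' Generate a gene set collection with controlled overlap
#'
#' Sizes are uniform in `set_size_range`. A fixed "core pool" of genes is
#' drawn once; each set takes `round(set_overlap_fraction * size)` members
#' from the core pool and the rest from genes not yet used by any set, so
#' overlap concentrates in the shared core. With overlap 0 and enough
#' genes, sets are pairwise disjoint; if fresh genes run out, the
#' remainder is drawn from already-used genes.
#'
#' @param config A `SyntheticConfig`.
#' @return A `GeneSetCollection` with sets named `SET_001`, ...
#' @export
generate_gene_sets <- function(config) {
  set.seed(config$rng_seed + seed_offset[["sets"]])
  genes <- synthetic_gene_ids(config$n_genes)
  if (config$n_sets == 0L)
    return(gene_set_collection(stats::setNames(list(), character(0)),
                               category = character(0)))
  size_choices <- seq(config$set_size_range[[1L]],
                      config$set_size_range[[2L]])
  sizes <- size_choices[sample.int(length(size_choices),
                                   config$n_sets, replace = TRUE)]
  core_n <- config$set_size_range[[2L]]
  core <- sample(genes, core_n)
  fresh <- setdiff(sample(genes), core)
  used <- character(0)
  sets <- vector("list", config$n_sets)
  for (i in seq_len(config$n_sets)) {
    n_core <- round(config$set_overlap_fraction * sizes[[i]])
    n_new <- sizes[[i]] - n_core
    members <- if (n_core > 0L) sample(core, n_core) else character(0)
    if (n_new > 0L) {
      take <- head(fresh, n_new)
      if (length(take)) fresh <- fresh[-seq_along(take)]
      if (length(take) < n_new) {
        pool <- setdiff(used, members)
        if (length(pool) < n_new - length(take))
          stop("gene universe too small for the requested sets")
        take <- c(take, sample(pool, n_new - length(take)))
      }
      members <- c(members, take)
    }
    sets[[i]] <- sort(members)
    used <- union(used, members)
  }
  names(sets) <- sprintf("SET_%0*d", nchar(as.character(config$n_sets)),
                         seq_len(config$n_sets))
  gene_set_collection(sets, category = "synthetic")
}

#' Generate a two-condition expression matrix with planted DE sets
#'
#' Baseline per-gene means are drawn once from Normal(8, 2); every sample
#' adds Normal(0, noise_sd) replicate noise. Genes belonging to a planted
#' DE set are shifted in the test group by `effect_size * noise_sd`, with
#' a per-set direction decided by a seed-determined coin flip (a gene in
#' several planted sets takes the direction of the first set that claims
#' it). Sample annotations mark group membership and replicate number.
#'
#' @param config A `SyntheticConfig`.
#' @param gene_sets A `GeneSetCollection` over the same gene universe.
#' @return List with `matrix` (an `ExpressionMatrix`) and `truth` (class
#'   `SyntheticTruth`: planted_de_set_names, planted_up_or_down,
#'   planted_link_pairs, de_gene_list).
#' @export
generate_expression <- function(config, gene_sets) {
  set.seed(config$rng_seed + seed_offset[["expression"]])
  genes <- synthetic_gene_ids(config$n_genes)
  if (length(gene_sets$sets)) {
    stray <- setdiff(unique(unlist(gene_sets$sets)), genes)
    if (length(stray))
      stop("gene sets use genes outside the configured universe: ",
           paste(head(stray, 5L), collapse = ", "))
  }
  planted <- config$planted_set_names
  if (is.null(planted) && config$n_planted_de_sets > 0L)
    planted <- sort(sample(names(gene_sets$sets),
                           config$n_planted_de_sets))
  if (length(planted)) {
    missing <- setdiff(planted, names(gene_sets$sets))
    if (length(missing))
      stop("planted set(s) absent from the collection: ",
           paste(missing, collapse = ", "))
  } else {
    planted <- character(0)
  }
  direction <- stats::setNames(
    ifelse(runif(length(planted)) < 0.5, "down", "up"), planted)

  shift <- stats::setNames(numeric(length(genes)), genes)
  for (s in planted) {
    mem <- gene_sets$sets[[s]]
    unclaimed <- mem[shift[mem] == 0]
    shift[unclaimed] <- ifelse(direction[[s]] == "up", 1, -1) *
      config$effect_size * config$noise_sd
  }
  de_genes <- names(shift)[shift != 0]

  nrep <- config$n_replicates_per_group
  baseline <- rnorm(length(genes), mean = 8, sd = 2)
  n_samp <- 2L * nrep
  noise <- matrix(rnorm(length(genes) * n_samp, sd = config$noise_sd),
                  nrow = length(genes))
  values <- baseline + noise
  values[, (nrep + 1L):n_samp] <- values[, (nrep + 1L):n_samp] + shift
  sample_ids <- c(sprintf("ref_%d", seq_len(nrep)),
                  sprintf("test_%d", seq_len(nrep)))
  dimnames(values) <- list(genes, sample_ids)
  samples <- data.frame(
    sample_id = sample_ids,
    group = rep(c("reference", "test"), each = nrep),
    replicate = rep(seq_len(nrep), 2L),
    stringsAsFactors = FALSE)
  truth <- structure(list(
    planted_de_set_names = planted,
    planted_up_or_down = direction,
    planted_link_pairs = lapply(config$planted_links,
                                function(pl) sort(c(pl[[1L]], pl[[2L]]))),
    de_gene_list = de_genes),
    class = "SyntheticTruth")
  list(matrix = expression_matrix(values, samples), truth = truth)
}

# map 0-based pair indices to (i, j) with 0 <= i < j < n
pair_from_index <- function(idx, n) {
  i <- floor((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * idx)) / 2)
  base <- i * (2 * n - i - 1) / 2
  bad <- base > idx  # guard against floating-point overshoot
  i[bad] <- i[bad] - 1
  base <- i * (2 * n - i - 1) / 2
  j <- idx - base + i + 1
  cbind(i + 1, j + 1)
}

#' Generate an interaction network with planted inter-set connectivity
#'
#' Background edges appear independently with `background_edge_prob` over
#' the whole gene universe (Erdos-Renyi). For every planted link
#' `(set_i, set_j, k)`, k extra distinct edges are added between members
#' of the two sets (never joining a shared gene to itself, never
#' duplicating an existing edge). All scores are set to 900, above the
#' default downstream confidence cutoff.
#'
#' @param config A `SyntheticConfig`.
#' @param gene_sets The `GeneSetCollection` the planted links refer to.
#' @return An `InteractionNetwork`.
#' @export
generate_network <- function(config, gene_sets) {
  set.seed(config$rng_seed + seed_offset[["network"]])
  genes <- synthetic_gene_ids(config$n_genes)
  n <- length(genes)
  edges <- NULL
  if (config$background_edge_prob > 0 && n >= 2L) {
    n_pairs <- n * (n - 1) / 2
    m <- rbinom(1L, n_pairs, config$background_edge_prob)
    if (m > 0L) {
      idx <- sample(n_pairs, m) - 1
      ij <- pair_from_index(idx, n)
      edges <- data.frame(gene_a = genes[ij[, 1L]],
                          gene_b = genes[ij[, 2L]],
                          stringsAsFactors = FALSE)
    }
  }
  existing <- if (is.null(edges)) character(0) else
    paste(pmin(edges$gene_a, edges$gene_b),
          pmax(edges$gene_a, edges$gene_b), sep = "\r")
  for (pl in config$planted_links) {
    nm <- c(pl[[1L]], pl[[2L]])
    missing <- setdiff(nm, names(gene_sets$sets))
    if (length(missing))
      stop("planted link references unknown set(s): ",
           paste(missing, collapse = ", "))
    k <- pl[[3L]]
    a <- gene_sets$sets[[nm[[1L]]]]
    b <- gene_sets$sets[[nm[[2L]]]]
    cross <- expand.grid(gene_a = a, gene_b = b,
                         stringsAsFactors = FALSE)
    cross <- cross[cross$gene_a != cross$gene_b, , drop = FALSE]
    key <- paste(pmin(cross$gene_a, cross$gene_b),
                 pmax(cross$gene_a, cross$gene_b), sep = "\r")
    cross <- cross[!duplicated(key) & !(key %in% existing), , drop = FALSE]
    if (nrow(cross) < k)
      stop("cannot plant ", k, " extra edges between ", nm[[1L]], " and ",
           nm[[2L]], ": only ", nrow(cross), " free pairs")
    pick <- cross[sample(nrow(cross), k), , drop = FALSE]
    edges <- rbind(edges, pick)
    existing <- c(existing, paste(pmin(pick$gene_a, pick$gene_b),
                                  pmax(pick$gene_a, pick$gene_b),
                                  sep = "\r"))
  }
  if (is.null(edges))
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        stringsAsFactors = FALSE)
  edges$score <- rep(900L, nrow(edges))
  interaction_network(edges)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_gene_sets()],
#' [generate_expression()] and [generate_network()] under the single
#' configured seed.
#'
#' @param config A `SyntheticConfig`.
#' @return List with `gene_sets`, `matrix`, `truth`, `network`.
#' @export
generate_synthetic_dataset <- function(config) {
  gene_sets <- generate_gene_sets(config)
  expr <- generate_expression(config, gene_sets)
  network <- generate_network(config, gene_sets)
  list(gene_sets = gene_sets, matrix = expr$matrix, truth = expr$truth,
       network = network)
}

#' Default contrast for a synthetic expression matrix
#'
#' @param mat An `ExpressionMatrix` produced by [generate_expression()].
#' @return A `Contrast` of the test group versus the reference group.
#' @export
synthetic_contrast <- function(mat) {
  contrast(
    sample_group("test",
                 mat$samples$sample_id[mat$samples$group == "test"]),
    sample_group("reference",
                 mat$samples$sample_id[mat$samples$group == "reference"]),
    name = "test vs reference")
}
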