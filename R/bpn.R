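# Biological process network inference: candidate links between enriched
# gene sets supported by interactions among perturbed genes, a Metropolis
# sampler over link subsets, posterior thresholding into a process network,
# and per-link support dissection.

#' MCMC-BPN configuration
#'
#' Production defaults follow the published protocol (10^7 burn-in and 10^8
#' sampling steps); tests and examples use desk-scale step counts. The
#' sampler targets exp(beta * (coverage - lambda * n_links)): lambda prices
#' each selected link in units of explained interactions, beta sharpens or
#' flattens the posterior. Both are calibration knobs, not published values.
#'
#' @param burn_in_steps Steps discarded before sampling.
#' @param mcmc_steps Post-burn-in steps.
#' @param link_penalty lambda >= 0; cost per selected link.
#' @param inverse_temperature beta > 0.
#' @param thin Keep one state every `thin` post-burn-in steps.
#' @param probability_threshold Default posterior cutoff tau (inclusive).
#' @param rng_seed Integer seed or `NULL` for the current RNG state.
#' @return A list of class `BpnConfig`.
#' @export
bpn_config <- function(burn_in_steps = 1e7, mcmc_steps = 1e8,
                       link_penalty = 2, inverse_temperature = 1,
                       thin = 100L, probability_threshold = 0.45,
                       rng_seed = NULL) {
  stopifnot(burn_in_steps >= 0, mcmc_steps > 0, link_penalty >= 0,
            inverse_temperature >= 0, thin >= 1L,
            probability_threshold >= 0, probability_threshold <= 1)
  structure(list(burn_in_steps = burn_in_steps, mcmc_steps = mcmc_steps,
                 link_penalty = link_penalty,
                 inverse_temperature = inverse_temperature,
                 thin = as.integer(thin),
                 probability_threshold = probability_threshold,
                 rng_seed = rng_seed),
            class = "BpnConfig")
}

#' Candidate links between significant gene sets
#'
#' For every unordered pair of distinct significant sets (A, B), collects
#' the network edges (u, v) whose endpoints are both perturbed and
#' assignable as u in A and v in B (or the mirror). A gene shared by both
#' sets may serve either side, but an edge never links a set to itself.
#' Pairs with no supporting interaction are not candidates. Each support
#' pair carries flags saying whether its endpoint lies in the leading edge
#' of the set it is assigned to; when both orientations of an edge are
#' valid, the orientation with more leading-edge endpoints is recorded.
#'
#' @param significant An `EnrichmentResults` table already filtered to the
#'   significant sets (rows carry `members` and `leading_edge`).
#' @param perturbed Character vector of perturbed genes (e.g. from
#'   [leading_edge_union()]).
#' @param network An `InteractionNetwork`.
#' @return A list of class `CandidateLinks`; each element has `set_a`,
#'   `set_b` (alphabetical), and a `support` data.frame (gene_a_side,
#'   gene_b_side, edge_id, in_le_a, in_le_b). The attribute `n_edges` is
#'   the number of perturbed-perturbed network edges (the coverage
#'   universe) and `n_sets` the number of significant sets.
#' @export
build_candidate_links <- function(significant, perturbed, network) {
  if (!nrow(significant) || !nrow(network))
    return(structure(list(), class = "CandidateLinks",
                     n_edges = 0L, n_sets = nrow(significant)))
  members <- lapply(significant$members, toupper)
  names(members) <- significant$set
  les <- lapply(significant$leading_edge, function(d) toupper(d$gene))
  names(les) <- significant$set
  perturbed <- toupper(perturbed)

  pp <- network$gene_a %in% perturbed & network$gene_b %in% perturbed
  edges <- network[pp, , drop = FALSE]
  if (!nrow(edges))
    return(structure(list(), class = "CandidateLinks",
                     n_edges = 0L, n_sets = nrow(significant)))
  edges$edge_id <- seq_len(nrow(edges))

  # gene -> significant sets containing it
  sets_of <- split(rep(names(members), lengths(members)),
                   unlist(members, use.names = FALSE))
  cand <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(edges))) {
    u <- edges$gene_a[[i]]; v <- edges$gene_b[[i]]
    su <- sets_of[[u]]; sv <- sets_of[[v]]
    if (is.null(su) || is.null(sv)) next
    for (A in su) for (B in sv) {
      if (A == B) next
      pair <- sort(c(A, B))
      key <- paste(pair, collapse = "\r")
      # orientation u->A, v->B; the mirror may also be valid
      a_gene <- if (A == pair[[1L]]) u else v
      b_gene <- if (A == pair[[1L]]) v else u
      in_le_a <- a_gene %in% les[[pair[[1L]]]]
      in_le_b <- b_gene %in% les[[pair[[2L]]]]
      mirror_ok <- b_gene %in% members[[pair[[1L]]]] &&
        a_gene %in% members[[pair[[2L]]]]
      if (mirror_ok) {
        m_le_a <- b_gene %in% les[[pair[[1L]]]]
        m_le_b <- a_gene %in% les[[pair[[2L]]]]
        if (m_le_a + m_le_b > in_le_a + in_le_b) {
          tmp <- a_gene; a_gene <- b_gene; b_gene <- tmp
          in_le_a <- m_le_a; in_le_b <- m_le_b
        }
      }
      row <- data.frame(gene_a_side = a_gene, gene_b_side = b_gene,
                        edge_id = edges$edge_id[[i]],
                        in_le_a = in_le_a, in_le_b = in_le_b,
                        stringsAsFactors = FALSE)
      if (is.null(cand[[key]])) {
        cand[[key]] <- list(set_a = pair[[1L]], set_b = pair[[2L]],
                            support = row)
      } else {
        prev <- cand[[key]]
        if (!edges$edge_id[[i]] %in% prev$support$edge_id) {
          prev$support <- rbind(prev$support, row)
          cand[[key]] <- prev
        }
      }
    }
  }
  keys <- sort(ls(cand))
  out <- lapply(keys, function(k) cand[[k]])
  structure(out, class = "CandidateLinks",
            n_edges = nrow(edges), n_sets = nrow(significant))
}

#' @export
print.CandidateLinks <- function(x, ...) {
  cat(sprintf("CandidateLinks: %d candidates over %d perturbed-gene edges\n",
              length(x), attr(x, "n_edges")))
  invisible(x)
}

#' Interaction coverage of a set of selected links
#'
#' Number of distinct network edges explained by (supporting) at least one
#' selected link; an edge supporting several links counts once.
#'
#' @param selected A `CandidateLinks` object or subset of one (a list of
#'   candidate links).
#' @return Integer count.
#' @export
coverage <- function(selected) {
  if (!length(selected)) return(0L)
  length(unique(unlist(lapply(selected, function(l) l$support$edge_id))))
}

#' Parsimony score of a set of selected links
#'
#' score = coverage(selected) - lambda * |selected|: explain many
#' interactions with few links.
#'
#' @param selected List of candidate links.
#' @param link_penalty lambda >= 0.
#' @return Numeric score.
#' @export
bpn_score <- function(selected, link_penalty = 2) {
  coverage(selected) - link_penalty * length(selected)
}

#' Sample link subsets by Metropolis MCMC and estimate link probabilities
#'
#' State: an indicator vector over candidate links, initialized empty. Each
#' step toggles one uniformly chosen candidate and accepts with probability
#' min(1, exp(beta * delta_score)) -- a symmetric-proposal Metropolis
#' kernel whose stationary distribution is pi(S) proportional to
#' exp(beta * (coverage(S) - lambda |S|)). A link's posterior probability
#' is its inclusion frequency over thinned post-burn-in states.
#'
#' @param candidates A `CandidateLinks` object with >= 1 candidate.
#' @param config A `BpnConfig`.
#' @return A `BpnResult`: `links` data.frame (set_a, set_b, n_support,
#'   n_leading_edge_support, probability), `best_subset` (logical vector),
#'   `best_score`, `n_samples`, `acceptance_rate`, plus the candidates and
#'   config used.
#' @export
mcmc_bpn <- function(candidates, config = bpn_config()) {
  if (!length(candidates))
    stop("no candidate links: review the significance threshold and the ",
         "interaction score cutoff")
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  edge_lists <- lapply(candidates, function(l) as.integer(l$support$edge_id))
  fit <- cpp_mcmc_bpn(edge_lists, attr(candidates, "n_edges"),
                      config$link_penalty, config$inverse_temperature,
                      config$burn_in_steps, config$mcmc_steps, config$thin)
  links <- data.frame(
    set_a = vapply(candidates, `[[`, character(1), "set_a"),
    set_b = vapply(candidates, `[[`, character(1), "set_b"),
    n_support = vapply(candidates, function(l) nrow(l$support), integer(1)),
    n_leading_edge_support = vapply(candidates, function(l)
      sum(l$support$in_le_a & l$support$in_le_b), integer(1)),
    probability = fit$probability,
    stringsAsFactors = FALSE)
  rownames(links) <- NULL
  structure(list(links = links,
                 best_subset = fit$best_state,
                 best_score = fit$best_score,
                 n_samples = fit$n_samples,
                 acceptance_rate = fit$acceptance_rate,
                 candidates = candidates,
                 config = config),
            class = "BpnResult")
}

#' @export
print.BpnResult <- function(x, ...) {
  cat(sprintf(
    "BpnResult: %d candidate links, best score %.1f, %d posterior samples\n",
    nrow(x$links), x$best_score, as.integer(x$n_samples)))
  invisible(x)
}

#' Threshold posterior link probabilities into a process network
#'
#' Retains links with probability at or above tau (inclusive). Nodes are
#' the gene sets incident to a retained link, labeled with their
#' enrichment direction when `results` is supplied; connected components
#' are numbered deterministically (by alphabetically smallest member set).
#'
#' @param result A `BpnResult`.
#' @param tau Probability threshold in [0, 1].
#' @param results Optional `EnrichmentResults` supplying up/down directions.
#' @return A list of class `ProcessNetwork`: `links` (retained rows),
#'   `nodes` (set, direction, component), `n_components`.
#' @export
threshold_bpn <- function(result, tau = result$config$probability_threshold,
                          results = NULL) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1)
    stop("tau must be a probability in [0, 1]")
  links <- result$links[result$links$probability >= tau, , drop = FALSE]
  rownames(links) <- NULL
  nodes <- sort(unique(c(links$set_a, links$set_b)))
  # union-find over retained links
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(links))) {
    ra <- find(links$set_a[[i]]); rb <- find(links$set_b[[i]])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  roots <- vapply(nodes, find, character(1))
  comp_ids <- stats::setNames(seq_along(sort(unique(roots))),
                              sort(unique(roots)))
  direction <- rep(NA_character_, length(nodes))
  if (!is.null(results))
    direction <- results$direction[match(nodes, results$set)]
  node_tab <- data.frame(set = nodes, direction = direction,
                         component = unname(comp_ids[roots]),
                         stringsAsFactors = FALSE)
  rownames(node_tab) <- NULL
  structure(list(links = links, nodes = node_tab,
                 n_components = length(unique(node_tab$component)),
                 tau = tau),
            class = "ProcessNetwork")
}

#' @export
print.ProcessNetwork <- function(x, ...) {
  cat(sprintf(
    "ProcessNetwork: %d links among %d gene sets in %d component(s) (tau = %g)\n",
    nrow(x$links), nrow(x$nodes), x$n_components, x$tau))
  invisible(x)
}

#' Probability threshold retaining a top fraction of possible links
#'
#' Finds tau such that the retained links are the top
#' `ceiling(top_fraction * n_possible)` candidates by posterior
#' probability (ties retained together). The default denominator counts
#' all unordered pairs of significant sets; the observed candidate count
#' is the alternative.
#'
#' @param result A `BpnResult`.
#' @param top_fraction Fraction in (0, 1].
#' @param denominator `"possible_pairs"` (all pairs of significant sets) or
#'   `"candidates"` (supported candidates only).
#' @return The threshold tau.
#' @export
quantile_threshold <- function(result, top_fraction,
                               denominator = c("possible_pairs",
                                               "candidates")) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  denominator <- match.arg(denominator)
  n_sets <- attr(result$candidates, "n_sets")
  n_possible <- switch(denominator,
                       possible_pairs = choose(n_sets, 2),
                       candidates = nrow(result$links))
  m <- ceiling(top_fraction * n_possible)
  probs <- sort(result$links$probability, decreasing = TRUE)
  if (m >= length(probs)) return(min(probs))
  probs[[m]]
}

#' Dissect the interaction support of one link
#'
#' Reports how many supporting interactions the link has in total and how
#' many connect genes lying in the leading edges of both linked sets, plus
#' the per-interaction listing.
#'
#' @param link One element of a `CandidateLinks` object.
#' @return A list of class `LinkReport`: `set_a`, `set_b`, `n_support`,
#'   `n_leading_edge_support`, `support` (data.frame).
#' @export
link_report <- function(link) {
  n <- nrow(link$support)
  n_le <- sum(link$support$in_le_a & link$support$in_le_b)
  structure(list(set_a = link$set_a, set_b = link$set_b,
                 n_support = n, n_leading_edge_support = n_le,
                 support = link$support),
            class = "LinkReport")
}

#' @export
print.LinkReport <- function(x, ...) {
  cat(sprintf("Link %s -- %s: %d of %d interactions connect leading-edge genes\n",
              x$set_a, x$set_b, x$n_leading_edge_support, x$n_support))
  invisible(x)
}

#' Write a process network as SIF
#'
#' @param pn A `ProcessNetwork`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(pn, path) {
  lines <- sprintf("%s\tlink\t%s", pn$links$set_a, pn$links$set_b)
  writeLines(lines, path)
  invisible(path)
}

#' Write a process network as GraphML with direction and q-value attributes
#'
#' @param pn A `ProcessNetwork`.
#' @param path Output path.
#' @param results Optional `EnrichmentResults` supplying q-values.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(pn, path, results = NULL) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  q <- rep(NA_real_, nrow(pn$nodes))
  if (!is.null(results)) q <- results$q[match(pn$nodes$set, results$set)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="direction" for="node" attr.name="direction" attr.type="string"/>',
    '  <key id="qvalue" for="node" attr.name="q_value" attr.type="double"/>',
    '  <key id="prob" for="edge" attr.name="probability" attr.type="double"/>',
    '  <graph edgedefault="undirected">'), con)
  for (i in seq_len(nrow(pn$nodes))) {
    writeLines(sprintf(
      '    <node id="%s"><data key="direction">%s</data><data key="qvalue">%s</data></node>',
      esc(pn$nodes$set[[i]]),
      ifelse(is.na(pn$nodes$direction[[i]]), "unknown",
             pn$nodes$direction[[i]]),
      ifelse(is.na(q[[i]]), "NaN", format(q[[i]], digits = 10))), con)
  }
  for (i in seq_len(nrow(pn$links))) {
    writeLines(sprintf(
      '    <edge source="%s" target="%s"><data key="prob">%s</data></edge>',
      esc(pn$links$set_a[[i]]), esc(pn$links$set_b[[i]]),
      format(pn$links$probability[[i]], digits = 10)), con)
  }
  writeLines(c("  </graph>", "</graphml>"), con)
  invisible(path)
}

#' Write candidate link probabilities as TSV
#'
#' Columns: set_a, set_b, n_support, n_leading_edge_support, probability.
#'
#' @param result A `BpnResult`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_links <- function(result, path) {
  write.table(result$links, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
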