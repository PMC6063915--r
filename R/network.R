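# STRING-style interaction networks: confidence-score filtering and
# restriction to the measured gene universe.

#' Construct an undirected interaction network
#'
#' Canonicalizes an edge table: gene symbols upper-cased, endpoints ordered
#' within each edge, self-loops dropped (with a message), reciprocal
#' duplicates collapsed keeping the maximum score.
#'
#' @param edges Data.frame with columns gene_a, gene_b, score (integers in
#'   0-1000).
#' @return An `InteractionNetwork` (a data.frame subclass).
#' @export
interaction_network <- function(edges) {
  if (!all(c("gene_a", "gene_b", "score") %in% names(edges)))
    stop("edges need gene_a, gene_b, score columns")
  score <- as.integer(edges$score)
  if (anyNA(score) || any(score < 0L | score > 1000L))
    stop("scores must be integers in [0, 1000]")
  a <- toupper(as.character(edges$gene_a))
  b <- toupper(as.character(edges$gene_b))
  loops <- a == b
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    a <- a[!loops]; b <- b[!loops]; score <- score[!loops]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (length(key)) {
    keep_score <- tapply(score, key, max)
    first <- !duplicated(key)
    out <- data.frame(gene_a = lo[first], gene_b = hi[first],
                      score = as.integer(keep_score[key[first]]),
                      stringsAsFactors = FALSE)
    out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  } else {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      score = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("InteractionNetwork", "data.frame")
  out
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d nodes, %d undirected edges\n",
              length(network_nodes(x)), nrow(x)))
  invisible(x)
}

#' Node set of an interaction network
#'
#' @param network An `InteractionNetwork`.
#' @return Sorted character vector of genes incident to at least one edge.
#' @export
network_nodes <- function(network) {
  sort(unique(c(network$gene_a, network$gene_b)))
}

#' Load and confidence-filter an interaction edge list
#'
#' Reads a 3-column tab-separated file (gene_a, gene_b, integer score; an
#' optional header line is detected and skipped), optionally remaps ids
#' through a 2-column alias table, removes every interaction scoring below
#' `score_min`, collapses reciprocal duplicates keeping the larger score,
#' and drops self-loops. A summary line with node and edge counts is
#' emitted via `message()`.
#'
#' @param path Edge-list TSV path.
#' @param score_min Minimum retained confidence score (edges with
#'   score < score_min are removed; the boundary itself is kept).
#' @param aliases Optional data.frame or 2-column TSV path mapping source
#'   ids (column 1) to gene symbols (column 2).
#' @return An `InteractionNetwork`.
#' @export
load_interactions <- function(path, score_min = 500L, aliases = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(interaction_network(data.frame(gene_a = character(0),
                                          gene_b = character(0),
                                          score = integer(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (is.na(suppressWarnings(as.integer(fields[[1L]][3L]))))
    start <- 2L  # header line
  if (start > length(fields))
    return(interaction_network(data.frame(gene_a = character(0),
                                          gene_b = character(0),
                                          score = integer(0))))
  fields <- fields[start:length(fields)]
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed edge row at line ", bad[[1L]] + start - 1L, " of ", path)
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  s <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(s))
    stop("non-integer score at line ",
         which(is.na(s))[[1L]] + start - 1L, " of ", path)
  if (!is.null(aliases)) {
    if (is.character(aliases))
      aliases <- read.delim(aliases, header = FALSE,
                            stringsAsFactors = FALSE)
    map <- stats::setNames(toupper(as.character(aliases[[2L]])),
                           toupper(as.character(aliases[[1L]])))
    a <- ifelse(toupper(a) %in% names(map), map[toupper(a)], a)
    b <- ifelse(toupper(b) %in% names(map), map[toupper(b)], b)
  }
  net <- interaction_network(data.frame(gene_a = a, gene_b = b, score = s,
                                        stringsAsFactors = FALSE))
  n_before <- nrow(net)
  net <- net[net$score >= score_min, , drop = FALSE]
  class(net) <- c("InteractionNetwork", "data.frame")
  rownames(net) <- NULL
  message(sprintf(
    "interaction network: %d edges read, %d below score %d dropped, %d nodes / %d edges retained",
    n_before, n_before - nrow(net), score_min,
    length(network_nodes(net)), nrow(net)))
  net
}

#' Restrict a network to a measured gene universe
#'
#' Keeps an interaction only when both endpoints were measured (present on
#' the array); isolated nodes disappear because the network is edge-defined.
#'
#' @param network An `InteractionNetwork`.
#' @param gene_universe Character vector of measured genes.
#' @return An `InteractionNetwork`.
#' @export
restrict_to_measured <- function(network, gene_universe) {
  universe <- toupper(as.character(gene_universe))
  keep <- network$gene_a %in% universe & network$gene_b %in% universe
  out <- network[keep, , drop = FALSE]
  class(out) <- c("InteractionNetwork", "data.frame")
  rownames(out) <- NULL
  message(sprintf(
    "restricted to %d measured genes: %d of %d edges retained (%d nodes)",
    length(unique(universe)), nrow(out), nrow(network),
    length(network_nodes(out))))
  out
}

#' Write an interaction network as 3-column TSV
#'
#' @param network An `InteractionNetwork`.
#' @param path Output path.
#' @param header Write a header line?
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, header = TRUE) {
  write.table(as.data.frame(network), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = header)
  invisible(path)
}
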