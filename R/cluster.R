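# Agglomerative hierarchical clustering of samples with deterministic
# tie-breaking, Newick serialization, and clade purity checks.
#
# Clustering is implemented directly (rather than via stats::hclust) because
# cluster-pair ties must break lexicographically by smallest member id for
# platform-independent dendrograms, and linkage distances are recomputed
# from the original sample-sample distances at every merge.

#' Hierarchically cluster the samples of an expression matrix
#'
#' Agglomerative clustering over sample-sample distances. Linkage distances
#' are evaluated on the original distance matrix (min over cross pairs for
#' single, max for complete, mean for average). When two candidate merges
#' are at exactly the same distance, the pair whose smallest member ids come
#' first lexicographically is merged, making the output deterministic.
#'
#' @param mat An `ExpressionMatrix` with at least 2 samples.
#' @param linkage `"single"`, `"complete"`, or `"average"`.
#' @param metric `"euclidean"`, `"manhattan"`, or `"correlation"`.
#' @return A `Dendrogram`: merge table in `stats::hclust` convention
#'   (negative entries are leaves), merge heights, and leaf labels.
#' @export
cluster_samples <- function(mat,
                            linkage = c("complete", "single", "average"),
                            metric = c("euclidean", "manhattan",
                                       "correlation")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  d <- sample_distance_matrix(mat$values, metric)
  cluster_from_distances(d, linkage)
}

#' Agglomerative clustering from a distance matrix
#'
#' @param d Symmetric numeric distance matrix with dimnames = sample ids.
#' @param linkage `"single"`, `"complete"`, or `"average"`.
#' @return A `Dendrogram`.
#' @export
cluster_from_distances <- function(d,
                                   linkage = c("complete", "single",
                                               "average")) {
  linkage <- match.arg(linkage)
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 2L) stop("clustering needs at least 2 samples")
  link_fun <- switch(linkage, single = min, complete = max, average = mean)

  # active clusters: node code (hclust convention) + member leaf indices
  active <- lapply(seq_len(n), function(i)
    list(code = -i, members = i, min_id = labels[[i]]))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (j <= i) next
        dij <- link_fun(d[active[[i]]$members, active[[j]]$members])
        key <- sort(c(active[[i]]$min_id, active[[j]]$min_id))
        cand <- list(dist = dij, key = key, i = i, j = j)
        if (is.null(best) || dij < best$dist ||
            (dij == best$dist &&
             (key[[1L]] < best$key[[1L]] ||
              (key[[1L]] == best$key[[1L]] && key[[2L]] < best$key[[2L]]))))
          best <- cand
      }
    }
    a <- active[[best$i]]; b <- active[[best$j]]
    codes <- sort(c(a$code, b$code))
    merge[step, ] <- codes
    height[[step]] <- best$dist
    merged <- list(code = step, members = c(a$members, b$members),
                   min_id = min(a$min_id, b$min_id))
    active <- c(active[-c(best$i, best$j)], list(merged))
  }
  structure(list(merge = merge, height = height, labels = labels,
                 linkage = linkage),
            class = "Dendrogram")
}

#' @export
print.Dendrogram <- function(x, ...) {
  cat(sprintf("Dendrogram: %d leaves, %s linkage, heights [%g, %g]\n",
              length(x$labels), x$linkage,
              min(x$height), max(x$height)))
  invisible(x)
}

node_leaf_sets <- function(tree) {
  n <- length(tree$labels)
  sets <- vector("list", n - 1L)
  get_members <- function(code) {
    if (code < 0L) return(-code)
    sets[[code]]
  }
  for (k in seq_len(n - 1L))
    sets[[k]] <- c(get_members(tree$merge[k, 1L]),
                   get_members(tree$merge[k, 2L]))
  lapply(sets, function(i) tree$labels[i])
}

#' Serialize a dendrogram as a Newick string
#'
#' Branch lengths are differences of merge heights (leaves sit at height 0),
#' so root-to-leaf path lengths equal the final merge height.
#'
#' @param tree A `Dendrogram`.
#' @return A single Newick string terminated by `;`.
#' @export
as_newick <- function(tree) {
  build <- function(code, parent_height) {
    if (code < 0L)
      return(sprintf("%s:%.12g", tree$labels[[-code]], parent_height))
    h <- tree$height[[code]]
    sprintf("(%s,%s):%.12g",
            build(tree$merge[code, 1L], h),
            build(tree$merge[code, 2L], h),
            parent_height - h)
  }
  root <- length(tree$height)
  h <- tree$height[[root]]
  sprintf("(%s,%s);",
          build(tree$merge[root, 1L], h),
          build(tree$merge[root, 2L], h))
}

#' Do sample groups form pure clades of a dendrogram?
#'
#' A group is pure iff some clade's leaf set equals exactly the group's
#' members; singleton groups are always pure (every leaf is a clade).
#'
#' @param tree A `Dendrogram`.
#' @param groups List of `SampleGroup` objects whose members are tree leaves.
#' @return Named logical vector, one entry per group.
#' @export
clade_purity <- function(tree, groups) {
  clades <- c(as.list(tree$labels), node_leaf_sets(tree))
  clade_keys <- vapply(clades,
                       function(s) paste(sort(s), collapse = "\r"),
                       character(1))
  res <- vapply(groups, function(g) {
    unknown <- setdiff(g$members, tree$labels)
    if (length(unknown))
      stop("unknown sample id(s) in group '", g$name, "': ",
           paste(unknown, collapse = ", "))
    paste(sort(g$members), collapse = "\r") %in% clade_keys
  }, logical(1))
  names(res) <- vapply(groups, `[[`, character(1), "name")
  res
}
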