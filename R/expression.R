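# Expression-level operations: probe-to-gene collapse, replicate imputation,
# and group distance statistics on log-scale intensity matrices.

#' Collapse probe-level rows to gene-level rows
#'
#' Summarizes probe-set-level data into gene-level data using a many-to-one
#' probe-to-gene map. With the default `max_per_sample` rule each gene x
#' sample value is the maximum over that gene's probes in that sample (the
#' conventional GSEA-style collapse); `mean` and `median` are exposed as
#' alternatives. Unmapped probes are dropped and their count reported via
#' `message()`.
#'
#' @param mat An `ExpressionMatrix` with probe ids on the rows.
#' @param map Data.frame with columns `probe_id` and `gene`; every mapped
#'   probe must map to exactly one gene.
#' @param method `"max_per_sample"`, `"mean"`, or `"median"`.
#' @return A gene-level `ExpressionMatrix`.
#' @export
collapse_probes <- function(mat, map,
                            method = c("max_per_sample", "mean", "median")) {
  method <- match.arg(method)
  if (!all(c("probe_id", "gene") %in% names(map)))
    stop("`map` needs probe_id and gene columns")
  if (anyDuplicated(map$probe_id))
    stop("a probe maps to more than one gene: ",
         paste(unique(map$probe_id[duplicated(map$probe_id)]), collapse = ", "))
  keep <- rownames(mat$values) %in% map$probe_id
  if (!any(keep))
    stop("no probe in the matrix is covered by the map")
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(n_dropped, " unmapped probes dropped during collapse")
  v <- mat$values[keep, , drop = FALSE]
  genes <- map$gene[match(rownames(v), map$probe_id)]
  fun <- switch(method,
                max_per_sample = function(x) apply(x, 2L, max),
                mean = function(x) colMeans(x),
                median = function(x) apply(x, 2L, stats::median))
  idx <- split(seq_len(nrow(v)), genes)
  out <- t(vapply(idx, function(i) fun(v[i, , drop = FALSE]),
                  numeric(ncol(v))))
  colnames(out) <- colnames(v)
  expression_matrix(out, samples = mat$samples)
}

#' Append a mean-imputed replicate to a two-sample group
#'
#' When a group has only two replicates, appends a simulated third sample
#' whose every value is the arithmetic mean of the two members. The new
#' sample is annotated with `imputed = TRUE` (existing samples get `FALSE`).
#'
#' @param mat An `ExpressionMatrix`.
#' @param group A `SampleGroup` with exactly 2 members.
#' @param new_id Sample id for the imputed replicate.
#' @return An `ExpressionMatrix` with one extra sample.
#' @export
impute_mean_replicate <- function(mat, group,
                                  new_id = paste0(group$name, "_imputed")) {
  if (length(group$members) != 2L)
    stop("mean-replicate imputation needs a group of exactly 2 samples, got ",
         length(group$members))
  check_group_in_matrix(mat, group)
  if (new_id %in% colnames(mat$values))
    stop("sample id already present: ", new_id)
  imput <- rowMeans(mat$values[, group$members, drop = FALSE])
  v <- cbind(mat$values, imput)
  colnames(v)[ncol(v)] <- new_id
  samples <- mat$samples
  if (!"imputed" %in% names(samples)) samples$imputed <- FALSE
  new_row <- samples[match(group$members[[1L]], samples$sample_id), ,
                     drop = FALSE]
  new_row$sample_id <- new_id
  new_row$imputed <- TRUE
  samples <- rbind(samples, new_row)
  expression_matrix(v, samples = samples)
}

sample_distance_matrix <- function(values,
                                   metric = c("euclidean", "manhattan",
                                              "correlation")) {
  metric <- match.arg(metric)
  if (metric == "correlation") {
    d <- 1 - stats::cor(values, method = "pearson")
    # numeric fuzz can push identical samples to ~ -1e-16
    d[d < 0 & d > -1e-12] <- 0
    d
  } else {
    as.matrix(stats::dist(t(values), method = metric))
  }
}

#' Average within- or between-group sample distance
#'
#' Within-group mode (`group_b = NULL`): mean distance over all unordered
#' member pairs. Between-group mode: mean over all cross pairs of two
#' disjoint groups. Correlation distance is 1 minus the Pearson correlation.
#'
#' @param mat An `ExpressionMatrix`.
#' @param group_a A `SampleGroup`.
#' @param group_b A `SampleGroup` or `NULL` for within-group mode.
#' @param metric `"euclidean"`, `"manhattan"`, or `"correlation"`.
#' @return A single numeric distance.
#' @export
average_group_distance <- function(mat, group_a, group_b = NULL,
                                   metric = c("euclidean", "manhattan",
                                              "correlation")) {
  metric <- match.arg(metric)
  check_group_in_matrix(mat, group_a)
  if (is.null(group_b)) {
    if (length(group_a$members) < 2L)
      stop("within-group distance needs at least 2 members in '",
           group_a$name, "'")
    d <- sample_distance_matrix(mat$values[, group_a$members, drop = FALSE],
                                metric)
    mean(d[upper.tri(d)])
  } else {
    check_group_in_matrix(mat, group_b)
    if (length(intersect(group_a$members, group_b$members)))
      stop("between-group distance needs disjoint groups")
    ids <- c(group_a$members, group_b$members)
    d <- sample_distance_matrix(mat$values[, ids, drop = FALSE], metric)
    mean(d[group_a$members, group_b$members])
  }
}
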