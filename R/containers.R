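#' Construct an expression matrix with sample annotations
#'
#' The central data container: a numeric matrix of log-scale intensities with
#' probe-set or gene identifiers on the rows and sample identifiers on the
#' columns, plus a per-sample annotation table (cell type, culture condition,
#' day, replicate, or any other covariates).
#'
#' @param values Numeric matrix with unique, non-empty rownames (probe or gene
#'   ids) and colnames (sample ids). All values must be finite.
#' @param samples Optional data.frame of per-sample annotations with a
#'   `sample_id` column covering every column of `values`. When `NULL` a
#'   minimal annotation table is created.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, samples = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (features) and colnames (samples)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate row ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!all(is.finite(values)))
    stop("all expression values must be finite")
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(values),
                          stringsAsFactors = FALSE)
  }
  if (!is.data.frame(samples) || !"sample_id" %in% names(samples))
    stop("`samples` must be a data.frame with a sample_id column")
  missing <- setdiff(colnames(values), samples$sample_id)
  if (length(missing))
    stop("annotations missing for samples: ", paste(missing, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("annotations:", paste(names(x$samples), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Construct a named sample group
#'
#' @param name Group label (e.g. one cell type in one culture condition).
#' @param members Character vector of sample ids; must be non-empty and
#'   duplicate-free.
#' @return An object of class `SampleGroup`.
#' @export
sample_group <- function(name, members) {
  members <- as.character(members)
  if (!length(members)) stop("a SampleGroup needs at least one member")
  if (anyDuplicated(members)) stop("duplicate members in group '", name, "'")
  structure(list(name = as.character(name), members = members),
            class = "SampleGroup")
}

check_group_in_matrix <- function(mat, group) {
  missing <- setdiff(group$members, colnames(mat$values))
  if (length(missing))
    stop("group '", group$name, "' has members absent from the matrix: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors (member genes per set). Names
#'   must be unique and no set may be empty.
#' @param category Optional character vector (one label per set, e.g.
#'   "pathway", "GO", "signaling"); recycled from "unknown" when absent.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, category = NULL) {
  if (!is.list(sets)) stop("`sets` must be a named list")
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("every gene set needs a name")
    if (anyDuplicated(names(sets)))
      stop("duplicate set names: ",
           paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
    sets <- lapply(sets, function(g) unique(as.character(g)))
    if (any(!lengths(sets))) stop("empty gene sets are not allowed")
  }
  if (is.null(category)) {
    category <- rep("unknown", length(sets))
  } else if (length(category) == 1L) {
    category <- rep(category, length(sets))
  }
  if (length(category) != length(sets))
    stop("`category` must have one entry per set")
  names(category) <- names(sets)
  structure(list(sets = sets, category = category),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets", length(x$sets)))
  if (length(x$sets))
    cat(sprintf(", sizes %d-%d", min(lengths(x$sets)), max(lengths(x$sets))))
  cat("\n")
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Construct a two-group contrast
#'
#' @param test_group,reference_group Disjoint [sample_group()] objects, each
#'   with at least two members (after any replicate imputation).
#' @param name Contrast label.
#' @return An object of class `Contrast`.
#' @export
contrast <- function(test_group, reference_group,
                     name = paste(test_group$name, "vs", reference_group$name)) {
  if (!inherits(test_group, "SampleGroup") ||
      !inherits(reference_group, "SampleGroup"))
    stop("both groups must be SampleGroup objects")
  if (length(intersect(test_group$members, reference_group$members)))
    stop("contrast groups must be disjoint")
  if (length(test_group$members) < 2L || length(reference_group$members) < 2L)
    stop("each contrast group needs at least 2 samples")
  structure(list(test = test_group, reference = reference_group,
                 name = as.character(name)),
            class = "Contrast")
}
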