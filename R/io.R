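# Readers and writers for the GSEA-world text formats: GCT 1.2 expression
# matrices, CLS class label files, GMT gene set collections, plain TSV
# matrices and sample-annotation tables.

#' Read an expression matrix from GCT or TSV
#'
#' GCT 1.2: a `#1.2` version line, a `rows<TAB>columns` dimension line, a
#' header row (`NAME`, `Description`, sample ids), then one row per feature.
#' TSV: a header row (feature-id column then sample ids) and numeric rows.
#'
#' @param path File path.
#' @param format `"gct"` or `"tsv"`.
#' @param samples Optional sample-annotation data.frame passed through to
#'   [expression_matrix()].
#' @return An `ExpressionMatrix`.
#' @export
load_expression <- function(path, format = c("gct", "tsv"), samples = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3L || !startsWith(lines[[1L]], "#1.2"))
      stop("malformed GCT header (line 1): expected '#1.2' in ", path)
    dims <- suppressWarnings(as.integer(strsplit(lines[[2L]], "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      stop("malformed GCT dimension line (line 2) in ", path)
    header <- strsplit(lines[[3L]], "\t", fixed = TRUE)[[1L]]
    n_samp <- length(header) - 2L
    body <- lines[-(1:3)]
    body <- body[nzchar(body)]
    if (length(body) != dims[[1L]] || n_samp != dims[[2L]])
      stop("GCT declared dimensions (", dims[[1L]], " x ", dims[[2L]],
           ") disagree with body (", length(body), " x ", n_samp, ")")
    fields <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != length(header))
    if (length(bad))
      stop("malformed GCT row at line ", bad[[1L]] + 3L)
    ids <- vapply(fields, `[[`, character(1), 1L)
    vals <- vapply(fields, function(f) {
      v <- suppressWarnings(as.numeric(f[-(1:2)]))
      v
    }, numeric(n_samp))
    vals <- matrix(vals, ncol = n_samp, byrow = TRUE)
    nn <- which(apply(vals, 1L, anyNA))
    if (length(nn))
      stop("non-numeric cell in GCT at line ", nn[[1L]] + 3L)
    dimnames(vals) <- list(ids, header[-(1:2)])
  } else {
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("TSV matrix needs an id column plus samples: ", path)
    ids <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(apply(tab[, -1L, drop = FALSE], 2L,
                         function(col) anyNA(suppressWarnings(as.numeric(col)))))
      stop("non-numeric cells in TSV column(s): ",
           paste(colnames(tab)[-1L][bad], collapse = ", "))
    }
    rownames(vals) <- ids
  }
  expression_matrix(vals, samples = samples)
}

#' Write an expression matrix as GCT 1.2 or TSV
#'
#' @param mat An `ExpressionMatrix`.
#' @param path Output path.
#' @param format `"gct"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, format = c("gct", "tsv")) {
  format <- match.arg(format)
  v <- mat$values
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t"),
                 paste(c("NAME", "Description", colnames(v)), collapse = "\t")),
               con)
    body <- cbind(rownames(v), "na",
                  format(v, trim = TRUE, digits = 15, scientific = FALSE))
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  } else {
    tab <- data.frame(id = rownames(v), v, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a CLS class-label file
#'
#' Categorical CLS: `n_samples n_classes 1`, then `# name1 name2 ...`, then a
#' line of per-sample labels (names or 0-based indices).
#'
#' @param path File path.
#' @return Character vector of class labels, one per sample.
#' @export
read_cls <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("malformed CLS file: ", path)
  hdr <- as.integer(strsplit(trimws(lines[[1L]]), "\\s+")[[1L]])
  names_line <- strsplit(trimws(lines[[2L]]), "\\s+")[[1L]]
  if (names_line[[1L]] != "#") stop("malformed CLS class-name line in ", path)
  class_names <- names_line[-1L]
  labels <- strsplit(trimws(lines[[3L]]), "\\s+")[[1L]]
  if (length(labels) != hdr[[1L]])
    stop("CLS declares ", hdr[[1L]], " samples but lists ", length(labels))
  if (all(labels %in% as.character(seq_along(class_names) - 1L)))
    labels <- class_names[as.integer(labels) + 1L]
  labels
}

#' Write a CLS class-label file
#'
#' @param labels Character vector of per-sample class labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cls <- function(labels, path) {
  classes <- unique(labels)
  writeLines(c(paste(length(labels), length(classes), 1L),
               paste("#", paste(classes, collapse = " ")),
               paste(labels, collapse = " ")),
             path)
  invisible(path)
}

#' Read a GMT gene set collection
#'
#' Each tab-separated line: set name, description, member genes. The
#' description field is used as the category label.
#'
#' @param path File path.
#' @return A `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[[1L]], " (need name, description, >=1 gene)")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  gene_set_collection(sets,
                      category = vapply(fields, `[[`, character(1), 2L))
}

#' Write a GMT gene set collection
#'
#' @param collection A `GeneSetCollection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[[i]], collection$category[[i]],
            collection$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample-annotation TSV
#'
#' Expected columns include `sample_id`; any further columns (cell_type,
#' culture, day, replicate, ...) are carried along.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_sample_annotations <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab))
    stop("annotation table must have a sample_id column: ", path)
  tab
}
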