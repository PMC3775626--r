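#' Read an OTU/contingency count table
#'
#' Reads a leaf-by-sample table of non-negative integer counts, either from
#' tab-separated text (first column = leaf label, header = sample ids) or
#' from a BIOM-JSON v1.0 file (dense or sparse; parsed with the
#' \pkg{biomformat} package when available, otherwise with a built-in
#' JSON reader). Rows are taxa/OTUs, columns are samples, matching the usual
#' orientation of microbiome contingency tables.
#'
#' @param path path to the table file.
#' @param format `"tsv"` or `"biom"` (BIOM-JSON v1.0).
#' @return an integer matrix with leaf row names and sample column names.
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_user("count table file not found: ", path)
  m <- switch(format, tsv = read_counts_tsv(path), biom = read_counts_biom(path))
  validate_count_table(m)
}

#' Validate a count matrix
#'
#' @param m numeric matrix, rows = leaves, columns = samples.
#' @return the matrix with storage mode integer, after checking that all
#'   cells are non-negative integers and that row/column names are unique.
#' @export
validate_count_table <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  stopifnot(is.matrix(m))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_user("count table must have row (leaf) and column (sample) names")
  if (anyDuplicated(rownames(m)))
    stop_user("duplicate row label(s): ",
              paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop_user("duplicate sample id(s): ",
              paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop_user("non-integer or negative count at row '", rownames(m)[bad[1, 1]],
              "', sample '", colnames(m)[bad[1, 2]], "'")
  storage.mode(m) <- "integer"
  m
}

read_counts_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # leading "# ..." provenance lines (as written by write_count_table) are skipped
  while (length(lines) && grepl("^# ", lines[1L])) lines <- lines[-1L]
  if (!length(lines)) stop_user("empty TSV table: ", path)
  df <- utils::read.delim(text = lines, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_user("TSV table needs a label column and >= 1 sample column")
  labels <- trimws(as.character(df[[1L]]))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) & m != "",
                 arr.ind = TRUE)
    if (nrow(bad))
      stop_user("non-numeric cell '", m[bad[1, 1], bad[1, 2]], "' at row '",
                labels[bad[1, 1]], "', sample '", colnames(m)[bad[1, 2]], "'")
    storage.mode(m) <- "numeric"
  }
  rownames(m) <- labels
  m
}

read_counts_biom <- function(path) {
  if (requireNamespace("biomformat", quietly = TRUE)) {
    b <- tryCatch(biomformat::read_biom(path),
                  error = function(e) stop_user("BIOM parse error: ", conditionMessage(e)))
    m <- as.matrix(biomformat::biom_data(b))
    return(m)
  }
  # fallback: direct BIOM-JSON v1.0 (dense and sparse encodings)
  j <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop_user("BIOM parse error: ", conditionMessage(e)))
  if (is.null(j$rows) || is.null(j$columns) || is.null(j$data))
    stop_user("BIOM parse error: missing rows/columns/data in ", path)
  rn <- vapply(j$rows, function(r) r$id, "")
  cn <- vapply(j$columns, function(r) r$id, "")
  m <- matrix(0, length(rn), length(cn), dimnames = list(rn, cn))
  if (identical(j$matrix_type, "dense")) {
    for (i in seq_along(j$data)) m[i, ] <- unlist(j$data[[i]])
  } else {
    for (trip in j$data) m[trip[[1]] + 1L, trip[[2]] + 1L] <- trip[[3]]
  }
  m
}

#' Align a count table with a tree's leaf set
#'
#' In `"strict"` mode (the default everywhere in this package) the table rows
#' and the tree leaves must coincide exactly; any mismatch is an error, since
#' a silent mismatch usually indicates an upstream labelling bug. In
#' `"intersect"` mode rows that are not tree leaves are dropped with a
#' warning and tree leaves without a row become all-zero rows, so the result
#' always has one row per tree leaf, in tree leaf order.
#'
#' @param tree a [ptree].
#' @param table count matrix as from [read_count_table()].
#' @param mode `"strict"` or `"intersect"`.
#' @return the aligned count matrix (rows in tree leaf order).
#' @export
align_tree_table <- function(tree, table, mode = c("strict", "intersect")) {
  mode <- match.arg(mode)
  table <- validate_count_table(table)
  leaves <- leaf_labels(tree)
  extra <- setdiff(rownames(table), leaves)
  missing <- setdiff(leaves, rownames(table))
  if (mode == "strict") {
    if (length(extra) || length(missing))
      stop_user("tree/table label mismatch; ",
                if (length(extra)) paste0("table-only: ",
                  paste(utils::head(extra, 10L), collapse = ", "), "; ") else "",
                if (length(missing)) paste0("tree-only: ",
                  paste(utils::head(missing, 10L), collapse = ", ")) else "")
  } else {
    if (length(extra))
      warning(length(extra), " table row(s) not in tree dropped: ",
              paste(utils::head(extra, 10L), collapse = ", "))
  }
  out <- matrix(0L, length(leaves), ncol(table),
                dimnames = list(leaves, colnames(table)))
  keep <- intersect(leaves, rownames(table))
  out[keep, ] <- table[keep, , drop = FALSE]
  out
}

#' Extract one sample from a count table
#'
#' @param table count matrix.
#' @param sample sample id (column name) or column index.
#' @return named integer vector of per-leaf counts.
#' @export
sample_counts <- function(table, sample) {
  table <- validate_count_table(table)
  v <- table[, sample]
  stats::setNames(as.integer(v), rownames(table))
}

#' Write a count table as TSV
#' @param table count matrix.
#' @param path output path.
#' @param label_header header for the leaf-label column.
#' @param comment optional comment line written first (prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, label_header = "otu_id", comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- data.frame(label = rownames(table), table, check.names = FALSE)
  names(df)[1L] <- label_header
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
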