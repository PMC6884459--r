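#' Construct an expression matrix for one condition
#'
#' Container for per-gene, per-replicate expression values of a single
#' condition, together with the unit of measurement.
#'
#' @param values numeric matrix, genes x replicates, non-negative, no
#'   missing cells. Row names (if present) are used as gene identifiers
#'   unless `gene_ids` is given.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param unit `"FPKM"` or `"count"`.
#' @param condition_label free-text label (e.g. `"control"`, `"mutant"`).
#' @return An object of class `expression_matrix`: a list with elements
#'   `gene_ids`, `values` (with gene ids as row names), `unit`,
#'   `condition_label`.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2), c("g1", "g2", "g3"), "FPKM", "ctl")
#' m
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              unit = c("FPKM", "count"),
                              condition_label = "") {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids))
    stop_devdelay("gene_ids must be supplied (or set as row names)")
  gene_ids <- as.character(gene_ids)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_devdelay("expression matrix needs at least 1 gene and 1 replicate")
  if (length(gene_ids) != nrow(values))
    stop_devdelay("gene_ids length (%d) does not match row count (%d)",
                  length(gene_ids), nrow(values))
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop_devdelay("duplicated gene id: %s", dup[1L], class = "devdelay_format_error")
  if (anyNA(values))
    stop_devdelay("missing cells are not allowed", class = "devdelay_value_error")
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop_devdelay("negative value at gene '%s', replicate column %d",
                  gene_ids[idx[1L]], idx[2L], class = "devdelay_value_error")
  }
  rownames(values) <- gene_ids
  if (is.null(colnames(values)))
    colnames(values) <- paste0("rep", seq_len(ncol(values)))
  structure(
    list(gene_ids = gene_ids, values = values, unit = unit,
         condition_label = as.character(condition_label)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d replicates [%s]%s\n",
              nrow(x$values), ncol(x$values), x$unit,
              if (nzchar(x$condition_label))
                paste0(" (", x$condition_label, ")") else ""))
  utils::str(x$values, give.attr = FALSE)
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a gene-level expression table
#'
#' Parses a TSV with a header row (`gene_id`, then one column per replicate)
#' into an [expression_matrix()]. Decimal point is `"."`; no thousands
#' separators. Row order is preserved.
#'
#' @param path path to the TSV file.
#' @inheritParams expression_matrix
#' @return An `expression_matrix`.
#' @seealso [write_expression_table()]
#' @export
read_expression_table <- function(path, unit = c("FPKM", "count"),
                                  condition_label = "") {
  unit <- match.arg(unit)
  tab <- read_tsv_strict(path, min_cols = 2L)
  vals <- parse_numeric_body(tab, path)
  expression_matrix(vals, gene_ids = tab[[1L]], unit = unit,
                    condition_label = condition_label)
}

#' Write a gene-level expression table
#'
#' Inverse of [read_expression_table()]: `gene_id` column followed by one
#' column per replicate, tab-separated, header included.
#'
#' @param x an `expression_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a developmental reference time-course
#'
#' Per-gene expression across ordered, contiguous, half-open developmental
#' time bins `[start, end)` in hours (default layout: 12 bins of 2 h
#' covering `[0, 24)`).  The set of reference-silent genes — genes with
#' value 0 in every bin — is computed on construction and is always
#' recomputable from the matrix.
#'
#' @param values numeric matrix, genes x bins, non-negative.
#' @param gene_ids unique gene identifiers, one per row.
#' @param bin_starts,bin_ends numeric vectors of bin boundaries in hours;
#'   bins must be sorted, non-overlapping and contiguous.
#' @return An object of class `time_course`: list with `gene_ids`, `bins`
#'   (data frame `start`, `end`, `label`), `values`, `silent_set`.
#' @export
time_course <- function(values, gene_ids = rownames(values),
                        bin_starts, bin_ends) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values) || anyDuplicated(gene_ids))
    stop_devdelay("gene ids must be unique and match the row count",
                  class = "devdelay_format_error")
  if (anyNA(values) || any(values < 0))
    stop_devdelay("time-course values must be non-negative with no missing cells",
                  class = "devdelay_value_error")
  nb <- length(bin_starts)
  if (nb != length(bin_ends) || nb != ncol(values) || nb < 1L)
    stop_devdelay("bin boundaries must match the number of value columns")
  o <- order(bin_starts)
  bin_starts <- bin_starts[o]; bin_ends <- bin_ends[o]
  values <- values[, o, drop = FALSE]
  if (any(bin_ends <= bin_starts))
    stop_devdelay("each bin must satisfy end > start",
                  class = "devdelay_format_error")
  if (nb > 1L && any(abs(bin_starts[-1L] - bin_ends[-nb]) > 1e-9))
    stop_devdelay("bins must be contiguous and non-overlapping",
                  class = "devdelay_format_error")
  labels <- paste0(format_hours(bin_starts), "-", format_hours(bin_ends))
  colnames(values) <- labels
  rownames(values) <- gene_ids
  structure(
    list(gene_ids = gene_ids,
         bins = data.frame(start = bin_starts, end = bin_ends, label = labels,
                           stringsAsFactors = FALSE),
         values = values,
         silent_set = gene_ids[rowSums(values) == 0]),
    class = "time_course"
  )
}

format_hours <- function(h) {
  ifelse(abs(h - round(h)) < 1e-9, as.character(round(h)),
         vapply(h, format, "", trim = TRUE))
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf(
    "time_course: %d genes x %d bins covering [%s, %s) h; %d reference-silent genes\n",
    nrow(x$values), nrow(x$bins), format_hours(x$bins$start[1L]),
    format_hours(x$bins$end[nrow(x$bins)]), length(x$silent_set)))
  invisible(x)
}

#' Read a developmental reference time-course table
#'
#' Parses a TSV whose header is `gene_id` followed by bin labels of the form
#' `"start-end"` in hours (e.g. `0-2`, `2-4`, ..., `22-24`).  Columns may
#' arrive in any order; they are sorted by bin start and validated to be
#' contiguous and non-overlapping.  The silent set (all-zero rows) is
#' computed.
#'
#' @param path path to the TSV file.
#' @return A [time_course()] object.
#' @export
read_time_course <- function(path) {
  tab <- read_tsv_strict(path, min_cols = 2L)
  vals <- parse_numeric_body(tab, path)
  labels <- names(tab)[-1L]
  m <- regmatches(labels, regexec("^([0-9.]+)-([0-9.]+)$", labels))
  bad <- labels[vapply(m, length, 1L) != 3L]
  if (length(bad))
    stop_devdelay("bin label '%s' is not of the form start-end", bad[1L],
                  class = "devdelay_format_error")
  starts <- vapply(m, function(z) as.numeric(z[2L]), 1)
  ends <- vapply(m, function(z) as.numeric(z[3L]), 1)
  time_course(vals, gene_ids = tab[[1L]], bin_starts = starts, bin_ends = ends)
}

#' Write a developmental reference time-course table
#'
#' @param x a `time_course`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_time_course <- function(x, path) {
  stopifnot(inherits(x, "time_course"))
  df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- shared TSV plumbing ------------------------------------------------------

read_tsv_strict <- function(path, min_cols = 2L) {
  if (!file.exists(path))
    stop_devdelay("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop_devdelay("%s: need a header row and at least one data row", path,
                  class = "devdelay_format_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L)
    stop_devdelay("%s: ragged rows (header has %d fields, row %d has %d)",
                  path, ncols[1L], which(ncols != ncols[1L])[1L] - 1L,
                  ncols[ncols != ncols[1L]][1L],
                  class = "devdelay_format_error")
  if (ncols[1L] < min_cols)
    stop_devdelay("%s: expected at least %d columns", path, min_cols,
                  class = "devdelay_format_error")
  header <- fields[[1L]]
  body <- fields[-1L]
  out <- lapply(seq_along(header), function(j)
    vapply(body, `[[`, "", j))
  names(out) <- header
  out
}

parse_numeric_body <- function(tab, path) {
  cols <- lapply(tab[-1L], function(col) {
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop_devdelay("%s: non-numeric cell '%s' (gene '%s')", path,
                    col[i], tab[[1L]][i], class = "devdelay_value_error")
    }
    v
  })
  vals <- do.call(cbind, cols)
  colnames(vals) <- names(tab)[-1L]
  vals
}
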