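#' Construct a validated Q matrix
#'
#' A Q matrix holds inferred ancestry membership coefficients: one row per
#' individual, one column per cluster, entries nonnegative and each row
#' summing to 1. `q_matrix()` validates a matrix or data frame against these
#' invariants and returns a tibble of cluster columns (class `q_matrix`),
#' with rows renormalized to sum to exactly 1 in working precision.
#'
#' Entries exactly 0 are permitted, as are all-zero columns (such columns are
#' inert in every statistic computed by this package). A row of all zeros, a
#' negative entry, or a row sum outside `1 +/- tol` is an error.
#'
#' @param x A numeric matrix or data frame, individuals in rows, clusters in
#'   columns.
#' @param group Optional single group/population label attached to the matrix
#'   and carried into bootstrap and comparison output.
#' @param row_labels Optional character vector of individual identifiers,
#'   length `nrow(x)`.
#' @param col_labels Optional character vector of cluster names, length
#'   `ncol(x)`; defaults to existing column names or `Cluster1..K`.
#' @param tol Row-sum tolerance: every raw row sum must lie in
#'   `[1 - tol, 1 + tol]`. Defaults to `1e-3`, which accommodates the 3-6
#'   decimal rounding of STRUCTURE/ADMIXTURE output.
#' @return A tibble of class `q_matrix` with K numeric columns; attributes
#'   `group` and `row_labels` hold the optional metadata.
#' @examples
#' q <- q_matrix(rbind(c(1, 0), c(0.5, 0.5)))
#' q_stat(q)
#' @export
q_matrix <- function(x, group = NULL, row_labels = NULL, col_labels = NULL,
                     tol = 1e-3) {
  mat <- as.matrix(x)
  if (length(mat) == 0L) stop("Q matrix is empty", call. = FALSE)
  if (!is.numeric(mat)) stop("Q matrix entries must be numeric", call. = FALSE)
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative membership coefficient at row %d, column %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  mat <- .renormalize_rows(mat, tol)

  if (is.null(col_labels)) col_labels <- colnames(mat)
  if (is.null(col_labels)) col_labels <- paste0("Cluster", seq_len(ncol(mat)))
  stopifnot(length(col_labels) == ncol(mat))
  if (!is.null(row_labels)) {
    row_labels <- as.character(row_labels)
    stopifnot(length(row_labels) == nrow(mat))
  }
  colnames(mat) <- col_labels
  out <- tibble::as_tibble(mat)
  attr(out, "group") <- group
  attr(out, "row_labels") <- row_labels
  class(out) <- c("q_matrix", class(out))
  out
}

#' @export
print.q_matrix <- function(x, ...) {
  grp <- attr(x, "group")
  cat(sprintf("Q matrix: %d individuals x %d clusters%s\n",
              nrow(x), ncol(x),
              if (is.null(grp)) "" else paste0(" (group: ", grp, ")")))
  NextMethod()
}

# shared row-sum validation + exact renormalization, on a base matrix
.renormalize_rows <- function(mat, tol) {
  rs <- rowSums(mat)
  if (any(rs == 0)) {
    stop("row(s) of all zeros: ", paste(which(rs == 0), collapse = ", "),
         call. = FALSE)
  }
  off <- which(abs(rs - 1) > tol)
  if (length(off) > 0L) {
    stop(sprintf(
      "row sum(s) outside 1 +/- %g for row(s): %s (sums %s)", tol,
      paste(off, collapse = ", "),
      paste(signif(rs[off], 6), collapse = ", ")
    ), call. = FALSE)
  }
  mat / rs
}

#' Renormalize Q-matrix rows to unit sums
#'
#' Divides each row by its sum so that rows sum to exactly 1 in working
#' precision, after checking that every raw row sum lies within `1 +/- tol`.
#' Idempotent: applying it twice gives the same result.
#'
#' @param q A `q_matrix`, matrix or data frame of membership coefficients.
#' @inheritParams q_matrix
#' @return A `q_matrix` with unit row sums; the input is not modified.
#' @export
normalize_rows <- function(q, tol = 1e-3) {
  q_matrix(q_values(q), group = attr(q, "group"),
           row_labels = attr(q, "row_labels"), tol = tol)
}

# extract the plain numeric matrix from any accepted Q-matrix representation
q_values <- function(q) {
  if (is.matrix(q)) {
    storage.mode(q) <- "double"
    return(q)
  }
  as.matrix(as.data.frame(q))
}

#' Read a Q matrix from delimited text
#'
#' Reads the plain-text dialects produced by population-structure software.
#' The ADMIXTURE `.Q` dialect is whitespace-delimited and headerless; CSV and
#' TSV files may carry a single header row of cluster names and a leading
#' column of individual labels. Lines starting with `#` and blank lines are
#' ignored. Full STRUCTURE report files (header blocks, per-individual
#' metadata) are not parsed: extract the numeric block, or drop leading
#' metadata columns explicitly with `skip_cols`.
#'
#' @param path Path to the file.
#' @param dialect One of `"auto"`, `"whitespace"`, `"csv"`, `"tsv"`.
#'   `"auto"` sniffs the separator from the first non-comment line (a tab
#'   wins over a comma, which wins over whitespace).
#' @param skip_cols Number of leading metadata columns to drop before
#'   parsing (counted after the label column, if any); no heuristics are
#'   applied beyond this.
#' @param has_header If `TRUE` the first non-comment line holds cluster
#'   names.
#' @param label_col If `TRUE` the first column holds individual labels,
#'   stored as `row_labels`.
#' @inheritParams q_matrix
#' @return A validated `q_matrix`.
#' @export
read_q_matrix <- function(path, dialect = c("auto", "whitespace", "csv", "tsv"),
                          skip_cols = 0, has_header = FALSE, label_col = FALSE,
                          group = NULL, tol = 1e-3) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty Q-matrix file: ", path, call. = FALSE)

  if (dialect == "auto") {
    probe <- lines[[1L]]
    dialect <- if (grepl("\t", probe)) "tsv"
      else if (grepl(",", probe)) "csv"
      else "whitespace"
  }
  sep <- switch(dialect, whitespace = "\\s+", csv = ",", tsv = "\t")
  fields <- lapply(lines, function(l) strsplit(trimws(l), sep)[[1L]])

  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    stop(sprintf("ragged rows: line widths %s",
                 paste(unique(widths), collapse = ", ")), call. = FALSE)
  }

  col_labels <- NULL
  if (has_header) {
    header <- fields[[1L]]
    fields <- fields[-1L]
    if (length(fields) == 0L) stop("no data rows after header", call. = FALSE)
  }
  drop <- skip_cols + as.integer(label_col)
  if (drop >= widths[[1L]]) {
    stop("skip_cols/label_col leave no data columns", call. = FALSE)
  }

  row_labels <- NULL
  if (label_col) {
    row_labels <- vapply(fields, function(f) f[[1L]], character(1))
  }
  keep <- function(f) if (drop > 0L) f[-seq_len(drop)] else f
  cells <- do.call(rbind, lapply(fields, keep))
  if (has_header) col_labels <- keep(header)

  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at row %d, column %d",
                 cells[bad[1L], bad[2L]], bad[1L], bad[2L] + drop),
         call. = FALSE)
  }
  q_matrix(vals, group = group, row_labels = row_labels,
           col_labels = col_labels, tol = tol)
}

#' Write a Q matrix as delimited text
#'
#' The whitespace dialect (ADMIXTURE `.Q`) is headerless and label-free;
#' CSV/TSV optionally carry the cluster names as a header and the individual
#' labels as a first column. Values are written at full double precision so
#' that a write/read round trip reproduces the matrix to better than 1e-12.
#'
#' @inheritParams normalize_rows
#' @param path Output file path.
#' @param dialect One of `"whitespace"`, `"csv"`, `"tsv"`.
#' @param col_names Write a header row of cluster names (CSV/TSV only).
#' @param row_labels Write the individual labels as a first column (CSV/TSV
#'   only; requires labels to be present on `q`).
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(q, path, dialect = c("whitespace", "csv", "tsv"),
                           col_names = FALSE, row_labels = FALSE) {
  dialect <- match.arg(dialect)
  mat <- q_values(q)
  sep <- switch(dialect, whitespace = " ", csv = ",", tsv = "\t")
  cells <- matrix(format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                  nrow = nrow(mat))
  header <- NULL
  if (dialect != "whitespace") {
    if (row_labels) {
      labs <- attr(q, "row_labels")
      if (is.null(labs)) stop("q has no row labels to write", call. = FALSE)
      cells <- cbind(labs, cells)
    }
    if (col_names) {
      cn <- colnames(mat)
      if (is.null(cn)) cn <- paste0("Cluster", seq_len(ncol(mat)))
      if (row_labels) cn <- c("id", cn)
      header <- paste(cn, collapse = sep)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines(apply(cells, 1L, paste, collapse = sep), con)
  invisible(path)
}
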