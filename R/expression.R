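#' Expression tables
#'
#' An expression table is a tibble with a `gene_id` character column followed
#' by one numeric column per sample, carrying non-negative values on any
#' scale (NanoString counts, RNA-seq FPKM, microarray intensities). The
#' measurement platform travels with the table as the `"platform"` attribute
#' so downstream steps can decide, e.g., whether background correction
#' applies.
#'
#' @param x A data frame whose first column (or a column named `gene_id`)
#'   holds unique gene identifiers and whose remaining columns are numeric
#'   sample values.
#' @param platform One of `"nanostring_counts"`, `"rnaseq_fpkm"`,
#'   `"microarray_intensity"`, `"unknown"`.
#' @return A validated expression tibble.
#' @export
as_expression <- function(x, platform = c("unknown", "nanostring_counts",
                                          "rnaseq_fpkm", "microarray_intensity")) {
  platform <- match.arg(platform)
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  x <- as_tibble(x)
  if (!"gene_id" %in% names(x)) names(x)[1] <- "gene_id"
  x <- dplyr::relocate(x, "gene_id")
  x$gene_id <- as.character(x$gene_id)
  if (ncol(x) < 2L) abort("Expression table needs at least one sample column.")
  if (anyNA(x$gene_id) || any(x$gene_id == "")) {
    abort("Missing or empty gene identifiers.")
  }
  if (anyDuplicated(x$gene_id)) {
    dup <- unique(x$gene_id[duplicated(x$gene_id)])
    abort(paste0("Duplicate gene identifiers: ", toString(head(dup, 5))))
  }
  smp <- names(x)[-1]
  if (anyDuplicated(smp)) {
    abort(paste0("Duplicate sample identifiers: ",
                 toString(unique(smp[duplicated(smp)]))))
  }
  for (s in smp) {
    v <- x[[s]]
    if (!is.numeric(v)) {
      abort(paste0("Non-numeric values in sample '", s, "'."))
    }
    bad <- which(!is.finite(v))
    if (length(bad)) {
      abort(paste0("Non-numeric (missing/non-finite) value for gene '",
                   x$gene_id[bad[1]], "', sample '", s, "'."))
    }
    neg <- which(v < 0)
    if (length(neg)) {
      abort(paste0("Negative value ", v[neg[1]], " for gene '",
                   x$gene_id[neg[1]], "', sample '", s, "'."))
    }
  }
  attr(x, "platform") <- platform
  x
}

#' @rdname as_expression
#' @param expr An expression tibble.
#' @export
expr_platform <- function(expr) {
  attr(expr, "platform") %||% "unknown"
}

# gene x sample numeric matrix view
expr_values <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene_id
  storage.mode(m) <- "double"
  m
}

expr_from_matrix <- function(m, platform = "unknown") {
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(gene_id = rownames(m)), df)
  as_expression(df, platform)
}

#' Read a delimited expression table
#'
#' Reads a TSV (default) or CSV (by `.csv` extension) expression table with
#' one header row of identifiers. Values must be numeric and non-negative;
#' offending cells are reported by gene and sample. Tables may store genes
#' in rows (default) or samples in rows.
#'
#' @param path Path to a delimited text file.
#' @param orientation `"genes_in_rows"` or `"samples_in_rows"`.
#' @param platform Platform tag attached to the result (see
#'   [as_expression()]).
#' @return An expression tibble.
#' @export
read_expression_table <- function(path,
                                  orientation = c("genes_in_rows", "samples_in_rows"),
                                  platform = "unknown") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort(paste0("Empty or header-only table: ", path))
  fields <- strsplit(lines, delim, fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) {
    abort(paste0("Ragged rows in ", path, ": rows have ",
                 toString(unique(nf)), " fields."))
  }
  header <- fields[[1]]
  body <- fields[-1]
  ids <- vapply(body, `[[`, character(1), 1L)
  col_ids <- header[-1]
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(col_ids),
                 dimnames = list(ids, col_ids))
  for (i in seq_along(body)) {
    raw <- body[[i]][-1]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num))
    if (length(bad)) {
      abort(paste0("Non-numeric cell '", raw[bad[1]], "' at row '", ids[i],
                   "', column '", col_ids[bad[1]], "' in ", path))
    }
    vals[i, ] <- num
  }
  if (orientation == "samples_in_rows") vals <- t(vals)
  expr_from_matrix(vals, platform)
}

#' Write an expression table
#'
#' @inheritParams read_expression_table
#' @param expr An expression tibble.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path,
                                   orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  expr <- as_expression(expr, expr_platform(expr))
  m <- expr_values(expr)
  if (orientation == "samples_in_rows") m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- if (orientation == "genes_in_rows") "gene_id" else "sample_id"
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Sample labels
#'
#' Validates a sample-to-histology label table: a tibble with `sample_id`
#' and `class` character columns, one row per sample.
#'
#' @param x A data frame with `sample_id` and `class` columns (or two
#'   columns taken in that order).
#' @return A validated label tibble.
#' @export
as_labels <- function(x) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  x <- as_tibble(x)
  if (!all(c("sample_id", "class") %in% names(x))) {
    if (ncol(x) < 2) abort("Labels need `sample_id` and `class` columns.")
    names(x)[1:2] <- c("sample_id", "class")
  }
  x <- dplyr::select(x, "sample_id", "class")
  x$sample_id <- as.character(x$sample_id)
  x$class <- as.character(x$class)
  if (anyNA(x$sample_id) || anyNA(x$class)) abort("Missing values in labels.")
  if (anyDuplicated(x$sample_id)) {
    abort(paste0("Duplicate sample ids in labels: ",
                 toString(unique(x$sample_id[duplicated(x$sample_id)]))))
  }
  x
}

#' @rdname as_labels
#' @param path Path to a two-column TSV/CSV with header.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  as_labels(readr::read_delim(path, delim = delim, show_col_types = FALSE))
}

#' @rdname as_labels
#' @param labels A label tibble.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(as_labels(labels), path)
  invisible(path)
}
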