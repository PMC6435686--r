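#' Marker panels
#'
#' A marker panel maps each histology class to its prototypic marker genes
#' and carries an alias table so that gene-symbol dialects across platforms
#' (e.g. `TTF-1` vs `NKX2-1`) resolve to the panel's canonical symbols.
#'
#' @param classes Named list: class label -> ordered character vector of
#'   canonical gene symbols. Classes must not share genes.
#' @param aliases Named list: canonical symbol -> character vector of
#'   accepted synonyms. Each synonym may point to at most one panel gene.
#' @return An object of class `marker_panel`.
#' @export
marker_panel <- function(classes, aliases = list()) {
  if (!is.list(classes) || is.null(names(classes)) || any(names(classes) == "")) {
    abort("`classes` must be a named list of gene vectors.")
  }
  genes <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(genes)) {
    abort(paste0("Classes must be disjoint; shared genes: ",
                 toString(unique(genes[duplicated(genes)]))))
  }
  if (length(aliases)) {
    unknown <- setdiff(names(aliases), genes)
    if (length(unknown)) {
      abort(paste0("Aliases for genes not in the panel: ", toString(unknown)))
    }
    syn <- unlist(aliases, use.names = FALSE)
    if (anyDuplicated(syn)) {
      abort(paste0("Synonym maps to more than one panel gene: ",
                   toString(unique(syn[duplicated(syn)]))))
    }
    if (length(intersect(syn, genes))) {
      abort(paste0("Synonym collides with a canonical panel symbol: ",
                   toString(intersect(syn, genes))))
    }
  }
  structure(
    list(classes = lapply(classes, as.character),
         aliases = lapply(aliases, as.character)),
    class = "marker_panel"
  )
}

#' Default 11-gene NSCLC histology panel
#'
#' The marker set used for histology prediction: LCNEC markers CHGA, SYP,
#' CD56; AC markers SFTPG, NAPSA, TTF-1; SqCC markers TP73L, KRT6A, KRT5,
#' KRT40, KRT16. `SFTPG` and `TP73L` are legacy symbols retained as
#' canonical; the alias table maps current HGNC symbols onto them.
#'
#' @return A `marker_panel` with 11 genes across 3 classes.
#' @export
default_marker_panel <- function() {
  panel <- marker_panel(
    classes = list(
      AC = c("SFTPG", "NAPSA", "TTF-1"),
      LCNEC = c("CHGA", "SYP", "CD56"),
      SqCC = c("TP73L", "KRT6A", "KRT5", "KRT40", "KRT16")
    ),
    aliases = list(
      "TTF-1" = c("NKX2-1", "TTF1"),
      "CD56" = "NCAM1",
      "TP73L" = c("TP63", "P63"),
      "SFTPG" = "SFTA3",
      "KRT40" = "KA36"
    )
  )
  stopifnot(length(panel_genes(panel)) == 11L)
  panel
}

#' @rdname marker_panel
#' @param panel A `marker_panel`.
#' @export
panel_genes <- function(panel) {
  unlist(panel$classes, use.names = FALSE)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel>", length(panel_genes(x)), "genes,",
      length(x$classes), "classes\n")
  for (cl in names(x$classes)) {
    cat("  ", cl, ": ", toString(x$classes[[cl]]), "\n", sep = "")
  }
  invisible(x)
}

#' @method tidy marker_panel
#' @export
tidy.marker_panel <- function(x, ...) {
  tibble(
    class = rep(names(x$classes), lengths(x$classes)),
    gene = unlist(x$classes, use.names = FALSE)
  )
}

#' Read or write a marker panel definition
#'
#' YAML (or JSON) file with top-level `classes` (class -> gene list) and
#' optional `aliases` (canonical -> synonyms).
#'
#' @param path File path.
#' @return A `marker_panel` ([read_marker_panel()]) or `path` invisibly.
#' @export
read_marker_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(spec$classes)) abort("Panel file lacks a `classes` block.")
  marker_panel(spec$classes, spec$aliases %||% list())
}

#' @rdname read_marker_panel
#' @param panel A `marker_panel`.
#' @export
write_marker_panel <- function(panel, path) {
  yaml::write_yaml(list(classes = panel$classes, aliases = panel$aliases), path)
  invisible(path)
}

# Resolve `genes` against the table's rows using the panel alias map.
# Returns expr restricted to those genes, canonical names, given order.
resolve_genes <- function(expr, genes, aliases) {
  rows <- expr$gene_id
  idx <- integer(length(genes))
  missing <- character()
  for (i in seq_along(genes)) {
    g <- genes[i]
    accepted <- c(g, aliases[[g]])
    hit <- which(rows %in% accepted)
    if (length(hit) == 0L) {
      missing <- c(missing, paste0(g, " (tried: ", toString(accepted), ")"))
    } else if (length(hit) > 1L) {
      abort(paste0("Ambiguous alias resolution for panel gene '", g,
                   "': matrix rows ", toString(rows[hit]),
                   " all resolve to it."))
    } else {
      idx[i] <- hit
    }
  }
  if (length(missing)) {
    abort(paste0("Panel genes not found in the expression table: ",
                 paste(missing, collapse = "; ")))
  }
  out <- expr[idx, , drop = FALSE]
  out$gene_id <- genes
  as_expression(out, expr_platform(expr))
}

#' Restrict an expression table to the marker panel
#'
#' Matches every panel gene against the table's rows, directly or through
#' the panel's alias table, and returns the table restricted to the panel
#' genes in panel order under their canonical symbols. Unmatched panel
#' genes and ambiguous matches (two rows resolving to one panel gene) are
#' hard errors.
#'
#' @param expr An expression tibble.
#' @param panel A `marker_panel`.
#' @return An expression tibble with one row per panel gene.
#' @export
resolve_panel <- function(expr, panel = default_marker_panel()) {
  expr <- as_expression(expr, expr_platform(expr))
  resolve_genes(expr, panel_genes(panel), panel$aliases)
}
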