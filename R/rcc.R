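#' Read a batch of NanoString RCC files
#'
#' Parses single-sample nCounter RCC files (bracketed sections with a
#' `Code_Summary` CSV block holding `CodeClass,Name,Accession,Count`) into
#' one expression table with a column per file. Windows line endings and
#' trailing blank lines are tolerated. The sample id is taken from the
#' `Sample_Attributes` `ID` field, falling back to the file stem; id
#' collisions across files are disambiguated by suffixing the file stem.
#'
#' Counts are carried through unaltered: the column sum of the returned
#' matrix equals the sum of the `Count` fields of the corresponding file.
#' All files must share the same probe set (one codeset per batch).
#'
#' @param paths Character vector of RCC file paths.
#' @return A list with `expression` (platform `"nanostring_counts"`) and
#'   `probe_classes`, a tibble mapping `probe_id` to its `code_class`
#'   (Endogenous, Negative, Positive, Housekeeping, ...).
#' @export
read_rcc_batch <- function(paths) {
  if (length(paths) == 0) abort("No RCC files given.")
  parsed <- lapply(paths, parse_rcc_file)
  probes <- parsed[[1]]$code_summary$Name
  for (p in parsed[-1]) {
    if (!identical(sort(p$code_summary$Name), sort(probes))) {
      abort(paste0("Probe set in ", p$path,
                   " differs from the first file; one codeset per batch."))
    }
  }
  ids <- vapply(parsed, `[[`, character(1), "sample_id")
  stems <- vapply(paths, function(p) sub("\\.[^.]*$", "", basename(p)), character(1))
  dup <- duplicated(ids) | duplicated(ids, fromLast = TRUE)
  ids[dup] <- paste0(ids[dup], "_", stems[dup])
  if (anyDuplicated(ids)) abort("Unresolvable sample id collision across RCC files.")

  m <- matrix(0, nrow = length(probes), ncol = length(parsed),
              dimnames = list(probes, ids))
  for (j in seq_along(parsed)) {
    cs <- parsed[[j]]$code_summary
    m[cs$Name, j] <- cs$Count
  }
  classes <- parsed[[1]]$code_summary[, c("Name", "CodeClass")]
  for (p in parsed[-1]) {
    other <- p$code_summary
    cl <- setNames(classes$CodeClass, classes$Name)
    if (any(cl[other$Name] != other$CodeClass)) {
      abort(paste0("Probe CodeClass conflicts across files (", p$path, ")."))
    }
  }
  list(
    expression = expr_from_matrix(m, "nanostring_counts"),
    probe_classes = tibble(probe_id = classes$Name, code_class = classes$CodeClass)
  )
}

parse_rcc_file <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  open_idx <- grep("^<[A-Za-z_]+>$", lines)
  sections <- list()
  for (i in open_idx) {
    name <- sub("^<([A-Za-z_]+)>$", "\\1", lines[i])
    close_tag <- paste0("</", name, ">")
    close_i <- which(lines == close_tag)
    close_i <- close_i[close_i > i][1]
    if (is.na(close_i)) abort(paste0("Unterminated section <", name, "> in ", path))
    sections[[name]] <- lines[seq(i + 1L, close_i - 1L)]
  }
  if (is.null(sections$Code_Summary)) {
    abort(paste0("Missing Code_Summary section in ", path))
  }
  cs_lines <- sections$Code_Summary
  cs_lines <- cs_lines[nzchar(trimws(cs_lines))]
  fields <- strsplit(cs_lines, ",", fixed = TRUE)
  header <- trimws(fields[[1]])
  need <- c("CodeClass", "Name", "Accession", "Count")
  if (!all(need %in% header)) {
    abort(paste0("Code_Summary header must contain ", toString(need), " in ", path))
  }
  rows <- fields[-1]
  get <- function(r, col) trimws(r[match(col, header)])
  name <- vapply(rows, get, character(1), "Name")
  if (anyDuplicated(name)) {
    abort(paste0("Duplicate probe Name '", name[duplicated(name)][1],
                 "' in ", path))
  }
  count_chr <- vapply(rows, get, character(1), "Count")
  if (any(!grepl("^[0-9]+$", count_chr))) {
    bad <- count_chr[!grepl("^[0-9]+$", count_chr)][1]
    abort(paste0("Non-integer Count '", bad, "' in ", path))
  }
  sample_id <- NA_character_
  if (!is.null(sections$Sample_Attributes)) {
    sa <- strsplit(sections$Sample_Attributes, ",", fixed = TRUE)
    for (kv in sa) {
      if (length(kv) >= 2 && trimws(kv[1]) == "ID" && nzchar(trimws(kv[2]))) {
        sample_id <- trimws(kv[2])
        break
      }
    }
  }
  if (is.na(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  list(
    path = path,
    sample_id = sample_id,
    code_summary = data.frame(
      CodeClass = vapply(rows, get, character(1), "CodeClass"),
      Name = name,
      Accession = vapply(rows, get, character(1), "Accession"),
      Count = as.numeric(count_chr),
      stringsAsFactors = FALSE
    )
  )
}
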