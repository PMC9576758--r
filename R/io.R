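#' Read an expression matrix from TSV
#'
#' Expects the first column to hold gene IDs and the header row sample IDs.
#'
#' @param path TSV file path.
#' @return Genes x samples numeric matrix. Duplicate gene or sample IDs are
#'   an error.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene IDs in ", path, call. = FALSE)
  if (anyDuplicated(names(df)[-1L])) {
    stop("duplicate sample IDs in ", path, call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- genes
  m
}

#' Write an expression matrix to TSV
#'
#' @param matrix Genes x samples matrix.
#' @param path Output path; first column `gene_id`, header row sample IDs.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("malformed GMT line: ", f[1L], call. = FALSE)
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a MAF-like mutation table from TSV
#'
#' Column names are mapped onto the canonical record fields so MAF- and
#' Annovar-style headers can both be consumed.
#'
#' @param path TSV file path.
#' @param column_map Named character vector mapping canonical names
#'   (`sample_id`, `gene`, `variant_class`, `sift`, `polyphen_hdiv`,
#'   `polyphen_hvar`, `fathmm`, `clinvar`) to the file's column names.
#'   Canonical names absent from the map are looked up verbatim; evidence
#'   columns may be missing from the file.
#' @return Data frame with canonical column names; empty annotation strings
#'   become `NA`.
#' @export
read_mutation_tsv <- function(path, column_map = character()) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  canon <- c("sample_id", "gene", "variant_class", "sift", "polyphen_hdiv",
             "polyphen_hvar", "fathmm", "clinvar")
  out <- list()
  for (field in canon) {
    src <- if (field %in% names(column_map)) column_map[[field]] else field
    if (src %in% names(df)) out[[field]] <- df[[src]]
  }
  need <- c("sample_id", "gene", "variant_class")
  if (!all(need %in% names(out))) {
    stop("mutation table must provide columns: ",
         paste(setdiff(need, names(out)), collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  for (col in intersect(canon[-(1:3)], names(out))) {
    v <- as.character(out[[col]])
    v[!nzchar(trimws(v))] <- NA_character_
    out[[col]] <- v
  }
  out
}
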