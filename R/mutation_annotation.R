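#' Variant classes kept as protein-sequence-altering
#'
#' The analysis keeps only mutations that alter the protein sequence; silent,
#' splicing, intronic, upstream and downstream variants are excluded. Class
#' strings are matched case-insensitively after stripping a trailing
#' `_mutation` and mapping common MAF spellings (e.g. `Frame_Shift_Del`) onto
#' the canonical vocabulary.
#'
#' @return Character vector of retained canonical variant classes.
#' @export
protein_altering_classes <- function() {
  c("missense", "nonsense", "nonstop", "frameshift", "inframe_indel",
    "start_lost", "stop_lost", "translation_start_site")
}

.excluded_classes <- function() {
  c("silent", "splicing", "intronic", "upstream", "downstream",
    "splice_site", "intron", "5'utr", "3'utr", "igr", "rna")
}

# canonicalize a variant_class string: lower-case, MAF spellings mapped
.canon_class <- function(x) {
  x <- tolower(trimws(x))
  x <- sub("_mutation$", "", x)
  map <- c(frame_shift_del = "frameshift", frame_shift_ins = "frameshift",
           in_frame_del = "inframe_indel", in_frame_ins = "inframe_indel",
           "5'flank" = "upstream", "3'flank" = "downstream",
           splice_region = "splicing")
  hit <- match(x, names(map))
  x[!is.na(hit)] <- map[hit[!is.na(hit)]]
  x
}

#' Filter a mutation table to protein-altering records
#'
#' @param table Data frame with at least `sample_id`, `gene`,
#'   `variant_class` columns (MAF-like).
#' @param classes Canonical classes to retain; defaults to
#'   [protein_altering_classes()].
#' @return The retained rows, with a message reporting how many records were
#'   excluded. Unknown `variant_class` values raise a warning and are
#'   excluded rather than failing.
#' @examples
#' tab <- data.frame(sample_id = "s1", gene = "BRAF",
#'                   variant_class = c("missense", "silent", "intronic",
#'                                     "frameshift"))
#' filter_protein_altering(tab)$variant_class
#' @export
filter_protein_altering <- function(table, classes = protein_altering_classes()) {
  stopifnot(is.data.frame(table),
            all(c("sample_id", "gene", "variant_class") %in% names(table)))
  if (nrow(table) == 0L) return(table)
  cls <- .canon_class(table$variant_class)
  unknown <- !(cls %in% classes) & !(cls %in% .excluded_classes())
  if (any(unknown)) {
    warning(sprintf("excluding %d record(s) with unknown variant_class: %s",
                    sum(unknown),
                    paste(unique(cls[unknown]), collapse = ", ")),
            call. = FALSE)
  }
  keep <- cls %in% classes
  message(sprintf("filter_protein_altering: retained %d of %d records (%d excluded)",
                  sum(keep), nrow(table), sum(!keep)))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default damaging/pathogenic vocabularies for the consensus call
#'
#' The categorical calls each tool itself emits: SIFT `D`(eleterious),
#' PolyPhen-2 `D` (probably damaging) and `P` (possibly damaging), FATHMM
#' `D`, and ClinVar `Pathogenic`/`Likely_pathogenic`. Matching is
#' case-insensitive and tolerant of spaces vs underscores.
#'
#' @return Named list of character vectors, one per evidence column.
#' @export
damaging_vocabulary <- function() {
  list(
    sift = c("d", "deleterious"),
    polyphen_hdiv = c("d", "p", "probably_damaging", "possibly_damaging"),
    polyphen_hvar = c("d", "p", "probably_damaging", "possibly_damaging"),
    fathmm = c("d", "deleterious"),
    clinvar = c("pathogenic", "likely_pathogenic")
  )
}

.norm_ann <- function(x) gsub(" ", "_", tolower(trimws(as.character(x))))

#' Consensus pathogenicity call per mutation record
#'
#' A record is called pathogenic if any computational tool (SIFT, PolyPhen-2
#' HDIV, PolyPhen-2 HVAR, FATHMM) calls it damaging, or ClinVar marks it
#' pathogenic or likely pathogenic. Missing fields never count as damaging.
#'
#' @param table Data frame of mutation records; evidence columns (`sift`,
#'   `polyphen_hdiv`, `polyphen_hvar`, `fathmm`, `clinvar`) may be absent or
#'   `NA`.
#' @param vocabulary Damaging vocabularies per column; defaults to
#'   [damaging_vocabulary()].
#' @return Integer vector (0/1), one call per row of `table`.
#' @examples
#' call_pathogenic(data.frame(sift = "T", clinvar = "Likely pathogenic"))
#' call_pathogenic(data.frame(sift = NA, clinvar = NA))
#' @export
call_pathogenic <- function(table, vocabulary = damaging_vocabulary()) {
  stopifnot(is.data.frame(table))
  out <- rep(0L, nrow(table))
  for (col in names(vocabulary)) {
    if (!col %in% names(table)) next
    v <- .norm_ann(table[[col]])
    hit <- !is.na(v) & v %in% vocabulary[[col]]
    out[hit] <- 1L
  }
  out
}

#' Build per-sample alteration labels for a pathway
#'
#' For each sample: `any_mutation = 1` iff it has at least one (already
#' filtered) record in the pathway's driver genes; `pathogenic_mutation = 1`
#' iff at least one such record passes the consensus pathogenicity call.
#' Samples with no records get 0/0.
#'
#' @param table Mutation table, already passed through
#'   [filter_protein_altering()].
#' @param pathway A [pathway_definition()].
#' @param samples Character vector covering the cohort; a sample present in
#'   `table` but absent here is an error (guards against silent ID
#'   mismatches).
#' @param vocabulary Passed to [call_pathogenic()].
#' @return Data frame (`sample_id`, `any_mutation`, `pathogenic_mutation`),
#'   one row per entry of `samples`, in the same order.
#' @export
build_labels <- function(table, pathway, samples,
                         vocabulary = damaging_vocabulary()) {
  stopifnot(is.data.frame(table), inherits(pathway, "pathway_definition"),
            is.character(samples), length(samples) > 0L)
  stray <- setdiff(unique(table$sample_id), samples)
  if (length(stray) > 0L) {
    stop(sprintf("mutation table contains %d sample(s) absent from `samples` (e.g. %s)",
                 length(stray), stray[1L]), call. = FALSE)
  }
  in_driver <- table$gene %in% pathway$driver_genes
  drv <- table[in_driver, , drop = FALSE]
  patho <- call_pathogenic(drv, vocabulary)
  any_mut <- as.integer(samples %in% drv$sample_id)
  path_mut <- as.integer(samples %in% drv$sample_id[patho == 1L])
  data.frame(sample_id = samples, any_mutation = any_mut,
             pathogenic_mutation = path_mut, stringsAsFactors = FALSE)
}
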