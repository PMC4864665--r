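#' Reference databases of annotated marker sequences
#'
#' A `reference_db` couples marker-gene sequences with fully specified
#' eight-rank lineages (the PR2 convention).  Every entry must carry a
#' complete lineage; partial annotations belong in OTU assignments, not in
#' the reference.
#'
#' @param ids unique sequence identifiers.
#' @param seqs sequences (non-empty), same length as `ids`.
#' @param lineages a character matrix with 8 columns (one row per entry) or a
#'   character vector of semicolon-joined 8-rank strings.
#' @return A `reference_db` object: list with `ids`, `seq` (named character)
#'   and `lineage` (character matrix, rownames = ids, 8 columns).
#' @export
reference_db <- function(ids, seqs, lineages) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicated reference ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs))) stop("reference sequences must be non-empty")
  if (is.character(lineages) && is.null(dim(lineages))) {
    parts <- strsplit(lineages, ";", fixed = TRUE)
    nrk <- lengths(parts)
    if (any(nrk != 8))
      stop("lineage(s) with != 8 ranks for id(s): ",
           paste(head(ids[nrk != 8], 5), collapse = ", "))
    lineages <- do.call(rbind, parts)
  }
  lineages <- as.matrix(lineages)
  if (ncol(lineages) != 8) stop("lineage matrix must have 8 columns")
  if (nrow(lineages) != length(ids))
    stop("one lineage per reference sequence required")
  if (any(lineages == "" | is.na(lineages)))
    stop("reference lineages must be fully specified (depth 8)")
  rownames(lineages) <- ids
  colnames(lineages) <- rank_names_
  structure(list(ids = ids, seq = setNames(as.character(seqs), ids),
                 lineage = lineages),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d entries, sequence lengths %d-%d\n",
              length(x$ids), min(nchar(x$seq)), max(nchar(x$seq))))
  invisible(x)
}

#' Load a reference database from FASTA + taxonomy table
#'
#' The taxonomy table is a two-column TSV (no header requirement beyond the
#' first row being data or a header named `id`/`lineage`): sequence id and a
#' semicolon-joined 8-rank lineage.  Every FASTA id must be present.
#'
#' @param fasta_path FASTA file of reference sequences.
#' @param taxonomy_path TSV mapping every FASTA id to its lineage.
#' @return A [reference_db].
#' @export
parse_reference_db <- function(fasta_path, taxonomy_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  tax <- read.delim(taxonomy_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("id", "lineage"), quote = "")
  if (identical(tolower(tax$id[1]), "id")) tax <- tax[-1, , drop = FALSE]
  missing <- setdiff(ids, tax$id)
  if (length(missing) > 0)
    stop("FASTA id(s) missing from taxonomy table: ",
         paste(head(missing, 10), collapse = ", "))
  lin <- tax$lineage[match(ids, tax$id)]
  message(sprintf("reference database: %d entries loaded", length(ids)))
  reference_db(ids, as.character(seqs), lin)
}

#' Write a reference database as FASTA + taxonomy TSV
#'
#' @param db a [reference_db].
#' @param fasta_path,taxonomy_path output paths.
#' @return `fasta_path`, invisibly.
#' @export
export_reference_db <- function(db, fasta_path, taxonomy_path) {
  writeLines(paste0(">", db$ids, "\n", unname(db$seq)), fasta_path)
  lin <- apply(db$lineage, 1, paste, collapse = ";")
  writeLines(paste0(db$ids, "\t", lin), taxonomy_path)
  invisible(fasta_path)
}

#' Drop entries from a reference database
#'
#' @param db a [reference_db].
#' @param ids entry ids to remove.
#' @return The reduced [reference_db].
#' @export
drop_reference_entries <- function(db, ids) {
  keep <- setdiff(db$ids, ids)
  if (length(keep) == 0) stop("cannot drop every reference entry")
  reference_db(keep, db$seq[keep], db$lineage[keep, , drop = FALSE])
}
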