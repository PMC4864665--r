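#' OTU-by-sample count tables
#'
#' The central container of the pipeline: an OTU x sample matrix of
#' non-negative integer counts, plus the centroid sequence of every OTU
#' (with the concatenation junction for two-read amplicons), its lineage
#' annotation, and the marker the table was built from.
#'
#' @param counts integer matrix, OTUs in rows (rownames = OTU ids), samples
#'   in columns (colnames = sample ids).
#' @param centroids named character vector of centroid sequences covering all
#'   OTU ids (may be empty for tables read back from disk).
#' @param junctions optional named integer vector: concatenation junction per
#'   centroid (NA for merged amplicons).
#' @param lineages optional named character vector of semicolon-joined
#'   lineages (partial depth allowed; "" = unclassified).
#' @param marker `"16S"` or `"18S"`.
#' @param unassigned optional per-sample counts of reads that mapped to no
#'   centroid (kept so read totals are conserved).
#' @return An `otu_table` object.
#' @export
otu_table <- function(counts, centroids = character(0), junctions = NULL,
                      lineages = NULL, marker = c("16S", "18S"),
                      unassigned = NULL) {
  marker <- match.arg(marker)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    stop("counts must have OTU-id rownames")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) stop("counts must have sample-id colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (length(centroids) > 0) {
    missing <- setdiff(rownames(counts), names(centroids))
    if (length(missing) > 0)
      stop("OTU(s) without centroid sequence: ",
           paste(head(missing, 5), collapse = ", "))
  }
  if (!is.null(lineages)) {
    lineages <- setNames(as.character(lineages), names(lineages))
  }
  structure(list(counts = counts,
                 centroids = centroids,
                 junctions = junctions,
                 lineages = lineages,
                 marker = marker,
                 unassigned = unassigned),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table (%s): %d OTUs x %d samples, %s reads assigned\n",
              x$marker, nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Serialise / load an OTU table as TSV
#'
#' One row per OTU, one column per sample, and a trailing `lineage` column
#' (semicolon-joined ranks; empty = unclassified).  Centroid sequences are
#' carried separately as FASTA (see [export_centroids_fasta()]), so
#' `read_otu_table(write_otu_table(x))` restores counts and lineages exactly.
#'
#' @param table an [otu_table].
#' @param path output/input TSV path.
#' @param marker marker tag to attach on reading.
#' @return `write_otu_table` returns `path` invisibly; `read_otu_table`
#'   returns an [otu_table].
#' @export
write_otu_table <- function(table, path) {
  counts <- table$counts
  if (any(counts < 0)) stop("counts must be non-negative")
  lin <- if (is.null(table$lineages)) rep("", nrow(counts))
         else unname(table$lineages[rownames(counts)])
  lin[is.na(lin)] <- ""
  df <- cbind(data.frame(OTU_ID = rownames(counts) %||% character(0),
                         stringsAsFactors = FALSE),
              as.data.frame(counts, check.names = FALSE),
              data.frame(lineage = lin, stringsAsFactors = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path, marker = c("16S", "18S")) {
  marker <- match.arg(marker)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2 || names(df)[1] != "OTU_ID" ||
      names(df)[ncol(df)] != "lineage")
    stop("not an OTU-table TSV: expected OTU_ID ... lineage columns")
  sample_cols <- setdiff(names(df), c("OTU_ID", "lineage"))
  if (nrow(df) == 0) {
    counts <- matrix(0L, 0, length(sample_cols),
                     dimnames = list(character(0), sample_cols))
    return(otu_table(counts, marker = marker))
  }
  num <- suppressWarnings(
    vapply(df[sample_cols], as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(df$OTU_ID, sample_cols))
  if (any(is.na(num)))
    stop("non-numeric count in OTU table: ", path)
  if (any(num != round(num)))
    stop("non-integer count in OTU table: ", path)
  lin <- setNames(df$lineage, df$OTU_ID)
  otu_table(num, lineages = lin, marker = marker)
}

#' Export OTU centroid sequences as FASTA
#'
#' Concatenated centroids carry their junction index in the header
#' (`>OTU_3 junction=271`), so the split point survives the round trip.
#'
#' @param table an [otu_table] with centroid sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
export_centroids_fasta <- function(table, path) {
  ids <- rownames(table$counts)
  if (length(table$centroids) == 0) stop("table carries no centroid sequences")
  hdr <- ids
  if (!is.null(table$junctions)) {
    j <- table$junctions[ids]
    hdr <- ifelse(is.na(j), ids, paste0(ids, " junction=", j))
  }
  writeLines(paste0(">", hdr, "\n", unname(table$centroids[ids])), path)
  invisible(path)
}

#' Sample metadata tables
#'
#' Reads a TSV with one row per sample.  Columns `sample_id`, `salinity`
#' (practical salinity, unitless) and `temperature` (degrees C) are required;
#' any further columns (station labels, coordinates, ...) are preserved.
#'
#' @param path TSV path.
#' @return A data frame with one row per sample.
#' @export
parse_sample_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("sample_id", "salinity", "temperature")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  for (col in c("salinity", "temperature")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]])) || anyNA(v))
      stop("non-numeric ", col, " in metadata")
    df[[col]] <- v
  }
  if (any(df$salinity < 0)) stop("salinity must be >= 0")
  df
}
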