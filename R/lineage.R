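#' Eight-rank taxonomy paths
#'
#' Lineages follow the PR2-style eight-rank convention (levels 1-8:
#' kingdom, supergroup, division/phylum, class, order, family, genus,
#' species).  A lineage carries an assignment `depth`: ranks beyond the depth
#' are empty strings, and depth 0 means unclassified.
#'
#' @param ranks character vector of up to 8 rank names (padded with "").
#' @param depth number of assigned ranks; defaults to the number of leading
#'   non-empty ranks.
#' @return A `lineage` object (list with `ranks` and `depth`).
#' @export
lineage <- function(ranks, depth = NULL) {
  ranks <- as.character(ranks)
  if (length(ranks) > 8) stop("a lineage has at most 8 ranks")
  ranks <- c(ranks, rep("", 8 - length(ranks)))
  ranks[is.na(ranks)] <- ""
  if (is.null(depth)) {
    nz <- ranks != ""
    depth <- if (any(!nz)) which(!nz)[1] - 1L else 8L
  }
  depth <- as.integer(depth)
  if (depth < 0 || depth > 8) stop("depth must be in 0..8")
  if (depth < 8 && any(ranks[(depth + 1):8] != ""))
    stop("ranks beyond the assignment depth must be empty")
  if (depth > 0 && any(ranks[seq_len(depth)] == ""))
    stop("assigned ranks must be non-empty up to the depth")
  structure(list(ranks = ranks, depth = depth), class = "lineage")
}

#' @export
print.lineage <- function(x, ...) {
  cat(sprintf("lineage (depth %d): %s\n", x$depth, lineage_string(x)))
  invisible(x)
}

#' Serialise a lineage as a semicolon-joined string
#'
#' @param x a [lineage], or a character vector of ranks.
#' @return A single string of the assigned ranks joined by `";"`.
#' @export
lineage_string <- function(x) {
  if (inherits(x, "lineage")) {
    if (x$depth == 0) return("")
    return(paste(x$ranks[seq_len(x$depth)], collapse = ";"))
  }
  paste(x[x != ""], collapse = ";")
}

#' Parse a semicolon-joined lineage string
#'
#' @param x character vector of strings such as
#'   `"Euk;Alveolata;Dinophyta;Dinophyceae"`.
#' @param full require all 8 ranks (used for reference lineages).
#' @return A list of [lineage] objects.
#' @export
parse_lineage <- function(x, full = FALSE) {
  lapply(x, function(s) {
    ranks <- if (is.na(s) || !nzchar(s)) character(0)
             else strsplit(s, ";", fixed = TRUE)[[1]]
    if (full && length(ranks) != 8)
      stop(sprintf("expected 8 semicolon-separated ranks, got %d in '%s'",
                   length(ranks), s))
    lineage(ranks)
  })
}

rank_names_ <- c("kingdom", "supergroup", "division", "class",
                 "order", "family", "genus", "species")
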