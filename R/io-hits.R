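HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a 12-column tabular alignment hit file
#'
#' Parses the standard 12-column tab-separated alignment format
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Reverse-strand hits (subject start greater than subject
#' end) are normalized by swapping the subject coordinates and recording
#' `strand = "-"`, so downstream code sees `sstart <= send` throughout.
#' Row order is preserved.
#'
#' @param path Path to the hit file.
#' @return A data.frame of hits with a `strand` column appended.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "",
                            comment.char = "")
  if (length(nf) == 0L) {
    return(as_hit_table(stats::setNames(
      data.frame(character(0), character(0), numeric(0), integer(0),
                 integer(0), integer(0), integer(0), integer(0),
                 integer(0), integer(0), numeric(0), numeric(0)),
      HIT_COLUMNS)))
  }
  bad <- which(nf != 12L)
  if (length(bad)) {
    stop("hit table row ", bad[1L], " has ", nf[bad[1L]],
         " columns, expected 12", call. = FALSE)
  }
  df <- utils::read.delim(path, header = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          col.names = HIT_COLUMNS,
                          colClasses = c("character", "character", "numeric",
                                         "integer", "integer", "integer",
                                         "integer", "integer", "integer",
                                         "integer", "numeric", "numeric"))
  as_hit_table(df)
}

#' Validate and normalize an in-memory hit table
#'
#' @param df A data.frame with the 12 standard alignment columns.
#' @return The normalized hit table (strand flagged, subject coordinates
#'   ascending).
#' @export
as_hit_table <- function(df) {
  missing_cols <- setdiff(HIT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("hit table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, c(HIT_COLUMNS, setdiff(names(df), HIT_COLUMNS)), drop = FALSE]
  if (any(df$evalue < 0)) stop("negative e-value", call. = FALSE)
  if (any(df$pident < 0 | df$pident > 100)) {
    stop("percent identity outside [0, 100]", call. = FALSE)
  }
  if (any(df$qstart > df$qend)) {
    stop("query coordinates must be ascending", call. = FALSE)
  }
  if (is.null(df$strand)) {
    rev <- df$sstart > df$send
    df$strand <- ifelse(rev, "-", "+")
    tmp <- df$sstart[rev]
    df$sstart[rev] <- df$send[rev]
    df$send[rev] <- tmp
  }
  rownames(df) <- NULL
  df
}

#' Write a hit table in the 12-column tabular format
#'
#' Strand is folded back into the subject coordinates (descending for
#' minus-strand hits), inverting the normalization done on read.
#'
#' @param hits A hit table from [read_hit_table()] or [as_hit_table()].
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  out <- hits[, HIT_COLUMNS]
  rev <- !is.null(hits$strand) & hits$strand == "-"
  tmp <- out$sstart[rev]
  out$sstart[rev] <- out$send[rev]
  out$send[rev] <- tmp
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column synonym table (label, canonical)
#' @param path Path to a TSV with columns `label`, `canonical`.
#' @return A synonym map (named character vector), see [synonym_map()].
#' @export
read_synonyms <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  synonym_map(df$label, df$canonical)
}

#' Read a term lookup table (subject_id, term)
#' @param path Path to a TSV with columns `subject_id`, `term`.
#' @return A data.frame with those two columns.
#' @export
read_terms <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("subject_id", "term") %in% names(df))) {
    stop("term table needs columns subject_id and term", call. = FALSE)
  }
  df[, c("subject_id", "term")]
}
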