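#' Read a FASTA file of nucleotide sequences
#'
#' Parses with Biostrings after a light structural scan that reports the
#' offending line number for malformed input. Sequences are uppercased and
#' `U` is mapped to `T`, so RNA-style input becomes DNA. Identifiers are the
#' first whitespace-delimited token of each header; the remainder is kept as
#' the description.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by sequence id, with a
#'   `description` column in its metadata columns.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = character(0))
    return(out)
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[nonblank[1L]]) {
    stop("malformed FASTA: line ", nonblank[1L],
         " precedes the first header", call. = FALSE)
  }
  headers <- which(is_header)
  # a header followed immediately by another header (or EOF) has no sequence
  next_line <- c(headers[-1L], length(lines) + 1L)
  for (i in seq_along(headers)) {
    body <- lines[seq2(headers[i] + 1L, next_line[i] - 1L)]
    if (sum(nchar(trimws(body))) == 0L) {
      stop("malformed FASTA: empty sequence for header at line ",
           headers[i], call. = FALSE)
    }
    if (nchar(trimws(lines[headers[i]])) <= 1L) {
      stop("malformed FASTA: empty header at line ", headers[i],
           call. = FALSE)
    }
  }
  raw <- Biostrings::readBStringSet(path)
  seqs <- chartr("uU", "tT", as.character(raw))
  out <- Biostrings::DNAStringSet(toupper(seqs))
  full <- names(raw)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

# seq() that yields integer(0) when from > to, unlike base seq()
seq2 <- function(from, to) {
  if (from > to) integer(0) else seq.int(from, to)
}

#' Write sequences to FASTA
#'
#' @param x A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Clean raw reads of adaptor and polyA sequence
#'
#' Removes exact adaptor matches from either read end (longest adaptor
#' first), then terminal polyA (3') and polyT (5') runs of at least 8 bases
#' allowing at most one interrupting base, and finally drops reads of 30 bp
#' or less. The length floor comes from the library-cleaning convention for
#' pyrosequencing EST data; the polyA rule is this package's operational
#' definition of "polyA trimming".
#'
#' @param reads A named [Biostrings::DNAStringSet] or named character vector.
#' @param adaptors Character vector of adaptor/primer sequences (may be
#'   empty).
#' @param cfg A [pipeline_config()].
#' @return A [Biostrings::DNAStringSet] of retained, trimmed reads.
#' @export
clean_reads <- function(reads, adaptors = character(0),
                        cfg = pipeline_config()) {
  ids <- names(reads)
  seqs <- unname(as.character(reads))
  adaptors <- adaptors[order(nchar(adaptors), decreasing = TRUE)]
  # iterate to a fixpoint: trimming may expose a further adaptor copy or
  # terminal run, and cleaning must be idempotent
  repeat {
    before <- seqs
    for (ad in adaptors) {
      pre <- startsWith(seqs, ad)
      seqs[pre] <- substring(seqs[pre], nchar(ad) + 1L)
      suf <- endsWith(seqs, ad)
      seqs[suf] <- substring(seqs[suf], 1L, nchar(seqs[suf]) - nchar(ad))
    }
    seqs <- vapply(seqs, trim_terminal_run, character(1),
                   base = "A", end = "3", USE.NAMES = FALSE)
    seqs <- vapply(seqs, trim_terminal_run, character(1),
                   base = "T", end = "5", USE.NAMES = FALSE)
    if (identical(seqs, before)) break
  }
  keep <- nchar(seqs) >= cfg$min_read_length_after_clean
  out <- Biostrings::DNAStringSet(seqs[keep])
  names(out) <- ids[keep]
  out
}

# Trim a terminal homopolymer run of `base` (>= 8 occurrences, at most one
# interrupting base) from the 3' or 5' end. Returns the trimmed sequence.
trim_terminal_run <- function(seq, base, end = c("3", "5"), min_run = 8L) {
  end <- match.arg(end)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) return(seq)
  idx <- if (end == "3") n:1 else 1:n
  n_base <- 0L
  n_other <- 0L
  consumed <- 0L
  for (i in idx) {
    if (chars[i] == base) {
      n_base <- n_base + 1L
    } else {
      n_other <- n_other + 1L
      if (n_other > 1L) break
    }
    consumed <- consumed + 1L
  }
  # do not count a trailing interruption that no run follows
  while (consumed > 0L) {
    j <- if (end == "3") n - consumed + 1L else consumed
    if (chars[j] != base) {
      consumed <- consumed - 1L
      n_other <- n_other - 1L
    } else {
      break
    }
  }
  if (n_base < min_run) return(seq)
  if (end == "3") {
    substring(seq, 1L, n - consumed)
  } else {
    substring(seq, consumed + 1L)
  }
}
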