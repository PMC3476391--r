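#' Build a read-alignment table
#'
#' Validates the gapped read-to-isotig alignment records consumed by the
#' variant caller. `read_aln` and `isotig_aln` are equal-length aligned
#' strings in isotig orientation (`-` for gaps); minus-strand reads must
#' already be reverse-complemented into isotig orientation, with `strand`
#' recording the fact so edge trimming can follow the original read ends.
#'
#' @param df A data.frame with columns `read_id`, `isotig_id`, `read_len`,
#'   `qstart`, `qend` (1-based on the original read), `sstart`, `send`
#'   (1-based on the isotig), `pident`, `evalue`, `read_aln`, `isotig_aln`,
#'   and optionally `strand` (default `"+"`).
#' @return The validated data.frame.
#' @export
as_read_alignments <- function(df) {
  need <- c("read_id", "isotig_id", "read_len", "qstart", "qend",
            "sstart", "send", "pident", "evalue", "read_aln", "isotig_aln")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("alignment table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$strand)) df$strand <- "+"
  if (any(nchar(df$read_aln) != nchar(df$isotig_aln))) {
    stop("aligned strings must have equal length", call. = FALSE)
  }
  if (any(df$qstart > df$qend) || any(df$sstart > df$send)) {
    stop("alignment coordinates must be ascending", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Filter read alignments before variant calling
#'
#' Keeps alignments with e-value strictly below the cutoff, identity at or
#' above the minimum, and at most `snp_edge_slack` unaligned bases at each
#' read end ("all but the last five bases on each end of the read" at the
#' defaults). After per-alignment filtering, any read whose retained
#' alignments touch more than one isogroup has all of its alignments
#' removed: such reads are ambiguous between putative genes.
#'
#' @param alignments A table from [as_read_alignments()].
#' @param group_map Data.frame `isotig_id`, `isogroup_id` covering every
#'   aligned isotig.
#' @param cfg A [pipeline_config()].
#' @return The filtered alignment table.
#' @export
filter_alignments <- function(alignments, group_map,
                              cfg = pipeline_config()) {
  aln <- as_read_alignments(alignments)
  unknown <- setdiff(aln$isotig_id, group_map$isotig_id)
  if (length(unknown)) {
    stop("isotigs missing from the isogroup map: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  left_over <- aln$qstart - 1L
  right_over <- aln$read_len - aln$qend
  keep <- aln$evalue < cfg$snp_evalue &
    aln$pident >= cfg$snp_min_identity &
    left_over <= cfg$snp_edge_slack &
    right_over <= cfg$snp_edge_slack
  aln <- aln[keep, , drop = FALSE]
  if (nrow(aln) == 0L) return(aln)
  ig <- group_map$isogroup_id[match(aln$isotig_id, group_map$isotig_id)]
  n_groups <- tapply(ig, aln$read_id, function(g) length(unique(g)))
  multi <- names(n_groups)[n_groups > 1L]
  aln <- aln[!aln$read_id %in% multi, , drop = FALSE]
  rownames(aln) <- NULL
  aln
}

#' Edge-trim alignments and tally a pileup
#'
#' Read bases whose coordinate on the original read falls within
#' `snp_trim` bases of either read end contribute nothing (alignment edges
#' are error-prone). Remaining aligned bases are tallied per isotig
#' position; a read gap (deletion) contributes a `gap` count at the isotig
#' position it spans, and inserted read bases consume no isotig position.
#'
#' @param alignments Filtered alignments ([filter_alignments()]).
#' @param cfg A [pipeline_config()].
#' @return A data.frame of pileup columns: `isotig_id`, `position`
#'   (1-based), counts `A`, `C`, `G`, `T`, `gap`, and `depth` (non-gap).
#' @export
trim_and_pileup <- function(alignments, cfg = pipeline_config()) {
  empty <- data.frame(isotig_id = character(0), position = integer(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0), gap = integer(0), depth = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(alignments) == 0L) return(empty)
  trim <- cfg$snp_trim
  pieces <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    r <- strsplit(alignments$read_aln[i], "", fixed = TRUE)[[1]]
    s <- strsplit(alignments$isotig_aln[i], "", fixed = TRUE)[[1]]
    r_nongap <- r != "-"
    s_nongap <- s != "-"
    # coordinate of each aligned column on the original read; gaps take the
    # coordinate of the preceding read base (for trim purposes)
    read_coord <- cumsum(r_nongap)
    if (alignments$strand[i] == "-") {
      read_coord <- alignments$qend[i] + 1L - read_coord
      read_coord[!r_nongap] <- read_coord[!r_nongap] - 1L
    } else {
      read_coord <- alignments$qstart[i] - 1L + read_coord
    }
    iso_pos <- alignments$sstart[i] - 1L + cumsum(s_nongap)
    keep <- s_nongap &
      read_coord > trim &
      read_coord <= alignments$read_len[i] - trim
    if (!any(keep)) next
    base <- r[keep]
    base[base == "-"] <- "gap"
    pieces[[i]] <- data.frame(isotig_id = alignments$isotig_id[i],
                              position = iso_pos[keep], base = base,
                              stringsAsFactors = FALSE)
  }
  pieces <- Filter(Negate(is.null), pieces)
  if (!length(pieces)) return(empty)
  dt <- data.table::rbindlist(pieces)
  dt <- dt[dt$base %in% c("A", "C", "G", "T", "gap"), ]
  counts <- data.table::dcast(
    dt[, list(n = .N), by = c("isotig_id", "position", "base")],
    isotig_id + position ~ base, value.var = "n", fill = 0L)
  for (b in c("A", "C", "G", "T", "gap")) {
    if (is.null(counts[[b]])) counts[[b]] <- 0L
  }
  out <- as.data.frame(counts)[, c("isotig_id", "position",
                                   "A", "C", "G", "T", "gap")]
  out$depth <- out$A + out$C + out$G + out$T
  out <- out[order(out$isotig_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call SNPs from pileup columns
#'
#' Per column, the major allele is the most frequent non-gap base and the
#' minor allele the second most frequent; the column is called iff the
#' minor allele is supported by at least `snp_min_support` reads and its
#' frequency among non-gap bases strictly exceeds `snp_min_maf`. Gap
#' "alleles" never participate: indels are the platform's dominant error
#' mode and are excluded from both the candidate alleles and the depth
#' denominator. Ties for major/minor rank are broken alphabetically, so
#' calls are deterministic.
#'
#' @param columns Pileup from [trim_and_pileup()].
#' @param cfg A [pipeline_config()].
#' @return A data.frame of calls: `isotig_id`, `position`, `major`,
#'   `minor`, `minor_count`, `depth`, `minor_freq`.
#' @export
call_snps <- function(columns, cfg = pipeline_config()) {
  empty <- data.frame(isotig_id = character(0), position = integer(0),
                      major = character(0), minor = character(0),
                      minor_count = integer(0), depth = integer(0),
                      minor_freq = numeric(0), stringsAsFactors = FALSE)
  if (nrow(columns) == 0L) return(empty)
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(columns[, bases])
  # order decreasing by count with alphabetical tie-break
  rank1 <- max.col(cnt, ties.method = "first")
  major_count <- cnt[cbind(seq_len(nrow(cnt)), rank1)]
  cnt2 <- cnt
  cnt2[cbind(seq_len(nrow(cnt)), rank1)] <- -1L
  rank2 <- max.col(cnt2, ties.method = "first")
  minor_count <- cnt2[cbind(seq_len(nrow(cnt)), rank2)]
  depth <- columns$depth
  ok <- minor_count >= cfg$snp_min_support &
    depth > 0 &
    minor_count / depth > cfg$snp_min_maf
  if (!any(ok)) return(empty)
  out <- data.frame(
    isotig_id = columns$isotig_id[ok],
    position = columns$position[ok],
    major = bases[rank1[ok]],
    minor = bases[rank2[ok]],
    minor_count = as.integer(minor_count[ok]),
    depth = as.integer(depth[ok]),
    minor_freq = minor_count[ok] / depth[ok],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Deduplicate calls across isotigs of an isogroup
#'
#' Isotigs of one isogroup share contigs, so the same underlying
#' polymorphism is typically called once per isotig. Within an isogroup,
#' calls sharing major allele, minor allele and position key form one
#' redundancy class; exactly one call per class is flagged unique — the
#' one with the greatest minor-allele support, ties broken by smallest
#' isotig id. The position key is the underlying contig position when a
#' contig map is supplied, else the isotig-local position.
#'
#' @param calls Output of [call_snps()].
#' @param group_map Data.frame `isotig_id`, `isogroup_id`.
#' @param contig_map Optional data.frame `isotig_id`, `contig_id`, `start`,
#'   `end` giving each contig's 1-based span within each isotig, used to
#'   translate isotig positions to contig positions.
#' @return `calls` with `isogroup_id` and logical `unique` columns added.
#' @export
dedup_calls <- function(calls, group_map, contig_map = NULL) {
  if (nrow(calls) == 0L) {
    calls$isogroup_id <- character(0)
    calls$unique <- logical(0)
    return(calls)
  }
  idx <- match(calls$isotig_id, group_map$isotig_id)
  if (anyNA(idx)) {
    stop("calls reference isotigs missing from the isogroup map",
         call. = FALSE)
  }
  calls$isogroup_id <- group_map$isogroup_id[idx]
  pos_key <- as.character(calls$position)
  if (!is.null(contig_map)) {
    for (i in seq_len(nrow(calls))) {
      m <- contig_map[contig_map$isotig_id == calls$isotig_id[i] &
                        contig_map$start <= calls$position[i] &
                        contig_map$end >= calls$position[i], , drop = FALSE]
      if (nrow(m) >= 1L) {
        pos_key[i] <- paste0(m$contig_id[1L], ":",
                             calls$position[i] - m$start[1L] + 1L)
      }
    }
  }
  key <- paste(calls$isogroup_id, calls$major, calls$minor, pos_key,
               sep = "\r")
  o <- order(key, -calls$minor_count, calls$isotig_id)
  first <- !duplicated(key[o])
  calls$unique <- logical(nrow(calls))
  calls$unique[o] <- first
  calls
}

#' Variant rate per 1000 bp of assembled sequence
#'
#' @param n_unique Number of unique variant calls.
#' @param assembled_bases Total assembled bases the calls were made over.
#' @return Variants per kilobase.
#' @export
variant_rate <- function(n_unique, assembled_bases) {
  stopifnot(assembled_bases > 0)
  1000 * n_unique / assembled_bases
}

#' Expected false SNP calls from sequencing error
#'
#' Under independent per-base substitution errors at `error_rate`, the
#' chance that a monomorphic site of coverage `depth` accumulates at least
#' `min_support` identical-looking errors is the exact binomial tail
#' `P(X >= min_support)`; multiplied by the number of assayed sites it
#' bounds the expected number of false calls passing the read-support
#' filter.
#'
#' @param error_rate Per-base substitution error probability.
#' @param depth Read depth at the site.
#' @param min_support Minimum reads required to support a minor allele.
#' @param n_sites Number of sites assayed (1 gives the per-site
#'   probability).
#' @return Expected number of false calls.
#' @export
expected_false_snps <- function(error_rate, depth, min_support,
                                n_sites = 1) {
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 1) {
    stop("error_rate must lie in [0, 1]", call. = FALSE)
  }
  if (depth < 0 || min_support < 1) {
    stop("depth must be >= 0 and min_support >= 1", call. = FALSE)
  }
  n_sites * stats::pbinom(min_support - 1, size = depth, prob = error_rate,
                          lower.tail = FALSE)
}
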