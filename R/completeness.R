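#' Reciprocal best hits between a transcriptome and a core gene set
#'
#' A transcript and a core gene are paired if and only if each is the
#' other's best passing alignment: the gene is the transcript's top hit in
#' the forward search and the transcript is the gene's top hit in the
#' reverse search. "Best" is the maximum bit score, with ties broken by
#' smaller e-value and then lexicographically smallest subject id, so the
#' result does not depend on row order.
#'
#' @param forward Hit table of transcriptome-vs-core alignments.
#' @param reverse Hit table of core-vs-transcriptome alignments.
#' @param evalue_cutoff Strict e-value cutoff applied to both directions.
#' @return A data.frame with columns `query_id`, `core_gene_id`, one row
#'   per reciprocal pair.
#' @export
reciprocal_best_hits <- function(forward, reverse, evalue_cutoff = 1e-5) {
  fb <- top_hit(forward, evalue_cutoff)
  rb <- top_hit(reverse, evalue_cutoff)
  if (nrow(fb) == 0L || nrow(rb) == 0L) {
    return(data.frame(query_id = character(0),
                      core_gene_id = character(0),
                      stringsAsFactors = FALSE))
  }
  back <- rb[fb$sseqid, "sseqid"]
  mutual <- !is.na(back) & back == fb$qseqid
  out <- data.frame(query_id = fb$qseqid[mutual],
                    core_gene_id = fb$sseqid[mutual],
                    stringsAsFactors = FALSE)
  out <- out[order(out$core_gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Core-gene recovery report
#'
#' For each recovered core gene, the single best-bit forward alignment is
#' selected and its identity and subject-span coverage are recorded;
#' coverage is the aligned span on the core protein divided by the protein
#' length. Reports the recovery percentage and the means of identity,
#' covered fraction and covered amino acids.
#'
#' @param pairs Output of [reciprocal_best_hits()].
#' @param core A data.frame with columns `id` and `length` (protein length
#'   in aa).
#' @param forward The forward hit table used to derive `pairs`.
#' @return A one-row data.frame (`n_core`, `n_recovered`,
#'   `percent_recovered`, `mean_identity`, `mean_covered_fraction`,
#'   `mean_covered_aa`). An empty pair set reports zeros with a warning.
#' @export
recovery_report <- function(pairs, core, forward) {
  stopifnot(all(c("id", "length") %in% names(core)))
  if (anyDuplicated(core$id)) stop("duplicate core gene id", call. = FALSE)
  if (any(core$length < 1)) stop("core protein length must be >= 1",
                                 call. = FALSE)
  n_core <- nrow(core)
  if (nrow(pairs) == 0L) {
    warning("no reciprocal best hits; reporting zero recovery",
            call. = FALSE)
    return(data.frame(n_core = n_core, n_recovered = 0L,
                      percent_recovered = 0, mean_identity = 0,
                      mean_covered_fraction = 0, mean_covered_aa = 0))
  }
  key <- paste(forward$qseqid, forward$sseqid)
  sel <- forward[key %in% paste(pairs$query_id, pairs$core_gene_id), ,
                 drop = FALSE]
  o <- order(sel$sseqid, -sel$bitscore, sel$evalue, sel$qseqid)
  sel <- sel[o, , drop = FALSE]
  sel <- sel[!duplicated(sel$sseqid), , drop = FALSE]
  plen <- core$length[match(sel$sseqid, core$id)]
  if (anyNA(plen)) {
    stop("recovered gene absent from core set: ",
         paste(sel$sseqid[is.na(plen)], collapse = ", "), call. = FALSE)
  }
  covered_aa <- sel$send - sel$sstart + 1L
  data.frame(
    n_core = n_core,
    n_recovered = nrow(sel),
    percent_recovered = 100 * nrow(sel) / n_core,
    mean_identity = mean(sel$pident),
    mean_covered_fraction = mean(covered_aa / plen),
    mean_covered_aa = mean(covered_aa)
  )
}
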