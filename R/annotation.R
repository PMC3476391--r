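#' Best passing hit per query
#'
#' Keeps, for each query, the hit with the highest bit score among hits
#' whose e-value is strictly below the cutoff. Ties on bit score are broken
#' by smaller e-value, then by lexicographically smallest subject id, so
#' the result is independent of row order. Queries with no passing hit are
#' absent from the result.
#'
#' @param hits A hit table ([read_hit_table()] / [as_hit_table()]).
#' @param evalue_cutoff Strict upper bound on the e-value.
#' @return A hit table with one row per query, named by query id.
#' @export
top_hit <- function(hits, evalue_cutoff = 1e-5) {
  hits <- hits[hits$evalue < evalue_cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  rownames(hits) <- hits$qseqid
  hits
}

#' Top-k passing hits per query, by bit score
#'
#' @param hits A hit table.
#' @param k Number of hits to keep per query.
#' @param evalue_cutoff Strict upper bound on the e-value.
#' @return A hit table with at most `k` rows per query.
#' @export
top_k_hits <- function(hits, k = 5L, evalue_cutoff = 1e-10) {
  hits <- hits[hits$evalue < evalue_cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  hits <- hits[o, , drop = FALSE]
  keep <- stats::ave(seq_len(nrow(hits)), hits$qseqid,
                     FUN = seq_along) <= k
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize a gene label for comparison
#'
#' Case-folds, drops the noise tokens "predicted", "hypothetical" and the
#' "-like" suffix, strips punctuation and squeezes whitespace. Variant
#' spellings of the same gene name then compare equal.
#'
#' @param x Character vector of labels.
#' @return Normalized labels.
#' @export
normalize_label <- function(x) {
  y <- tolower(x)
  y <- gsub("-like\\b", "", y)
  y <- gsub("\\b(predicted|hypothetical)\\b", "", y)
  y <- gsub("[[:punct:]]+", " ", y)
  y <- gsub("\\s+", " ", y)
  trimws(y)
}

#' Build a synonym map
#'
#' Maps (normalized) labels to a canonical label. The map is made
#' idempotent: canonical labels map to themselves, and chains are followed
#' to their terminal canonical form.
#'
#' @param label Character vector of synonym labels.
#' @param canonical Character vector of the same length with each label's
#'   canonical form.
#' @return A named character vector of class `synonym_map`.
#' @export
synonym_map <- function(label = character(0), canonical = character(0)) {
  stopifnot(length(label) == length(canonical))
  map <- stats::setNames(normalize_label(canonical), normalize_label(label))
  # resolve chains a->b, b->c and force idempotence
  for (i in seq_len(5L)) {
    resolved <- ifelse(map %in% names(map), unname(map[map]), map)
    if (identical(resolved, unname(map))) break
    map[] <- resolved
  }
  class(map) <- "synonym_map"
  map
}

#' Apply a synonym map to labels
#'
#' @param labels Character vector of raw labels.
#' @param synonyms A [synonym_map()] (may be empty).
#' @return Canonical normalized labels.
#' @export
canonical_label <- function(labels, synonyms = synonym_map()) {
  norm <- normalize_label(labels)
  hit <- norm %in% names(synonyms)
  norm[hit] <- unname(unclass(synonyms)[norm[hit]])
  norm
}

#' Consolidate per-isotig annotations into one isogroup annotation
#'
#' Implements the cascade used to give each isogroup a single gene label:
#' (1) if every annotated isotig carries the same normalized label the
#' isogroup is annotated directly (`single`); (2) if the labels differ but
#' collapse to one canonical label under the synonym map, the canonical
#' label is assigned (`collapsed_synonym`); (3) otherwise the top five
#' secondary alignments of each isotig (pre-filtered at a strict e-value)
#' are intersected — a gene appearing in every isotig's top five that also
#' matches one of the original labels is assigned (`resolved_top5`), with
#' ties among several such genes broken by the highest cumulative bit score
#' across all isotigs; (4) isogroups that still carry multiple labels are
#' `unresolved` (null label), and isogroups whose isotigs had no hits at
#' all are `none`.
#'
#' @param unit_id The isogroup id.
#' @param isotig_labels Character vector of per-isotig gene labels (NA for
#'   isotigs without a passing hit).
#' @param synonyms A [synonym_map()].
#' @param secondary_hits Optional list, one element per labelled isotig,
#'   each a data.frame with columns `label` and `bitscore` holding that
#'   isotig's top-five secondary alignments (already filtered at the strict
#'   cutoff). Used only when steps (1)-(2) fail.
#' @return A one-row data.frame: `unit_id`, `gene_label`, `status`,
#'   `evidence`.
#' @export
consolidate_isogroup <- function(unit_id, isotig_labels,
                                 synonyms = synonym_map(),
                                 secondary_hits = NULL) {
  labelled <- !is.na(isotig_labels) & nzchar(isotig_labels)
  result <- function(label, status, evidence = "") {
    data.frame(unit_id = unit_id, gene_label = label, status = status,
               evidence = evidence, stringsAsFactors = FALSE)
  }
  if (!any(labelled)) return(result(NA_character_, "none"))
  raw <- isotig_labels[labelled]
  norm <- normalize_label(raw)
  canon <- canonical_label(raw, synonyms)
  if (length(unique(norm)) == 1L) {
    return(result(canon[1L], "single",
                  paste(unique(raw), collapse = "|")))
  }
  if (length(unique(canon)) == 1L) {
    return(result(canon[1L], "collapsed_synonym",
                  paste(unique(raw), collapse = "|")))
  }
  # step 3: intersection of top-5 secondary lists
  if (!is.null(secondary_hits) && length(secondary_hits)) {
    lists <- lapply(secondary_hits, function(df) {
      if (is.null(df) || nrow(df) == 0L) return(NULL)
      df$canon <- canonical_label(df$label, synonyms)
      df
    })
    lists <- Filter(Negate(is.null), lists)
    if (length(lists) == length(secondary_hits) && length(lists) > 0L) {
      shared <- Reduce(intersect, lapply(lists, function(df) df$canon))
      candidates <- intersect(shared, unique(canon))
      if (length(candidates) == 1L) {
        return(result(candidates, "resolved_top5", "top5-intersection"))
      }
      if (length(candidates) > 1L) {
        cum <- vapply(candidates, function(g) {
          sum(vapply(lists, function(df) {
            sum(df$bitscore[df$canon == g])
          }, numeric(1)))
        }, numeric(1))
        best <- candidates[order(-cum, candidates)][1L]
        return(result(best, "resolved_top5",
                      sprintf("top5-cumulative-bits=%.1f", max(cum))))
      }
    }
  }
  result(NA_character_, "unresolved", paste(unique(raw), collapse = "|"))
}

#' Consolidate annotations for every isogroup
#'
#' Convenience driver over [consolidate_isogroup()]: assigns each isotig
#' its best primary hit label, groups isotigs by isogroup, and runs the
#' consolidation cascade.
#'
#' @param isotig_groups A data.frame mapping `isotig_id` to `isogroup_id`.
#' @param primary_hits A hit table of isotig-vs-protein alignments.
#' @param subject_labels Named character vector mapping subject ids to gene
#'   labels (defaults to using subject ids as labels).
#' @param synonyms A [synonym_map()].
#' @param secondary_hits Optional hit table for the top-five rescreen.
#' @param cfg A [pipeline_config()].
#' @return A data.frame with one row per isogroup.
#' @export
consolidate_annotations <- function(isotig_groups, primary_hits,
                                    subject_labels = NULL,
                                    synonyms = synonym_map(),
                                    secondary_hits = NULL,
                                    cfg = pipeline_config()) {
  best <- top_hit(primary_hits, cfg$annotation_evalue)
  label_of <- function(sid) {
    if (is.null(subject_labels)) sid else unname(subject_labels[sid])
  }
  sec <- if (!is.null(secondary_hits)) {
    top_k_hits(secondary_hits, 5L, cfg$ortho_evalue)
  }
  group_ids <- sort(unique(isotig_groups$isogroup_id))
  out <- lapply(group_ids, function(gid) {
    itigs <- isotig_groups$isotig_id[isotig_groups$isogroup_id == gid]
    labels <- vapply(itigs, function(it) {
      if (it %in% best$qseqid) label_of(best[it, "sseqid"])
      else NA_character_
    }, character(1))
    sec_list <- NULL
    if (!is.null(sec)) {
      labelled <- itigs[!is.na(labels)]
      sec_list <- lapply(labelled, function(it) {
        df <- sec[sec$qseqid == it, , drop = FALSE]
        if (nrow(df) == 0L) return(NULL)
        data.frame(label = label_of(df$sseqid), bitscore = df$bitscore,
                   stringsAsFactors = FALSE)
      })
    }
    consolidate_isogroup(gid, labels, synonyms, sec_list)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Census of consolidated annotations
#'
#' Counts isogroups by consolidation status (unresolved isogroups count as
#' annotated: they returned alignments even though no single label could be
#' assigned, matching the bookkeeping convention of the source analyses),
#' plus label-sharing statistics over the isogroups that did receive a
#' label: how many unique labels there are, how many are represented by
#' exactly one isogroup versus several, and the mean number of isogroups
#' per multiply-represented label.
#'
#' @param assignments Output of [consolidate_annotations()].
#' @return A one-row data.frame of summary counts.
#' @export
annotation_census <- function(assignments) {
  st <- assignments$status
  labelled <- !is.na(assignments$gene_label)
  tab <- table(assignments$gene_label[labelled])
  multi <- tab[tab > 1L]
  data.frame(
    n_units = nrow(assignments),
    n_single = sum(st == "single"),
    n_collapsed_synonym = sum(st == "collapsed_synonym"),
    n_resolved_top5 = sum(st == "resolved_top5"),
    n_unresolved = sum(st == "unresolved"),
    n_none = sum(st == "none"),
    n_annotated = sum(st != "none"),
    n_unique_labels = length(tab),
    n_labels_single_unit = sum(tab == 1L),
    n_labels_multi_unit = length(multi),
    mean_units_per_multi_label =
      if (length(multi)) mean(multi) else 0,
    stringsAsFactors = FALSE
  )
}

#' Join term lookup tables (GO, pathway, orthology) onto units
#'
#' Each isotig or singleton is assigned its best passing hit at the
#' source-specific cutoff; a unit inherits the lookup table's terms for
#' that subject. For isogroups, all member isotigs must agree on the
#' subject: isogroups whose isotigs map to different subjects are flagged
#' multi-annotation and excluded. Subjects absent from the lookup table are
#' skipped with a warning.
#'
#' @param hits Hit table of isotig/singleton alignments against the term
#'   source's database.
#' @param lookup A data.frame with columns `subject_id`, `term`.
#' @param evalue_cutoff Strict e-value cutoff for this source.
#' @param unit_map Optional data.frame (`isotig_id`, `isogroup_id`) mapping
#'   queries to isogroups; queries not listed are treated as their own unit
#'   (singletons).
#' @return A list: `terms` (data.frame unit_id, subject_id, term),
#'   `excluded_multi` (character vector of multi-annotation isogroup ids).
#' @export
join_terms <- function(hits, lookup, evalue_cutoff, unit_map = NULL) {
  best <- top_hit(hits, evalue_cutoff)
  empty <- data.frame(unit_id = character(0), subject_id = character(0),
                      term = character(0), stringsAsFactors = FALSE)
  if (nrow(best) == 0L) {
    return(list(terms = empty, excluded_multi = character(0)))
  }
  unit <- best$qseqid
  if (!is.null(unit_map)) {
    idx <- match(best$qseqid, unit_map$isotig_id)
    unit <- ifelse(is.na(idx), best$qseqid, unit_map$isogroup_id[idx])
  }
  per_unit <- split(best$sseqid, unit)
  subjects <- vapply(per_unit, function(s) {
    if (length(unique(s)) == 1L) s[1L] else NA_character_
  }, character(1))
  excluded <- names(subjects)[is.na(subjects)]
  subjects <- subjects[!is.na(subjects)]
  known <- subjects %in% lookup$subject_id
  if (any(!known)) {
    warning("subjects missing from lookup table: ",
            paste(unique(subjects[!known]), collapse = ", "),
            call. = FALSE)
  }
  subjects <- subjects[known]
  if (!length(subjects)) {
    return(list(terms = empty, excluded_multi = excluded))
  }
  terms <- do.call(rbind, lapply(names(subjects), function(u) {
    s <- subjects[[u]]
    data.frame(unit_id = u, subject_id = s,
               term = lookup$term[lookup$subject_id == s],
               stringsAsFactors = FALSE)
  }))
  rownames(terms) <- NULL
  list(terms = terms, excluded_multi = excluded)
}
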