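#' Run the full synthetic post-assembly study end to end
#'
#' Generates a synthetic transcriptome with known truth and pushes it
#' through every processing stage in dependency order: simulate ->
#' isogroup -> annotate -> completeness -> express -> snp -> report. All
#' stage outputs are written as plain-text tables under `out_dir`,
#' together with a run manifest recording the configuration snapshot, the
#' seed and the output paths; re-running with the same manifest reproduces
#' the outputs byte for byte. Stages can be restricted with `stages`
#' (prerequisite computations still run in memory; only writing is
#' skipped).
#'
#' @param out_dir Output directory (created if needed).
#' @param rng_seed Integer seed governing every stochastic step.
#' @param cfg A [pipeline_config()].
#' @param n_genes Number of simulated genes.
#' @param n_core Core gene set size.
#' @param n_snps Planted SNPs.
#' @param depth Read depth for the variant-calling simulation.
#' @param n_random Random probes on the simulated array.
#' @param design Sample design for the expression stage.
#' @param stages Character vector of stages to write.
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a list with each stage's in-memory results.
#' @export
run_pipeline <- function(out_dir, rng_seed = 1L, cfg = pipeline_config(),
                         n_genes = 40L, n_core = 100L, n_snps = 60L,
                         depth = 12, n_random = 500L,
                         design = expression_design(
                           tissues = c("liver", "brain"), sexes = c("M", "F")),
                         stages = c("simulate", "isogroup", "annotate",
                                    "completeness", "express", "snp",
                                    "report"),
                         quiet = FALSE) {
  known <- c("simulate", "isogroup", "annotate", "completeness",
             "express", "snp", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop("unknown stage: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  outputs <- character(0)

  # -- simulate ------------------------------------------------------------
  sim <- simulate_transcriptome(n_genes = n_genes, rng_seed = rng_seed)
  tx <- sim_isotig_seqs(sim)
  reads <- simulate_reads(tx, depth = depth, n_snps = n_snps,
                          rng_seed = rng_seed + 1L)
  hits <- simulate_hits(sim, synonym_noise = 0.15, core_n = n_core,
                        core_fraction_present = 0.9,
                        rng_seed = rng_seed + 2L)
  groups_truth <- hits$annotation$isotig_groups
  expressed <- data.frame(unit_id = names(sim$contigs)[
    seq_len(min(10L, length(sim$contigs)))],
    tissue = design$tissue[1], sex = design$sex[1],
    stringsAsFactors = FALSE)
  expr <- simulate_expression(contig_units = names(sim$contigs),
                              singleton_units = names(sim$singletons),
                              design = design, expressed = expressed,
                              n_random = n_random,
                              rng_seed = rng_seed + 3L)
  if ("simulate" %in% stages) {
    f <- file.path(out_dir, "contigs.fasta")
    write_fasta(sim$contigs, f)
    outputs <- c(outputs, f, tsv(sim$links, "links.tsv"),
                 tsv(reads$snps, "truth_snps.tsv"))
    say("simulate: ", length(sim$contigs), " contigs, ",
        length(reads$reads), " reads, ", nrow(reads$snps),
        " planted SNPs")
  }

  # -- isogroup ------------------------------------------------------------
  graph <- contig_graph(sim$contigs, sim$links)
  isogroups <- cluster_isogroups(graph)
  isogroups <- enumerate_all_isotigs(isogroups, graph, cfg$max_isotigs)
  tabs <- isogroup_tables(isogroups)
  stats_tab <- assembly_stats(graph$contigs, sim$singletons, isogroups)
  if ("isogroup" %in% stages) {
    outputs <- c(outputs, tsv(tabs$membership, "isogroup_membership.tsv"),
                 tsv(tabs$isotigs, "isotigs.tsv"),
                 tsv(stats_tab, "assembly_stats.tsv"))
    say("isogroup: ", length(isogroups), " isogroups, ",
        nrow(tabs$isotigs), " isotigs")
  }

  # -- annotate ------------------------------------------------------------
  ann <- hits$annotation
  synonyms <- synonym_map(ann$synonyms$label, ann$synonyms$canonical)
  assignments <- consolidate_annotations(
    ann$isotig_groups, ann$primary_hits, ann$subject_labels, synonyms,
    ann$secondary_hits, cfg)
  census <- annotation_census(assignments)
  go_terms <- join_terms(ann$primary_hits, ann$go, cfg$go_evalue,
                         ann$isotig_groups)
  kegg_terms <- join_terms(ann$primary_hits, ann$kegg, cfg$kegg_evalue,
                           ann$isotig_groups)
  ortho_terms <- join_terms(ann$primary_hits, ann$ortho, cfg$ortho_evalue,
                            ann$isotig_groups)
  if ("annotate" %in% stages) {
    outputs <- c(outputs, tsv(assignments, "annotations.tsv"),
                 tsv(census, "annotation_census.tsv"),
                 tsv(go_terms$terms, "go_terms.tsv"),
                 tsv(kegg_terms$terms, "kegg_terms.tsv"),
                 tsv(ortho_terms$terms, "ortho_terms.tsv"))
    say("annotate: ", census$n_annotated, " of ", census$n_units,
        " isogroups annotated (", census$n_single, " single, ",
        census$n_collapsed_synonym + census$n_resolved_top5,
        " collapsed/resolved, ", census$n_unresolved, " unresolved)")
  }

  # -- completeness --------------------------------------------------------
  comp <- hits$completeness
  pairs <- reciprocal_best_hits(comp$forward, comp$reverse,
                                cfg$completeness_evalue)
  report <- recovery_report(pairs, comp$core, comp$forward)
  if ("completeness" %in% stages) {
    outputs <- c(outputs, tsv(pairs, "core_pairs.tsv"),
                 tsv(report, "completeness_report.tsv"))
    say("completeness: ", report$n_recovered, " of ", report$n_core,
        " core genes recovered (",
        sprintf("%.1f%%", report$percent_recovered), ")")
  }

  # -- express -------------------------------------------------------------
  ecalls <- call_expression(expr$scores, expr$manifest, expr$design, cfg)
  if ("express" %in% stages) {
    outputs <- c(outputs, tsv(ecalls$calls, "expression_calls.tsv"),
                 tsv(ecalls$units, "expressed_units.tsv"))
    say("express: ", sum(ecalls$units$expressed), " of ",
        nrow(ecalls$units), " units called expressed in >=1 group")
  }

  # -- snp -----------------------------------------------------------------
  aln <- filter_alignments(reads$alignments, groups_truth, cfg)
  pile <- trim_and_pileup(aln, cfg)
  calls <- call_snps(pile, cfg)
  calls <- dedup_calls(calls, groups_truth)
  assembled_bases <- sum(Biostrings::width(sim$contigs))
  rate <- variant_rate(sum(calls$unique), assembled_bases)
  false_exp <- expected_false_snps(cfg$seq_error_rate, 8L,
                                   cfg$snp_min_support, assembled_bases)
  if ("snp" %in% stages) {
    f <- file.path(out_dir, "snps.vcf")
    write_vcf(calls, f)
    outputs <- c(outputs, f, tsv(calls, "snp_calls.tsv"))
    say("snp: ", nrow(calls), " calls (", sum(calls$unique),
        " unique), rate ", sprintf("%.2f", rate), "/kb; expected false ",
        format(false_exp, digits = 3))
  }

  # -- report --------------------------------------------------------------
  summary_tab <- data.frame(
    quantity = c("n_contigs", "n_isogroups", "n_isotigs",
                 "n_annotated_isogroups", "core_percent_recovered",
                 "n_expressed_units", "n_unique_snps",
                 "variant_rate_per_kb", "expected_false_snps"),
    value = c(length(sim$contigs), length(isogroups), nrow(tabs$isotigs),
              census$n_annotated, report$percent_recovered,
              sum(ecalls$units$expressed), sum(calls$unique), rate,
              false_exp),
    stringsAsFactors = FALSE
  )
  if ("report" %in% stages) {
    outputs <- c(outputs, tsv(summary_tab, "summary.tsv"))
  }
  manifest <- data.frame(
    key = c("tool", "version", "seed", "stages", "out_dir",
            paste0("cfg.", names(unclass(cfg))[
              !vapply(unclass(cfg), is.null, logical(1))]),
            paste0("output.", seq_along(outputs))),
    value = c("postasm",
              as.character(utils::packageVersion("postasm")),
              as.character(rng_seed), paste(stages, collapse = ","),
              out_dir,
              vapply(unclass(cfg)[!vapply(unclass(cfg), is.null,
                                          logical(1))],
                     function(v) as.character(v), character(1)),
              outputs),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(out_dir, "run_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(sim = sim, reads = reads, hits = hits,
                 isogroups = isogroups, assembly_stats = stats_tab,
                 assignments = assignments, census = census,
                 go_terms = go_terms, kegg_terms = kegg_terms,
                 ortho_terms = ortho_terms,
                 pairs = pairs, completeness_report = report,
                 expression = expr, expression_calls = ecalls,
                 snp_calls = calls, variant_rate = rate,
                 expected_false_snps = false_exp,
                 summary = summary_tab))
}
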