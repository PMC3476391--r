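#' Pipeline configuration
#'
#' A single object holding every numeric threshold used across the pipeline,
#' with the defaults the downstream modules assume. Values can be overridden
#' individually; invalid settings fail immediately rather than at use time.
#'
#' @param annotation_evalue E-value cutoff (strict `<`) for primary homology
#'   annotation hits.
#' @param go_evalue E-value cutoff for GO term assignment.
#' @param ortho_evalue E-value cutoff for orthology-group assignment and the
#'   top-five rescreen during annotation consolidation.
#' @param kegg_evalue E-value cutoff for pathway assignment.
#' @param completeness_evalue E-value cutoff for reciprocal-best-hit
#'   completeness searches.
#' @param snp_evalue E-value cutoff for read-to-isotig alignments.
#' @param snp_min_identity Minimum percent identity for read alignments.
#' @param snp_edge_slack Maximum unaligned read overhang (bp) tolerated at
#'   each read end.
#' @param snp_trim Bases trimmed from each aligned read end before pileup.
#' @param snp_min_maf Minor-allele frequency that a call must exceed
#'   (strict `>`).
#' @param snp_min_support Minimum reads supporting the minor allele.
#' @param expr_null_quantile Quantile of the random-probe score distribution
#'   used as each individual's expression threshold.
#' @param expr_min_individuals Individuals per group that must be called for
#'   a group-level expression call.
#' @param expr_group_size Individuals per tissue-sex group.
#' @param probes_per_contig Maximum probes designed per contig.
#' @param probe_length Probe length in bp.
#' @param seq_error_rate Per-base substitution error rate of the sequencing
#'   platform (0.022% for Titanium pyrosequencing).
#' @param min_read_length_after_clean Reads strictly shorter than this after
#'   cleaning are dropped (reads of 30 bp or less are removed).
#' @param max_isotigs Combinatorial safety valve for isotig enumeration.
#' @param rng_seed Optional integer seed recorded with the configuration.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation_evalue = 1e-5,
                            go_evalue = 1e-15,
                            ortho_evalue = 1e-10,
                            kegg_evalue = 1e-5,
                            completeness_evalue = 1e-5,
                            snp_evalue = 1e-5,
                            snp_min_identity = 95,
                            snp_edge_slack = 5,
                            snp_trim = 5,
                            snp_min_maf = 0.20,
                            snp_min_support = 3,
                            expr_null_quantile = 0.975,
                            expr_min_individuals = 3,
                            expr_group_size = 6,
                            probes_per_contig = 3,
                            probe_length = 60,
                            seq_error_rate = 2.2e-4,
                            min_read_length_after_clean = 31,
                            max_isotigs = 100,
                            rng_seed = NULL) {
  cfg <- list(
    annotation_evalue = annotation_evalue,
    go_evalue = go_evalue,
    ortho_evalue = ortho_evalue,
    kegg_evalue = kegg_evalue,
    completeness_evalue = completeness_evalue,
    snp_evalue = snp_evalue,
    snp_min_identity = snp_min_identity,
    snp_edge_slack = snp_edge_slack,
    snp_trim = snp_trim,
    snp_min_maf = snp_min_maf,
    snp_min_support = snp_min_support,
    expr_null_quantile = expr_null_quantile,
    expr_min_individuals = expr_min_individuals,
    expr_group_size = expr_group_size,
    probes_per_contig = probes_per_contig,
    probe_length = probe_length,
    seq_error_rate = seq_error_rate,
    min_read_length_after_clean = min_read_length_after_clean,
    max_isotigs = max_isotigs,
    rng_seed = rng_seed
  )
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  thresholds <- c(
    "annotation_evalue", "go_evalue", "ortho_evalue", "kegg_evalue",
    "completeness_evalue", "snp_evalue", "snp_min_identity",
    "snp_edge_slack", "snp_trim", "snp_min_maf", "snp_min_support",
    "expr_null_quantile", "expr_min_individuals", "expr_group_size",
    "probes_per_contig", "probe_length", "seq_error_rate",
    "min_read_length_after_clean", "max_isotigs"
  )
  for (nm in thresholds) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("config value '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (cfg$expr_min_individuals > cfg$expr_group_size) {
    stop("expr_min_individuals must not exceed expr_group_size",
         call. = FALSE)
  }
  if (cfg$snp_min_maf <= 0 || cfg$snp_min_maf > 0.5) {
    stop("snp_min_maf must lie in (0, 0.5]", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    if (is.null(x[[nm]])) next
    cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
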