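#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study with known truth.
#
# Emulates the data a pyrosequencing transcriptome project hands to its
# post-assembly pipeline: contigs fragmented at isoform boundaries with
# broken-read links, singleton reads, pyrosequencing-like reads with
# planted SNPs, annotation/completeness hit tables with synonym noise and
# a partially present core gene set, and a probe-intensity matrix with a
# random-probe null compartment. Everything downstream (scripts 02-06)
# works from the files written here.

suppressMessages(library(postasm))

seed <- 20260926L
out <- "results/simdata"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
tsv <- function(df, name) {
  utils::write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

sim <- simulate_transcriptome(n_genes = 120, n_singletons = 40,
                              rng_seed = seed)
write_fasta(sim$contigs, file.path(out, "contigs.fasta"))
write_fasta(sim$singletons, file.path(out, "singletons.fasta"))
tsv(sim$links, "links.tsv")

tx <- sim_isotig_seqs(sim)
reads <- simulate_reads(tx, depth = 40, n_snps = 300,
                        maf_range = c(0.3, 0.5), rng_seed = seed + 1L)
write_fasta(reads$reads, file.path(out, "reads.fasta"))
tsv(reads$alignments, "read_alignments.tsv")
tsv(reads$snps, "truth_snps.tsv")

hits <- simulate_hits(sim, synonym_noise = 0.15, core_n = 716,
                      core_fraction_present = 646 / 716,
                      rng_seed = seed + 2L)
ann <- hits$annotation
tsv(ann$isotig_groups, "isotig_groups.tsv")
write_hit_table(ann$primary_hits, file.path(out, "ann_primary_hits.tsv"))
write_hit_table(ann$secondary_hits,
                file.path(out, "ann_secondary_hits.tsv"))
tsv(data.frame(subject_id = names(ann$subject_labels),
               label = unname(ann$subject_labels)), "subject_labels.tsv")
tsv(ann$synonyms, "synonyms.tsv")
tsv(ann$go, "terms_go.tsv")
tsv(ann$kegg, "terms_kegg.tsv")
tsv(ann$ortho, "terms_ortho.tsv")
comp <- hits$completeness
tsv(comp$core, "core_genes.tsv")
write_hit_table(comp$forward, file.path(out, "comp_forward.tsv"))
write_hit_table(comp$reverse, file.path(out, "comp_reverse.tsv"))
tsv(data.frame(core_gene_id = comp$present_ids), "truth_core_present.tsv")

design <- expression_design(tissues = c("liver", "hypothalamus"),
                            sexes = c("M", "F"), n_per_group = 6)
expressed <- data.frame(unit_id = names(sim$contigs)[1:30],
                        tissue = "liver", sex = "M",
                        stringsAsFactors = FALSE)
expr <- simulate_expression(contig_units = names(sim$contigs),
                            singleton_units = names(sim$singletons),
                            design = design, expressed = expressed,
                            n_random = 2604, effect_sd = 3,
                            rng_seed = seed + 3L)
tsv(expr$manifest, "expr_manifest.tsv")
tsv(design, "expr_design.tsv")
tsv(expressed, "truth_expressed.tsv")
mat <- data.frame(probe_id = rownames(expr$scores), expr$scores,
                  check.names = FALSE)
tsv(mat, "expr_matrix.tsv")

cat("simulated:", length(sim$contigs), "contigs in",
    length(sim$truth$genes), "genes,", length(sim$singletons),
    "singletons,", length(reads$reads), "reads,",
    nrow(reads$snps), "planted SNPs,", nrow(expr$manifest),
    "probes (2604 random)\n")
cat("inputs for stages 02-06 written under", out, "\n")
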