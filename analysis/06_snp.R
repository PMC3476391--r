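#!/usr/bin/env Rscript
# Stage 6 — SNP calling from read-to-isotig alignments.
#
# Filters alignments (e-value, identity, read-end overhang, multi-isogroup
# reads), trims 5 bases from each aligned read end, piles up the remaining
# bases, calls sites where the minor allele exceeds 20% frequency with at
# least 3 supporting reads, deduplicates calls across isotigs of an
# isogroup, and reports the variant rate plus the binomial bound on false
# calls from sequencing error.

suppressMessages(library(postasm))

ind <- "results/simdata"
cfg <- pipeline_config()
aln <- utils::read.delim(file.path(ind, "read_alignments.tsv"),
                         stringsAsFactors = FALSE)
groups <- utils::read.delim(file.path(ind, "isotig_groups.tsv"),
                            stringsAsFactors = FALSE)
contigs <- read_fasta(file.path(ind, "contigs.fasta"))

# reads were simulated per isotig (gene%03d.iso%d); map them to their gene
gmap <- unique(rbind(groups, data.frame(
  isotig_id = unique(aln$isotig_id),
  isogroup_id = sub("\\.iso[0-9]+$", "", unique(aln$isotig_id)))))

kept <- filter_alignments(aln, gmap, cfg)
pile <- trim_and_pileup(kept, cfg)
calls <- call_snps(pile, cfg)
calls <- dedup_calls(calls, gmap)

write_vcf(calls, "results/snps.vcf")
utils::write.table(calls, "results/snp_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

bases <- sum(Biostrings::width(contigs))
rate <- variant_rate(sum(calls$unique), bases)
fp <- expected_false_snps(cfg$seq_error_rate, depth = 8,
                          min_support = cfg$snp_min_support,
                          n_sites = nrow(pile))

truth <- utils::read.delim(file.path(ind, "truth_snps.tsv"),
                           stringsAsFactors = FALSE)
key <- paste(calls$isotig_id, calls$position)
truth_key <- paste(truth$isotig_id, truth$position)
cat(nrow(aln) - nrow(kept), "of", nrow(aln),
    "alignments removed by the filters\n")
cat(nrow(calls), "calls at", length(unique(key)), "sites;",
    sum(calls$unique), "unique after cross-isotig deduplication\n")
cat(sprintf("sensitivity on planted SNPs: %.3f\n",
            mean(truth_key %in% key)))
cat(sprintf("variant rate: %.2f per kb of assembled sequence (%d bases)\n",
            rate, bases))
cat(sprintf("expected false calls from sequencing error (depth 8 model): %.2e\n",
            fp))
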