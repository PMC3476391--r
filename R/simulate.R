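#' Simulate a fragmented transcriptome with isoform structure
#'
#' Generates gene models the way a pyrosequencing assembler fragments
#' them: a single-isoform gene becomes one contig with no links; a gene
#' with k >= 2 isoforms becomes a shared 5' contig, k alternative middle
#' contigs and a shared 3' contig, with broken-read links across each true
#' junction (a diamond-shaped contig graph). The truth object records the
#' expected isogroups (one per gene) and the expected isotig contig chains
#' (one per isoform).
#'
#' @param n_genes Number of genes.
#' @param isoform_probs Probabilities of 1, 2, ... isoforms per gene. The
#'   default puts 19% of genes in the multi-isoform class, the fraction of
#'   isogroups with multiple isotigs observed in deep songbird assemblies.
#' @param contig_length_mean Mean contig length in bp (default 884, a
#'   typical mean contig length for this platform).
#' @param contig_length_cv Coefficient of variation of contig length.
#' @param min_contig_length Shortest contig emitted.
#' @param links_per_junction Broken reads supporting each true junction.
#' @param n_singletons Number of singleton reads (unassembled putative
#'   transcript fragments) to emit alongside the contigs; their mean
#'   length of 344 bp reflects that singletons are single cleaned reads.
#' @param rng_seed Seed; identical seeds give identical output.
#' @return A list: `contigs` (named [Biostrings::DNAStringSet]),
#'   `singletons` (named [Biostrings::DNAStringSet]), `links` (data.frame
#'   `read_id`, `contig_a`, `contig_b`, `orientation`), and `truth`
#'   (per-gene contig chains and expected isotig count).
#' @export
simulate_transcriptome <- function(n_genes = 50,
                                   isoform_probs = c(0.81, 0.15, 0.04),
                                   contig_length_mean = 884,
                                   contig_length_cv = 0.5,
                                   min_contig_length = 150,
                                   links_per_junction = 2L,
                                   n_singletons = 10L,
                                   rng_seed = NULL) {
  stopifnot(n_genes >= 1, all(isoform_probs >= 0), sum(isoform_probs) > 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sdlog <- sqrt(log(1 + contig_length_cv^2))
  meanlog <- log(contig_length_mean) - sdlog^2 / 2
  rand_len <- function(n) {
    pmax(min_contig_length, round(stats::rlnorm(n, meanlog, sdlog)))
  }
  rand_seq <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }
  contig_ids <- character(0)
  contig_seqs <- character(0)
  links <- list()
  genes <- vector("list", n_genes)
  read_counter <- 0L
  new_contig <- function(gene, tag) {
    id <- sprintf("gene%03d_%s", gene, tag)
    contig_ids <<- c(contig_ids, id)
    contig_seqs <<- c(contig_seqs, rand_seq(rand_len(1)))
    id
  }
  add_links <- function(a, b) {
    for (j in seq_len(links_per_junction)) {
      read_counter <<- read_counter + 1L
      links[[length(links) + 1L]] <<- data.frame(
        read_id = sprintf("brkread%05d", read_counter),
        contig_a = a, contig_b = b, orientation = "forward",
        stringsAsFactors = FALSE)
    }
  }
  n_iso <- sample.int(length(isoform_probs), n_genes, replace = TRUE,
                      prob = isoform_probs)
  for (g in seq_len(n_genes)) {
    k <- n_iso[g]
    if (k == 1L) {
      c0 <- new_contig(g, "c1")
      genes[[g]] <- list(gene_id = sprintf("gene%03d", g),
                         contig_ids = c0,
                         isoform_chains = list(c0))
      next
    }
    head_c <- new_contig(g, "head")
    tail_c <- new_contig(g, "tail")
    alts <- vapply(seq_len(k), function(i) new_contig(g, paste0("alt", i)),
                   character(1))
    chains <- lapply(alts, function(a) c(head_c, a, tail_c))
    for (a in alts) {
      add_links(head_c, a)
      add_links(a, tail_c)
    }
    genes[[g]] <- list(gene_id = sprintf("gene%03d", g),
                       contig_ids = c(head_c, tail_c, alts),
                       isoform_chains = chains)
  }
  contigs <- Biostrings::DNAStringSet(stats::setNames(contig_seqs,
                                                      contig_ids))
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(read_id = character(0), contig_a = character(0),
               contig_b = character(0), orientation = character(0),
               stringsAsFactors = FALSE)
  singletons <- Biostrings::DNAStringSet(character(0))
  if (n_singletons > 0L) {
    slen <- pmax(31L, round(stats::rlnorm(
      n_singletons, log(344) - sdlog^2 / 2, sdlog)))
    singletons <- Biostrings::DNAStringSet(stats::setNames(
      vapply(slen, rand_seq, character(1)),
      sprintf("singleton%04d", seq_len(n_singletons))))
  }
  list(contigs = contigs, singletons = singletons, links = links,
       truth = list(genes = genes, rng_seed = rng_seed))
}

#' Assemble isotig sequences from a simulated transcriptome
#'
#' @param sim Output of [simulate_transcriptome()].
#' @return Named character vector of isotig (isoform) sequences; names are
#'   `gene%03d.iso%d`.
#' @export
sim_isotig_seqs <- function(sim) {
  seqs <- as.character(sim$contigs)
  out <- character(0)
  for (g in sim$truth$genes) {
    for (i in seq_along(g$isoform_chains)) {
      out[sprintf("%s.iso%d", g$gene_id, i)] <-
        paste(seqs[g$isoform_chains[[i]]], collapse = "")
    }
  }
  out
}

#' Simulate pyrosequencing-like reads with known alignments
#'
#' Samples reads from transcript sequences with lengths drawn from a
#' log-normal (mean 372 bp, the platform's typical mean read length),
#' substitution errors at the platform rate (0.022% by default),
#' optional homopolymer-length indels, and planted biallelic SNPs: each
#' read overlapping a planted site carries the minor allele with
#' probability equal to the site's minor-allele frequency. Because reads
#' are generated from the transcripts directly, their true gapped
#' alignments are emitted alongside, so the variant caller can run without
#' an external aligner.
#'
#' @param transcripts Named character vector of transcript sequences (for
#'   example [sim_isotig_seqs()] output).
#' @param depth Target mean fold-coverage per transcript.
#' @param mean_length Mean read length (bp).
#' @param length_cv Coefficient of variation of read length.
#' @param error_rate Per-base substitution error probability.
#' @param indel_hp_rate Per-run rate multiplier for homopolymer indels: a
#'   run of length L (>= 3) in a read gains or loses one base with
#'   probability `indel_hp_rate * L`.
#' @param n_snps Number of biallelic SNPs to plant across transcripts.
#' @param maf_range Range the per-site minor-allele frequency is drawn
#'   from.
#' @param rng_seed Seed.
#' @return A list: `reads` (named character vector), `alignments`
#'   (table accepted by [as_read_alignments()]), `snps` (truth data.frame
#'   `isotig_id`, `position`, `major`, `minor`, `maf`).
#' @export
simulate_reads <- function(transcripts, depth = 10, mean_length = 372,
                           length_cv = 0.3, error_rate = 2.2e-4,
                           indel_hp_rate = 0, n_snps = 0,
                           maf_range = c(0.3, 0.5), rng_seed = NULL) {
  stopifnot(depth >= 1, length(transcripts) >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  bases <- c("A", "C", "G", "T")
  sdlog <- sqrt(log(1 + length_cv^2))
  meanlog <- log(mean_length) - sdlog^2 / 2
  tx_ids <- names(transcripts)
  tx_len <- nchar(transcripts)
  # plant SNPs away from transcript ends: with uniform read starts the
  # first and last ~read-length bases are systematically under-covered
  margin <- max(100L, as.integer(round(mean_length)))
  snps <- NULL
  if (n_snps > 0L) {
    eligible <- tx_ids[tx_len >= 2L * margin + 100L]
    stopifnot(length(eligible) > 0L)
    site_tx <- sample(eligible, n_snps, replace = TRUE)
    rows <- lapply(seq_len(n_snps), function(i) {
      tx <- site_tx[i]
      pos <- sample(seq(margin, tx_len[tx] - margin), 1L)
      ref <- substr(transcripts[tx], pos, pos)
      alt <- sample(setdiff(bases, ref), 1L)
      data.frame(isotig_id = tx, position = pos, major = ref, minor = alt,
                 maf = stats::runif(1, maf_range[1], maf_range[2]),
                 stringsAsFactors = FALSE)
    })
    snps <- do.call(rbind, rows)
    snps <- snps[!duplicated(snps[, c("isotig_id", "position")]), ,
                 drop = FALSE]
    rownames(snps) <- NULL
  } else {
    snps <- data.frame(isotig_id = character(0), position = integer(0),
                       major = character(0), minor = character(0),
                       maf = numeric(0), stringsAsFactors = FALSE)
  }
  reads <- list()
  aln_rows <- list()
  read_counter <- 0L
  for (tx in tx_ids) {
    L <- tx_len[[tx]]
    n_reads <- max(1L, as.integer(ceiling(depth * L / mean_length)))
    tx_chars <- strsplit(transcripts[[tx]], "", fixed = TRUE)[[1]]
    site <- snps[snps$isotig_id == tx, , drop = FALSE]
    rl <- pmin(L, pmax(31L, round(stats::rlnorm(n_reads, meanlog, sdlog))))
    starts <- vapply(rl, function(l) sample.int(L - l + 1L, 1L), integer(1))
    for (r in seq_len(n_reads)) {
      read_counter <- read_counter + 1L
      s0 <- starts[r]
      s1 <- s0 + rl[r] - 1L
      ref <- tx_chars[s0:s1]
      rd <- ref
      # planted alleles
      if (nrow(site)) {
        inside <- site$position >= s0 & site$position <= s1
        for (j in which(inside)) {
          if (stats::runif(1) < site$maf[j]) {
            rd[site$position[j] - s0 + 1L] <- site$minor[j]
          }
        }
      }
      # substitution errors
      n_err <- stats::rbinom(1L, length(rd), error_rate)
      if (n_err > 0L) {
        at <- sample.int(length(rd), n_err)
        rd[at] <- vapply(rd[at], function(b) sample(setdiff(bases, b), 1L),
                         character(1))
      }
      ref_aln <- ref
      rd_aln <- rd
      # homopolymer-length indels
      if (indel_hp_rate > 0) {
        runs <- rle(rd)
        run_end <- cumsum(runs$lengths)
        hp <- which(runs$lengths >= 3L)
        for (h in hp) {
          if (stats::runif(1) < indel_hp_rate * runs$lengths[h]) {
            p <- run_end[h]
            if (stats::runif(1) < 0.5) {
              rd_aln[p] <- "-"           # deletion from the read
            } else {                     # extra read base, gap in reference
              rd_aln <- append(rd_aln, runs$values[h], after = p)
              ref_aln <- append(ref_aln, "-", after = p)
            }
          }
        }
      }
      read_seq <- paste(rd_aln[rd_aln != "-"], collapse = "")
      read_len <- nchar(read_seq)
      aligned_cols <- length(ref_aln)
      matches <- sum(ref_aln == rd_aln & ref_aln != "-")
      read_id <- sprintf("read%06d", read_counter)
      reads[[read_counter]] <- read_seq
      aln_rows[[read_counter]] <- data.frame(
        read_id = read_id, isotig_id = tx, read_len = read_len,
        qstart = 1L, qend = read_len, sstart = s0, send = s1,
        pident = 100 * matches / aligned_cols, evalue = 1e-60,
        read_aln = paste(rd_aln, collapse = ""),
        isotig_aln = paste(ref_aln, collapse = ""),
        strand = "+", stringsAsFactors = FALSE)
    }
  }
  alignments <- as_read_alignments(
    as.data.frame(data.table::rbindlist(aln_rows)))
  reads <- stats::setNames(unlist(reads), alignments$read_id)
  list(reads = reads, alignments = alignments, snps = snps)
}

#' Simulate annotation and completeness hit tables with known truth
#'
#' Builds the tabular-alignment inputs of the annotation and completeness
#' modules around a simulated transcriptome: every isotig hits its gene's
#' true protein with the top bit score (plus a weaker decoy), a chosen
#' fraction of isotigs report a synonymous alias of the gene label (with
#' the alias-to-canonical mapping supplied as a synonym table), term
#' tables attach GO/pathway/orthology identifiers to each true protein,
#' and a core gene set of which a chosen fraction has a planted
#' reciprocal-best homolog.
#'
#' @param sim Output of [simulate_transcriptome()].
#' @param synonym_noise Fraction of isotig annotations reported under a
#'   synonymous label.
#' @param core_n Size of the core single-copy gene set (the benchmark set
#'   has 716).
#' @param core_fraction_present Fraction of core genes with a planted
#'   homolog in the transcriptome.
#' @param rng_seed Seed.
#' @return A list with `annotation` (isotig_groups, primary_hits,
#'   secondary_hits, subject_labels, synonyms, go, kegg, ortho) and
#'   `completeness` (forward, reverse, core, present_ids).
#' @export
simulate_hits <- function(sim, synonym_noise = 0, core_n = 716L,
                          core_fraction_present = 0.9,
                          rng_seed = NULL) {
  stopifnot(synonym_noise >= 0, synonym_noise <= 1,
            core_fraction_present >= 0, core_fraction_present <= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  genes <- sim$truth$genes
  hit_row <- function(q, s, pid, len, qs, qe, ss, se, ev, bits) {
    data.frame(qseqid = q, sseqid = s, pident = pid, length = len,
               mismatch = round(len * (100 - pid) / 100), gapopen = 0L,
               qstart = qs, qend = qe, sstart = ss, send = se,
               evalue = ev, bitscore = bits, stringsAsFactors = FALSE)
  }
  groups <- list()
  prim <- list()
  sec <- list()
  labels <- character(0)
  syn_rows <- list()
  term_go <- list()
  term_kegg <- list()
  term_ortho <- list()
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    true_subj <- sprintf("PROT%03d", gi)
    alias_subj <- sprintf("PROT%03da", gi)
    canonical <- sprintf("GENE%03d", gi)
    alias <- sprintf("gene %03d alias", gi)
    labels[true_subj] <- canonical
    labels[alias_subj] <- alias
    syn_rows[[gi]] <- data.frame(label = alias, canonical = canonical,
                                 stringsAsFactors = FALSE)
    term_go[[gi]] <- data.frame(subject_id = c(true_subj, alias_subj),
                                term = sprintf("GO:%07d", gi),
                                stringsAsFactors = FALSE)
    term_kegg[[gi]] <- data.frame(subject_id = c(true_subj, alias_subj),
                                  term = sprintf("path:ko%05d", gi),
                                  stringsAsFactors = FALSE)
    term_ortho[[gi]] <- data.frame(subject_id = c(true_subj, alias_subj),
                                   term = sprintf("OG%05d", gi),
                                   stringsAsFactors = FALSE)
    decoy_subj <- sprintf("PROT%03d", (gi %% length(genes)) + 1L)
    for (i in seq_along(g$isoform_chains)) {
      itig <- sprintf("%s.iso%d", g$gene_id, i)
      groups[[length(groups) + 1L]] <- data.frame(
        isotig_id = itig, isogroup_id = g$gene_id,
        stringsAsFactors = FALSE)
      use_alias <- stats::runif(1) < synonym_noise
      subj <- if (use_alias) alias_subj else true_subj
      prim[[length(prim) + 1L]] <- rbind(
        hit_row(itig, subj, 92, 300, 1L, 300L, 1L, 300L, 1e-50, 250),
        hit_row(itig, decoy_subj, 70, 150, 1L, 150L, 1L, 150L, 1e-8, 90))
      # top-5 rescreen list always contains the true protein
      sec[[length(sec) + 1L]] <- rbind(
        hit_row(itig, true_subj, 95, 280, 1L, 280L, 1L, 280L, 1e-40, 240),
        hit_row(itig, decoy_subj, 72, 140, 1L, 140L, 1L, 140L, 1e-12, 95))
    }
  }
  groups <- do.call(rbind, groups)
  annotation <- list(
    isotig_groups = groups,
    primary_hits = as_hit_table(do.call(rbind, prim)),
    secondary_hits = as_hit_table(do.call(rbind, sec)),
    subject_labels = labels,
    synonyms = do.call(rbind, syn_rows),
    go = do.call(rbind, term_go),
    kegg = do.call(rbind, term_kegg),
    ortho = do.call(rbind, term_ortho)
  )
  # --- completeness -------------------------------------------------------
  core <- data.frame(id = sprintf("CORE%04d", seq_len(core_n)),
                     length = sample(200:600, core_n, replace = TRUE),
                     stringsAsFactors = FALSE)
  n_present <- round(core_fraction_present * core_n)
  present <- sort(sample(core$id, n_present))
  fwd <- list()
  rev <- list()
  for (cid in present) {
    plen <- core$length[core$id == cid]
    qid <- paste0("coretx_", cid)
    span <- max(1L, round(stats::runif(1, 0.5, 0.9) * plen))
    ss <- sample.int(plen - span + 1L, 1L)
    pid <- round(stats::runif(1, 75, 95), 1)
    fwd[[cid]] <- hit_row(qid, cid, pid, span, 1L, 3L * span,
                          ss, ss + span - 1L, 1e-40, 300)
    rev[[cid]] <- hit_row(cid, qid, pid, span, ss, ss + span - 1L,
                          1L, 3L * span, 1e-40, 300)
  }
  completeness <- list(
    forward = as_hit_table(do.call(rbind, fwd)),
    reverse = as_hit_table(do.call(rbind, rev)),
    core = core,
    present_ids = present
  )
  list(annotation = annotation, completeness = completeness)
}

#' Build a tissue-sex sample design
#'
#' @param tissues Tissue names.
#' @param sexes Sex labels.
#' @param n_per_group Individuals per tissue-sex group (the array study
#'   used 6).
#' @return A data.frame `individual`, `tissue`, `sex`.
#' @export
expression_design <- function(tissues = c("vmt", "hypothalamus", "liver",
                                          "pectoralis"),
                              sexes = c("M", "F"),
                              n_per_group = 6L) {
  grid <- expand.grid(rep = seq_len(n_per_group), tissue = tissues,
                      sex = sexes, stringsAsFactors = FALSE)
  grid$individual <- sprintf("%s_%s_%02d", grid$tissue, grid$sex, grid$rep)
  grid[, c("individual", "tissue", "sex")]
}

#' Simulate a normalized probe-intensity matrix with a null compartment
#'
#' Null probes (random probes and probes of unexpressed units) draw
#' scores from a common background distribution; probes of expressed
#' units are shifted upward by `effect_sd` background standard deviations
#' in the designated tissue-sex groups only. The manifest allocates up to
#' three probes per contig unit and one per singleton unit, plus
#' `n_random` random probes with no target.
#'
#' @param contig_units Character vector of contig unit ids.
#' @param singleton_units Character vector of singleton unit ids.
#' @param design Sample design from [expression_design()].
#' @param expressed Data.frame `unit_id`, `tissue`, `sex` designating the
#'   groups in which each expressed unit is shifted (units absent from it
#'   are null everywhere).
#' @param n_random Number of random (null) probes.
#' @param effect_sd Expression shift in background-SD units.
#' @param bg_mean,bg_sd Background score distribution parameters
#'   (normalized log-intensity scale).
#' @param probes_per_contig Probes allocated per contig unit.
#' @param rng_seed Seed.
#' @return A list: `manifest`, `scores` (matrix probes x individuals),
#'   `design`, `truth` (the `expressed` table).
#' @export
simulate_expression <- function(contig_units, singleton_units = character(0),
                                design = expression_design(),
                                expressed = NULL,
                                n_random = 2604L, effect_sd = 3,
                                bg_mean = 7, bg_sd = 1,
                                probes_per_contig = 3L,
                                rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  manifest <- rbind(
    if (length(contig_units)) data.frame(
      probe_id = sprintf("%s_p%d",
                         rep(contig_units, each = probes_per_contig),
                         rep(seq_len(probes_per_contig),
                             length(contig_units))),
      target_id = rep(contig_units, each = probes_per_contig),
      probe_class = "contig", stringsAsFactors = FALSE),
    if (length(singleton_units)) data.frame(
      probe_id = paste0(singleton_units, "_p1"),
      target_id = singleton_units,
      probe_class = "singleton", stringsAsFactors = FALSE),
    data.frame(probe_id = sprintf("random%05d", seq_len(n_random)),
               target_id = NA_character_, probe_class = "random",
               stringsAsFactors = FALSE)
  )
  n_probe <- nrow(manifest)
  n_ind <- nrow(design)
  scores <- matrix(stats::rnorm(n_probe * n_ind, bg_mean, bg_sd),
                   nrow = n_probe, ncol = n_ind,
                   dimnames = list(manifest$probe_id, design$individual))
  if (!is.null(expressed) && nrow(expressed)) {
    for (i in seq_len(nrow(expressed))) {
      probes <- manifest$probe_id[!is.na(manifest$target_id) &
                                    manifest$target_id ==
                                    expressed$unit_id[i]]
      cols <- design$individual[design$tissue == expressed$tissue[i] &
                                  design$sex == expressed$sex[i]]
      scores[probes, cols] <- scores[probes, cols] + effect_sd * bg_sd
    }
  }
  list(manifest = manifest, scores = scores, design = design,
       truth = expressed)
}
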