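iso_seq <- NULL
setup_iso <- function(len = 200) {
  set.seed(20)
  random_dna(len)
}

test_that("filter_alignments applies e-value, identity and edge rules", {
  iso <- setup_iso()
  gmap <- data.frame(isotig_id = c("t1", "t2", "t3"),
                     isogroup_id = c("gA", "gA", "gB"),
                     stringsAsFactors = FALSE)
  aln <- rbind(
    # 100 bp read aligned over read positions 4-97: overhangs 3 and 3
    toy_alignment("keep", "t1", iso, 11, 104, read_len = 100,
                  qstart = 4L, qend = 97L, pident = 96, evalue = 1e-20),
    # 5' overhang 9 > 5 -> dropped
    toy_alignment("over", "t1", iso, 11, 101, read_len = 100,
                  qstart = 10L, qend = 100L, pident = 96, evalue = 1e-20),
    # identity below 95 -> dropped
    toy_alignment("lowid", "t1", iso, 11, 104, read_len = 100,
                  qstart = 4L, qend = 97L, pident = 94.9, evalue = 1e-20),
    # e-value not strictly below 1e-5 -> dropped
    toy_alignment("bade", "t1", iso, 11, 104, read_len = 100,
                  qstart = 4L, qend = 97L, pident = 96, evalue = 1e-5)
  )
  out <- filter_alignments(aln, gmap)
  expect_equal(out$read_id, "keep")

  # a read hitting isotigs of two isogroups loses all its alignments
  multi <- rbind(
    toy_alignment("ambig", "t1", iso, 11, 100, read_len = 92,
                  qstart = 2L, qend = 91L),
    toy_alignment("ambig", "t3", iso, 11, 100, read_len = 92,
                  qstart = 2L, qend = 91L),
    toy_alignment("fine", "t1", iso, 11, 100, read_len = 92,
                  qstart = 2L, qend = 91L),
    toy_alignment("fine2", "t2", iso, 11, 100, read_len = 92,
                  qstart = 2L, qend = 91L)
  )
  out2 <- filter_alignments(multi, gmap)
  expect_setequal(out2$read_id, c("fine", "fine2"))

  expect_error(filter_alignments(
    toy_alignment("r", "tX", iso, 1, 50), gmap), "tX")
})

test_that("trim_and_pileup drops 5 bases at each read end and tracks gaps", {
  iso <- setup_iso(120)
  # single 100 bp read covering isotig positions 1..100
  aln <- toy_alignment("r1", "t1", iso, 1, 100)
  pile <- trim_and_pileup(aln)
  expect_equal(range(pile$position), c(6L, 95L))
  expect_true(all(pile$depth == 1L))
  expect_equal(nrow(pile), 90L)

  # two overlapping reads disagreeing at one site
  r2 <- substr(iso, 41, 120)
  disagree_pos <- 60L
  r2chars <- strsplit(r2, "")[[1]]
  ref_base <- r2chars[disagree_pos - 40L]
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  r2chars[disagree_pos - 40L] <- alt_base
  aln2 <- rbind(
    toy_alignment("r1", "t1", iso, 1, 100),
    toy_alignment("r2", "t1", iso, 41, 120,
                  read_seq = paste(r2chars, collapse = "")))
  pile2 <- trim_and_pileup(aln2)
  col <- pile2[pile2$position == disagree_pos, ]
  expect_equal(col$depth, 2L)
  expect_equal(unname(unlist(col[, c(ref_base, alt_base)])), c(1L, 1L))

  # insertion in the read consumes no isotig column; deletion counts a gap
  ins <- data.frame(read_id = "ri", isotig_id = "t1", read_len = 31L,
                    qstart = 1L, qend = 31L, sstart = 41L, send = 70L,
                    pident = 96,
                    evalue = 1e-30,
                    read_aln = paste0(substr(iso, 41, 55), "A",
                                      substr(iso, 56, 70)),
                    isotig_aln = paste0(substr(iso, 41, 55), "-",
                                        substr(iso, 56, 70)),
                    strand = "+", stringsAsFactors = FALSE)
  pin <- trim_and_pileup(ins)
  expect_equal(nrow(pin), 30L - 10L)          # 30 isotig positions, 5+5 trim
  expect_equal(range(pin$position), c(46L, 65L))
  expect_true(all(pin$gap == 0L))

  del <- data.frame(read_id = "rd", isotig_id = "t1", read_len = 29L,
                    qstart = 1L, qend = 29L, sstart = 41L, send = 70L,
                    pident = 96, evalue = 1e-30,
                    read_aln = paste0(substr(iso, 41, 55), "-",
                                      substr(iso, 57, 70)),
                    isotig_aln = substr(iso, 41, 70),
                    strand = "+", stringsAsFactors = FALSE)
  pdel <- trim_and_pileup(del)
  gapcol <- pdel[pdel$position == 56L, ]
  expect_equal(gapcol$gap, 1L)
  expect_equal(gapcol$depth, 0L)   # depth counts non-gap bases only
})

test_that("pileups and calls are invariant under read order", {
  iso <- setup_iso(150)
  set.seed(21)
  aln <- do.call(rbind, lapply(1:8, function(i) {
    s <- sample(1:60, 1)
    toy_alignment(paste0("r", i), "t1", iso, s, s + 80)
  }))
  base <- trim_and_pileup(aln)
  perm <- trim_and_pileup(aln[sample(nrow(aln)), ])
  expect_equal(perm, base)
})

test_that("call_snps applies support and frequency filters on non-gap depth", {
  col <- function(A = 0, C = 0, G = 0, T = 0, gap = 0, pos = 10L) {
    data.frame(isotig_id = "t1", position = pos, A = A, C = C, G = G,
               T = T, gap = gap, depth = A + C + G + T,
               stringsAsFactors = FALSE)
  }
  # 7 A / 3 G -> call with minor frequency 0.30
  r1 <- call_snps(col(A = 7, G = 3))
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$major, "A")
  expect_equal(r1$minor, "G")
  expect_equal(r1$minor_freq, 0.3)

  # 8 A / 2 G: frequency 0.20 is not > 0.20 -> no call; also support < 3
  expect_equal(nrow(call_snps(col(A = 8, G = 2))), 0L)
  # 12 A / 3 G: support ok but 0.20 not exceeded
  expect_equal(nrow(call_snps(col(A = 12, G = 3))), 0L)

  # gaps excluded from alleles and depth: 5 A / 4 gap / 3 G calls G at 3/8
  r2 <- call_snps(col(A = 5, G = 3, gap = 4))
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$depth, 8L)
  expect_equal(r2$minor_freq, 3 / 8)

  # third allele ignored: major vs top minor only
  r3 <- call_snps(col(A = 10, G = 5, C = 1))
  expect_equal(r3$minor, "G")
})

test_that("no call violates the support or frequency invariants", {
  set.seed(22)
  cols <- data.frame(
    isotig_id = "t1", position = 1:500,
    A = rpois(500, 6), C = rpois(500, 2), G = rpois(500, 1),
    T = rpois(500, 0.5), gap = rpois(500, 0.5))
  cols$depth <- cols$A + cols$C + cols$G + cols$T
  calls <- call_snps(cols)
  expect_true(all(calls$minor_count >= 3))
  expect_true(all(calls$minor_freq > 0.20))
  expect_true(all(calls$major != calls$minor))
})

test_that("dedup keeps one call per redundancy class", {
  gmap <- data.frame(isotig_id = sprintf("t%03d", 1:250),
                     isogroup_id = "isogroup00018",
                     stringsAsFactors = FALSE)
  # 250 isotigs of one isogroup all report the same G/T call at 551
  calls <- data.frame(
    isotig_id = sprintf("t%03d", 1:250), position = 551L,
    major = "G", minor = "T",
    minor_count = c(9L, rep(5L, 249)), depth = 20L,
    minor_freq = c(0.45, rep(0.25, 249)), stringsAsFactors = FALSE)
  dd <- dedup_calls(calls, gmap)
  expect_equal(sum(dd$unique), 1L)
  # the representative has the greatest minor-allele support
  expect_equal(dd$isotig_id[dd$unique], "t001")

  # same alleles at different contig positions are both unique
  cmap <- data.frame(isotig_id = c("t001", "t002"),
                     contig_id = c("cA", "cB"),
                     start = 1L, end = 1000L, stringsAsFactors = FALSE)
  two <- calls[1:2, ]
  dd2 <- dedup_calls(two, gmap, cmap)
  expect_equal(sum(dd2$unique), 2L)
  # ... but the same underlying contig position collapses to one
  cmap_same <- data.frame(isotig_id = c("t001", "t002"),
                          contig_id = "cA", start = 1L, end = 1000L,
                          stringsAsFactors = FALSE)
  dd3 <- dedup_calls(two, gmap, cmap_same)
  expect_equal(sum(dd3$unique), 1L)

  # calls in different isogroups are never merged
  gmap2 <- data.frame(isotig_id = c("t001", "t002"),
                      isogroup_id = c("gA", "gB"))
  dd4 <- dedup_calls(two, gmap2)
  expect_equal(sum(dd4$unique), 2L)
})

test_that("variant_rate and expected_false_snps follow their formulas", {
  expect_equal(round(variant_rate(25781, 35.8e6), 2), 0.72)
  expect_equal(variant_rate(0, 1000), 0)
  expect_equal(variant_rate(1, 1000), 1)

  expect_equal(expected_false_snps(0, 8, 3), 0)
  # exact tail for >= 3 substitution errors at depth 8, p = 2.2e-4
  p <- 2.2e-4
  exact <- sum(vapply(3:8, function(k) {
    choose(8, k) * p^k * (1 - p)^(8 - k)
  }, numeric(1)))
  expect_equal(expected_false_snps(p, 8, 3), exact, tolerance = 1e-12)
  expect_lt(expected_false_snps(p, 8, 3), 1.055e-8)
  # monotone in the support threshold
  expect_lt(expected_false_snps(p, 8, 4), expected_false_snps(p, 8, 3))
  expect_error(expected_false_snps(1.5, 8, 3), "error_rate")
})

test_that("planted SNPs are recovered and monomorphic sites stay quiet", {
  tx <- stats::setNames(
    vapply(1:10, function(i) random_dna(1500), character(1)),
    paste0("t", 1:10))
  sim <- simulate_reads(tx, depth = 50, n_snps = 120,
                        maf_range = c(0.3, 0.5), rng_seed = 23)
  gmap <- data.frame(isotig_id = names(tx), isogroup_id = names(tx),
                     stringsAsFactors = FALSE)
  aln <- filter_alignments(sim$alignments, gmap)
  pile <- trim_and_pileup(aln)
  calls <- call_snps(pile)
  key <- paste(calls$isotig_id, calls$position)
  truth_key <- paste(sim$snps$isotig_id, sim$snps$position)
  sens <- mean(truth_key %in% key)
  expect_gt(sens, 0.95)
  # recovered alleles match the planted ones
  hit <- calls[key %in% truth_key, ]
  m <- match(paste(hit$isotig_id, hit$position), truth_key)
  expect_true(all(hit$minor == sim$snps$minor[m] |
                    hit$major == sim$snps$minor[m]))
  # false calls on monomorphic sites stay within the binomial bound
  n_false <- sum(!key %in% truth_key)
  bound <- expected_false_snps(2.2e-4, 50, 3, nrow(pile))
  expect_lte(n_false, max(3, 10 * bound))
})
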