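test_that("design_probes allocates evenly spaced non-overlapping probes", {
  set.seed(12)
  contigs <- c(
    long = random_dna(600),     # room for 3 probes
    mid = random_dna(130),      # only 2 non-overlapping 60-mers fit
    tiny = random_dna(59)       # shorter than a probe -> skipped
  )
  singles <- c(s1 = random_dna(100))
  expect_warning(m <- design_probes(contigs, singles), "skipped")
  acc <- probe_accounting(m)
  expect_equal(unname(acc$by_class["contig"]), 5L)
  expect_equal(unname(acc$by_class["singleton"]), 1L)
  expect_equal(sum(acc$by_class), nrow(m))
  expect_equal(sum(m$target_id == "long"), 3L)
  expect_equal(sum(m$target_id == "mid"), 2L)
  expect_false("tiny" %in% m$target_id)
  # non-overlap within each target
  for (tid in unique(m$target_id)) {
    st <- sort(m$start[m$target_id == tid])
    if (length(st) > 1) expect_true(all(diff(st) >= 60))
  }
  expect_true(all(nchar(m$seq) == 60L))
  # the array's published allocation identity: 3k+2l+1m probes
  expect_equal(33545 * 3 + 61 * 2 + 65 * 1, 100822)
})

test_that("probes avoid N runs where an N-free window exists", {
  seq_with_n <- paste0(random_dna(80), strrep("N", 10), random_dna(80))
  m <- design_probes(c(x = seq_with_n))
  expect_true(nrow(m) >= 1L)
  expect_false(any(grepl("N", m$seq)))
})

test_that("random probes reflect the training composition", {
  # degenerate order-0 chain: all-A input gives all-A probes
  p0 <- generate_random_probes(c("AAAAAAAAAA"), n = 5, order = 0,
                               rng_seed = 1)
  expect_true(all(p0 == strrep("A", 60)))

  # order-1 chain trained on CG-free input never emits CG
  set.seed(13)
  train <- gsub("CG", "CA", vapply(1:20, function(i) random_dna(500),
                                   character(1)))
  while (any(grepl("CG", train))) train <- gsub("CG", "CA", train)
  p1 <- generate_random_probes(train, n = 200, order = 1, rng_seed = 2)
  expect_false(any(grepl("CG", p1)))
  expect_true(all(nchar(p1) == 60L))

  # reproducible under seed; default count matches the array design
  a <- generate_random_probes(train, n = 50, order = 1, rng_seed = 3)
  b <- generate_random_probes(train, n = 50, order = 1, rng_seed = 3)
  expect_identical(a, b)
  expect_equal(formals(generate_random_probes)$n, 2604L)

  expect_error(generate_random_probes(character(0), n = 5), "training")
})

test_that("individual_threshold is the type-7 empirical 97.5% quantile", {
  scores <- matrix(c(1:1000), ncol = 1,
                   dimnames = list(sprintf("rnd%04d", 1:1000), "ind1"))
  manifest <- data.frame(probe_id = rownames(scores),
                         target_id = NA_character_,
                         probe_class = "random", stringsAsFactors = FALSE)
  thr <- individual_threshold(scores, manifest, "ind1")
  expect_equal(thr, 975.025)

  # constant null scores: threshold equals the constant, nothing above it
  const <- matrix(rep(5, 100), ncol = 1,
                  dimnames = list(sprintf("r%03d", 1:100), "ind1"))
  mconst <- data.frame(probe_id = rownames(const),
                       target_id = NA_character_, probe_class = "random")
  expect_equal(individual_threshold(const, mconst, "ind1"), 5)
  expect_equal(sum(const[, 1] > 5), 0L)

  expect_error(individual_threshold(
    scores, data.frame(probe_id = "x", target_id = "y",
                       probe_class = "contig"), "ind1"), "random")
})

test_that("fraction of null scores above their own threshold is about 2.5%", {
  set.seed(14)
  x <- stats::rnorm(100000)
  thr <- null_threshold(x, 0.975)
  frac <- mean(x > thr)
  expect_lt(abs(frac - 0.025), 0.002)
})

test_that("call_unit applies the median rule and the 3-of-6 rule", {
  design <- expression_design(tissues = "liver", sexes = "M",
                              n_per_group = 6)
  n_random <- 200
  set.seed(15)
  manifest <- rbind(
    data.frame(probe_id = paste0("u1_p", 1:3), target_id = "u1",
               probe_class = "contig", stringsAsFactors = FALSE),
    data.frame(probe_id = paste0("rnd", 1:n_random),
               target_id = NA_character_, probe_class = "random",
               stringsAsFactors = FALSE))
  scores <- matrix(stats::rnorm(nrow(manifest) * 6),
                   nrow = nrow(manifest),
                   dimnames = list(manifest$probe_id, design$individual))
  thr <- vapply(design$individual, function(i) {
    null_threshold(scores[paste0("rnd", 1:n_random), i])
  }, numeric(1))

  # individual called iff the median probe value exceeds the threshold:
  # force 2 of 3 probes high in individuals 1..k
  for (k in 2:4) {
    sc <- scores
    sc[paste0("u1_p", 1:2), 1:k] <- 10   # median of (10, 10, x) = 10
    calls <- call_unit(sc, manifest, design, "u1")
    expect_equal(calls$n_called, k)
    expect_equal(calls$called, k >= 3)
    expect_equal(calls$any_group_called, k >= 3)
  }
  # 1 of 3 probes high leaves the median below threshold
  sc <- scores
  sc["u1_p1", ] <- 10
  calls <- call_unit(sc, manifest, design, "u1")
  expect_equal(calls$n_called, sum(apply(
    sc[paste0("u1_p", 1:3), ], 2, stats::median) > thr))

  expect_error(call_unit(scores, manifest, design, "nope"), "no probes")
})

test_that("raising a score never turns a called unit uncalled", {
  set.seed(16)
  design <- expression_design(tissues = "liver", sexes = c("M", "F"),
                              n_per_group = 6)
  sim <- simulate_expression(contig_units = paste0("u", 1:20),
                             design = design, n_random = 120,
                             rng_seed = 17)
  base <- call_expression(sim$scores, sim$manifest, sim$design)
  bumped <- sim$scores
  targets <- !is.na(sim$manifest$target_id)
  bumped[sim$manifest$probe_id[targets], ] <-
    bumped[sim$manifest$probe_id[targets], ] + 1
  after <- call_expression(bumped, sim$manifest, sim$design)
  expect_true(all(after$calls$n_called >= base$calls$n_called))
  expect_true(all(after$units$expressed >= base$units$expressed))
})

test_that("replication_pvalue is the exact binomial tail", {
  expect_equal(replication_pvalue(6, 1, 0.025), 1 - 0.975^6)
  # closed-form exact tail for at least 3 of 6 at p = 0.025
  p <- 0.025
  exact <- sum(vapply(3:6, function(k) {
    choose(6, k) * p^k * (1 - p)^(6 - k)
  }, numeric(1)))
  expect_equal(replication_pvalue(6, 3, 0.025), exact)
  expect_lt(replication_pvalue(6, 3, 0.025), 0.0006)
  expect_equal(replication_pvalue(6, 3, 0), 0)
  expect_error(replication_pvalue(6, 7, 0.1), "k must")
  expect_error(replication_pvalue(6, 3, 1.2), "p must")
})

test_that("planted expression shifts are detected and nulls are not", {
  design <- expression_design(tissues = c("liver", "brain"),
                              sexes = c("M", "F"), n_per_group = 6)
  units <- paste0("u", 1:40)
  expressed <- data.frame(unit_id = paste0("u", 1:20),
                          tissue = "liver", sex = "M",
                          stringsAsFactors = FALSE)
  sim <- simulate_expression(contig_units = units, design = design,
                             expressed = expressed, n_random = 2604,
                             effect_sd = 3, rng_seed = 18)
  res <- call_expression(sim$scores, sim$manifest, sim$design)
  calls <- res$calls
  planted <- calls$unit_id %in% expressed$unit_id &
    calls$tissue == "liver" & calls$sex == "M"
  expect_gt(mean(calls$called[planted]), 0.95)
  # sensitivity at the unit level
  expect_gt(mean(res$units$expressed[res$units$unit_id %in%
                                       expressed$unit_id]), 0.95)
  # null groups stay near the analytic group-level false-call rate
  null_rate <- mean(calls$called[!planted])
  expect_lt(null_rate, 0.01)
})
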