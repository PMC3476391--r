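test_that("cluster_isogroups returns the connected components", {
  contigs <- data.frame(id = c("c1", "c2", "c3"), length = c(100, 200, 300))
  links <- data.frame(read_id = c("r1", "r2"),
                      contig_a = c("c1", "c2"), contig_b = c("c2", "c3"))
  gs <- cluster_isogroups(contig_graph(contigs, links))
  expect_length(gs, 1L)
  expect_equal(gs[[1]]$contig_ids, c("c1", "c2", "c3"))

  gs2 <- cluster_isogroups(contig_graph(contigs, NULL))
  expect_length(gs2, 3L)
  expect_true(all(lengths(lapply(gs2, `[[`, "contig_ids")) == 1L))

  # two components of sizes 2 and 3: union of members is all contigs
  contigs5 <- data.frame(id = paste0("c", 1:5), length = 100)
  links5 <- data.frame(read_id = paste0("r", 1:3),
                       contig_a = c("c1", "c3", "c4"),
                       contig_b = c("c2", "c4", "c5"))
  gs5 <- cluster_isogroups(contig_graph(contigs5, links5))
  sizes <- sort(lengths(lapply(gs5, `[[`, "contig_ids")))
  expect_equal(sizes, c(2L, 3L))
  expect_setequal(unlist(lapply(gs5, `[[`, "contig_ids")), contigs5$id)
})

test_that("contig_graph enforces its invariants", {
  contigs <- data.frame(id = c("c1", "c2"), length = c(100, 200))
  expect_error(contig_graph(contigs, data.frame(
    read_id = "r1", contig_a = "c1", contig_b = "c1")), "self-link")
  expect_error(contig_graph(contigs, data.frame(
    read_id = "r1", contig_a = "c1", contig_b = "cX")), "cX")
  expect_error(contig_graph(data.frame(id = c("c1", "c1"),
                                       length = c(1, 2))), "duplicate")
})

test_that("enumerate_isotigs handles the canonical small topologies", {
  diamond <- contig_graph(
    data.frame(id = paste0("c", 1:4), length = c(100, 200, 300, 400)),
    data.frame(read_id = paste0("r", 1:4),
               contig_a = c("c1", "c2", "c1", "c3"),
               contig_b = c("c2", "c4", "c3", "c4"),
               orientation = "forward"))
  gs <- cluster_isogroups(diamond)
  iso <- enumerate_isotigs(gs[[1]], diamond)
  paths <- lapply(iso, `[[`, "contig_ids")
  expect_equal(paths, list(c("c1", "c2", "c4"), c("c1", "c3", "c4")))
  expect_equal(vapply(iso, `[[`, numeric(1), "length"), c(700, 800))
  expect_false(attr(iso, "truncated"))

  chain <- contig_graph(
    data.frame(id = paste0("c", 1:3), length = 100),
    data.frame(read_id = c("r1", "r2"),
               contig_a = c("c1", "c2"), contig_b = c("c2", "c3"),
               orientation = "forward"))
  gsc <- cluster_isogroups(chain)
  isoc <- enumerate_isotigs(gsc[[1]], chain)
  expect_equal(lapply(isoc, `[[`, "contig_ids"),
               list(c("c1", "c2", "c3")))

  single <- contig_graph(data.frame(id = "c9", length = 123))
  gss <- cluster_isogroups(single)
  isos <- enumerate_isotigs(gss[[1]], single)
  expect_length(isos, 1L)
  expect_equal(isos[[1]]$contig_ids, "c9")
  expect_equal(isos[[1]]$length, 123)
})

test_that("enumeration truncates at max_isotigs with a flag", {
  # complete bipartite-ish fan: many maximal paths
  n <- 6L
  ids <- c("s", paste0("m", 1:n), "t")
  links <- rbind(
    data.frame(read_id = paste0("a", 1:n), contig_a = "s",
               contig_b = paste0("m", 1:n), orientation = "forward"),
    data.frame(read_id = paste0("b", 1:n), contig_a = paste0("m", 1:n),
               contig_b = "t", orientation = "forward"))
  g <- contig_graph(data.frame(id = ids, length = 100), links)
  grp <- cluster_isogroups(g)[[1]]
  full <- enumerate_isotigs(grp, g, max_isotigs = 100L)
  expect_length(full, n)
  expect_false(attr(full, "truncated"))
  cut <- enumerate_isotigs(grp, g, max_isotigs = 3L)
  expect_length(cut, 3L)
  expect_true(attr(cut, "truncated"))
})

test_that("cycles terminate paths and raise a warning", {
  g <- contig_graph(
    data.frame(id = paste0("c", 1:3), length = 100),
    data.frame(read_id = paste0("r", 1:3),
               contig_a = c("c1", "c2", "c3"),
               contig_b = c("c2", "c3", "c1"),
               orientation = "forward"))
  grp <- cluster_isogroups(g)[[1]]
  expect_warning(iso <- enumerate_isotigs(grp, g), "cycle")
  expect_gte(length(iso), 1L)
  for (t in iso) expect_false(anyDuplicated(t$contig_ids) > 0)
})

test_that("clustering and enumeration match the brute-force oracle on random graphs", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    directed <- rep %% 2 == 0
    toy <- random_toy_graph(n, p = 0.35, directed_links = directed)
    gs <- cluster_isogroups(toy$graph)

    # partition property + component equivalence
    members <- lapply(gs, `[[`, "contig_ids")
    expect_equal(sort(unlist(members)), sort(toy$contigs$id))
    expect_equal(anyDuplicated(unlist(members)), 0L)
    edges <- data.frame(from = toy$links$contig_a, to = toy$links$contig_b)
    expect_equal(
      sort(vapply(oracle_components(toy$contigs$id, edges), paste,
                  character(1), collapse = ",")),
      sort(vapply(members, function(m) paste(sort(m), collapse = ","),
                  character(1))))

    for (grp in gs) {
      if (component_is_cyclic_for_test(grp, toy, directed)) next
      iso <- suppressWarnings(
        enumerate_isotigs(grp, toy$graph, max_isotigs = 10000L))
      got <- lapply(iso, `[[`, "contig_ids")
      sub_edges <- edges[edges$from %in% grp$contig_ids &
                           edges$to %in% grp$contig_ids, , drop = FALSE]
      want <- if (length(grp$contig_ids) == 1L) {
        list(grp$contig_ids)
      } else {
        oracle_maximal_paths(grp$contig_ids, sub_edges, directed)
      }
      expect_equal(
        sort(vapply(got, paste, character(1), collapse = ",")),
        sort(vapply(want, paste, character(1), collapse = ",")))
      expect_gte(length(got), 1L)
    }
  }
})

test_that("planted isoform chains are recovered as isotigs", {
  sim <- simulate_transcriptome(n_genes = 25, rng_seed = 11)
  g <- contig_graph(sim$contigs, sim$links)
  gs <- enumerate_all_isotigs(cluster_isogroups(g), g)
  expect_length(gs, length(sim$truth$genes))
  got_paths <- unlist(lapply(gs, function(grp) {
    lapply(grp$isotigs, function(t) paste(t$contig_ids, collapse = ","))
  }))
  for (gene in sim$truth$genes) {
    for (chain in gene$isoform_chains) {
      expect_true(paste(chain, collapse = ",") %in% got_paths)
    }
  }
})

test_that("assembly_stats summarizes counts and means", {
  contigs <- data.frame(id = c("a", "b"), length = c(800, 1000))
  s <- suppressWarnings(assembly_stats(contigs))
  expect_equal(s$mean_length[s$entity == "contigs"], 900)
  expect_equal(s$n[s$entity == "contigs"], 2L)

  w <- testthat::capture_warnings(
    empty <- assembly_stats(data.frame(id = character(0),
                                       length = numeric(0))))
  expect_match(w, "empty", all = FALSE)
  expect_equal(empty$n[empty$entity == "contigs"], 0L)
  expect_equal(empty$mean_length[empty$entity == "contigs"], 0)

  # diamond + free contig: 2 isogroups, 1 with multiple (2) isotigs
  g <- contig_graph(
    data.frame(id = paste0("c", 1:5), length = 100),
    data.frame(read_id = paste0("r", 1:4),
               contig_a = c("c1", "c2", "c1", "c3"),
               contig_b = c("c2", "c4", "c3", "c4"),
               orientation = "forward"))
  gs <- enumerate_all_isotigs(cluster_isogroups(g), g)
  st <- suppressWarnings(assembly_stats(g$contigs, NULL, gs))
  expect_equal(st$n[st$entity == "isogroups"], 2L)
  expect_equal(st$n[st$entity == "isogroups_multi_isotig"], 1L)
  expect_equal(st$n[st$entity == "isotigs"], 3L)
})
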