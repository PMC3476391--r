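# Independent brute-force oracles and small fixture builders.

# All simple paths of a graph, by exhaustive recursive extension over the
# raw edge list (no shared code with the package's enumerator).
oracle_all_simple_paths <- function(nodes, edges, directed) {
  # edges: data.frame from,to (directed) or unordered pairs (undirected)
  nbr <- function(v, path) {
    out <- edges$to[edges$from == v]
    if (!directed) out <- c(out, edges$from[edges$to == v])
    setdiff(unique(out), path)
  }
  paths <- list()
  grow <- function(path) {
    paths[[length(paths) + 1L]] <<- path
    for (w in nbr(path[length(path)], path)) grow(c(path, w))
  }
  for (v in nodes) grow(v)
  paths
}

# Maximal simple paths: not extendable at either end; undirected paths
# canonicalized to start at the lexicographically smaller endpoint.
oracle_maximal_paths <- function(nodes, edges, directed) {
  all_paths <- oracle_all_simple_paths(nodes, edges, directed)
  succ <- function(v, path) {
    out <- edges$to[edges$from == v]
    if (!directed) out <- c(out, edges$from[edges$to == v])
    setdiff(unique(out), path)
  }
  pred <- function(v, path) {
    out <- edges$from[edges$to == v]
    if (!directed) out <- c(out, edges$to[edges$from == v])
    setdiff(unique(out), path)
  }
  keep <- Filter(function(p) {
    length(succ(p[length(p)], p)) == 0L && length(pred(p[1L], p)) == 0L
  }, all_paths)
  keep <- lapply(keep, function(p) {
    if (!directed && p[1L] > p[length(p)]) rev(p) else p
  })
  unique(keep)
}

# Brute-force connected components via repeated neighbourhood expansion.
oracle_components <- function(nodes, edges) {
  comp <- list()
  left <- nodes
  while (length(left)) {
    cur <- left[1L]
    repeat {
      grown <- unique(c(
        cur,
        edges$to[edges$from %in% cur],
        edges$from[edges$to %in% cur]
      ))
      if (length(grown) == length(cur)) break
      cur <- grown
    }
    comp[[length(comp) + 1L]] <- sort(cur)
    left <- setdiff(left, cur)
  }
  comp
}

# Random contig graph on <= n nodes with edge probability p.
random_toy_graph <- function(n, p = 0.3, directed_links = TRUE) {
  ids <- sprintf("c%02d", seq_len(n))
  contigs <- data.frame(id = ids, length = 100L + seq_len(n))
  pairs <- utils::combn(ids, 2L)
  pick <- stats::runif(ncol(pairs)) < p
  k <- sum(pick)
  links <- data.frame(
    read_id = sprintf("r%03d", seq_len(k)),
    contig_a = pairs[1L, pick],
    contig_b = pairs[2L, pick],
    orientation = rep(if (directed_links) "forward" else NA_character_, k),
    stringsAsFactors = FALSE
  )
  list(contigs = contigs, links = links,
       graph = contig_graph(contigs, links))
}

# 12-column hit row builder.
hit <- function(q, s, bits = 100, evalue = 1e-20, pident = 90,
                len = 100L, qs = 1L, qe = 100L, ss = 1L, se = 100L) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
             mismatch = 0L, gapopen = 0L, qstart = qs, qend = qe,
             sstart = ss, send = se, evalue = evalue, bitscore = bits,
             stringsAsFactors = FALSE)
}

hits_table <- function(...) as_hit_table(do.call(rbind, list(...)))

# Gapless read alignment covering an isotig span.
toy_alignment <- function(read_id, isotig_id, iso_seq, sstart, send,
                          read_seq = NULL, read_len = NULL,
                          qstart = 1L, qend = NULL,
                          pident = 99, evalue = 1e-30, strand = "+") {
  ref <- substr(iso_seq, sstart, send)
  if (is.null(read_seq)) read_seq <- ref
  if (is.null(read_len)) read_len <- nchar(read_seq)
  if (is.null(qend)) qend <- qstart + nchar(read_seq) - 1L
  data.frame(read_id = read_id, isotig_id = isotig_id,
             read_len = read_len, qstart = qstart, qend = qend,
             sstart = sstart, send = send, pident = pident,
             evalue = evalue, read_aln = read_seq, isotig_aln = ref,
             strand = strand, stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

component_is_cyclic_for_test <- function(grp, toy, directed) {
  # the oracle's maximality definition and the enumerator agree on acyclic
  # components; cyclic ones are covered by the dedicated cycle test
  links <- toy$links[toy$links$contig_a %in% grp$contig_ids &
                       toy$links$contig_b %in% grp$contig_ids, ]
  if (nrow(links) == 0L) return(FALSE)
  if (directed) {
    g <- igraph::graph_from_data_frame(
      unique(links[, c("contig_a", "contig_b")]), directed = TRUE,
      vertices = data.frame(name = grp$contig_ids))
    !igraph::is_dag(g)
  } else {
    e <- unique(data.frame(a = pmin(links$contig_a, links$contig_b),
                           b = pmax(links$contig_a, links$contig_b)))
    nrow(e) > length(grp$contig_ids) - 1L
  }
}

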