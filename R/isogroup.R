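#' Build a contig graph from contigs and broken-read links
#'
#' The contig graph is the substrate for isogroup clustering: vertices are
#' contigs, edges are broken reads whose alignment spanned two contigs the
#' assembler kept separate. Multiple reads may link the same contig pair
#' (the link table is a multiset).
#'
#' @param contigs A data.frame with columns `id`, `length` and optionally
#'   `depth` and `seq`, or a named [Biostrings::DNAStringSet] (lengths are
#'   taken from the sequences).
#' @param links A data.frame with columns `read_id`, `contig_a`, `contig_b`
#'   and optionally `orientation` (`"forward"`: a precedes b in the
#'   transcript; `"reverse"`: b precedes a). May have zero rows.
#' @return An object of class `contig_graph`.
#' @export
contig_graph <- function(contigs, links = NULL) {
  if (methods::is(contigs, "DNAStringSet")) {
    contigs <- data.frame(id = names(contigs),
                          length = Biostrings::width(contigs),
                          seq = as.character(contigs),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "length") %in% names(contigs)))
  if (anyDuplicated(contigs$id)) stop("duplicate contig id", call. = FALSE)
  if (any(contigs$length < 1)) stop("contig length must be >= 1",
                                    call. = FALSE)
  if (is.null(contigs$depth)) contigs$depth <- NA_real_
  if (is.null(links) || nrow(links) == 0L) {
    links <- data.frame(read_id = character(0), contig_a = character(0),
                        contig_b = character(0), orientation = character(0),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("read_id", "contig_a", "contig_b") %in% names(links)))
  if (is.null(links$orientation)) links$orientation <- NA_character_
  if (any(links$contig_a == links$contig_b)) {
    stop("self-links (contig_a == contig_b) are not allowed", call. = FALSE)
  }
  unknown <- setdiff(c(links$contig_a, links$contig_b), contigs$id)
  if (length(unknown)) {
    stop("link endpoint not among contigs: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_or <- !is.na(links$orientation) &
    !links$orientation %in% c("forward", "reverse")
  if (any(bad_or)) stop("orientation must be 'forward' or 'reverse'",
                        call. = FALSE)
  structure(list(contigs = contigs, links = links), class = "contig_graph")
}

#' @export
print.contig_graph <- function(x, ...) {
  cat("<contig_graph> ", nrow(x$contigs), " contigs, ",
      nrow(x$links), " broken-read links\n", sep = "")
  invisible(x)
}

#' Cluster contigs into isogroups
#'
#' Isogroups are the connected components of the contig-link graph: contigs
#' joined (directly or transitively) by broken reads form one putative
#' gene. Contigs with no links become singleton isogroups. The result is a
#' total, disjoint partition of the contigs.
#'
#' @param graph A [contig_graph()].
#' @return A list of class `isogroup_set`; each element has `id` and
#'   `contig_ids`. Isogroup ids are `isogroup00001, ...` in order of each
#'   component's first contig.
#' @export
cluster_isogroups <- function(graph) {
  stopifnot(inherits(graph, "contig_graph"))
  g <- igraph::graph_from_data_frame(
    graph$links[, c("contig_a", "contig_b")],
    directed = FALSE,
    vertices = data.frame(name = graph$contigs$id)
  )
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  # stable order: by first appearance of a member contig in the input
  first_idx <- vapply(members, function(m) {
    min(match(m, graph$contigs$id))
  }, numeric(1))
  members <- members[order(first_idx)]
  out <- lapply(seq_along(members), function(i) {
    list(id = sprintf("isogroup%05d", i),
         contig_ids = sort(members[[i]]))
  })
  class(out) <- "isogroup_set"
  out
}

#' @export
print.isogroup_set <- function(x, ...) {
  sizes <- vapply(x, function(g) length(g$contig_ids), integer(1))
  cat("<isogroup_set> ", length(x), " isogroups (",
      sum(sizes > 1L), " with >1 contig)\n", sep = "")
  invisible(x)
}

#' Enumerate isotigs (link-supported contig paths) for one isogroup
#'
#' An isotig is a maximal simple path through the isogroup's contigs in
#' which every consecutive pair shares at least one broken-read link. When
#' all links carry an orientation the graph is traversed as directed
#' (`forward` means contig_a precedes contig_b); otherwise it is treated as
#' undirected and each path is canonicalized to start at its
#' lexicographically smaller endpoint. A single-contig isogroup yields one
#' isotig equal to that contig. Cycles cannot be represented as simple
#' paths; when the component contains one, enumeration still terminates
#' (paths simply stop) and a warning is raised. Enumeration is truncated
#' with a flag once `max_isotigs` paths have been collected.
#'
#' @param group One element of [cluster_isogroups()] output.
#' @param graph The [contig_graph()] the group came from.
#' @param max_isotigs Safety cap on the number of enumerated paths.
#' @return A list of isotigs (`id`, `contig_ids`, `length`), with attribute
#'   `truncated` set to `TRUE` if the cap was hit.
#' @export
enumerate_isotigs <- function(group, graph, max_isotigs = 100L) {
  stopifnot(inherits(graph, "contig_graph"))
  ids <- group$contig_ids
  lens <- stats::setNames(graph$contigs$length, graph$contigs$id)
  make_isotig <- function(i, path) {
    list(id = sprintf("%s.isotig%03d", group$id, i),
         contig_ids = path,
         length = sum(lens[path]))
  }
  if (length(ids) == 1L) {
    out <- list(make_isotig(1L, ids))
    attr(out, "truncated") <- FALSE
    return(out)
  }
  links <- graph$links[graph$links$contig_a %in% ids &
                         graph$links$contig_b %in% ids, , drop = FALSE]
  directed <- nrow(links) > 0L && !anyNA(links$orientation)
  if (directed) {
    from <- ifelse(links$orientation == "forward",
                   links$contig_a, links$contig_b)
    to <- ifelse(links$orientation == "forward",
                 links$contig_b, links$contig_a)
    succ <- split(to, factor(from, levels = ids))
    pred <- split(from, factor(to, levels = ids))
  } else {
    from <- c(links$contig_a, links$contig_b)
    to <- c(links$contig_b, links$contig_a)
    succ <- split(to, factor(from, levels = ids))
    pred <- succ
  }
  succ <- lapply(succ, unique)
  pred <- lapply(pred, unique)
  has_cycle <- component_has_cycle(ids, links, directed)
  if (has_cycle) {
    warning("isogroup ", group$id,
            " contains a cycle; isotigs are simple paths only",
            call. = FALSE)
  }
  paths <- list()
  truncated <- FALSE
  emit <- function(path) {
    if (!directed && path[1] > path[length(path)]) path <- rev(path)
    key <- paste(path, collapse = "\r")
    if (!is.null(paths[[key]])) return(TRUE)
    if (length(paths) >= max_isotigs) {
      truncated <<- TRUE
      return(FALSE)
    }
    paths[[key]] <<- path
    TRUE
  }
  extend <- function(path) {
    nxt <- setdiff(succ[[path[length(path)]]], path)
    # maximal: extendable neither forward nor backward
    if (length(nxt) == 0L) {
      prv <- setdiff(pred[[path[1L]]], path)
      if (length(prv) == 0L) {
        return(emit(path))
      }
      return(TRUE)
    }
    for (v in nxt) {
      if (!extend(c(path, v))) return(FALSE)
    }
    TRUE
  }
  for (v in sort(ids)) {
    # only start where the path cannot be pre-extended
    if (!extend(v)) break
  }
  out <- unname(paths)
  # deterministic order: lexicographic on the contig sequence
  keys <- vapply(out, paste, character(1), collapse = "\r")
  out <- out[order(keys)]
  out <- lapply(seq_along(out), function(i) make_isotig(i, out[[i]]))
  if (length(out) == 0L) {
    # every vertex lies on a cycle with no path endpoints; fall back to a
    # degenerate single-contig isotig so every isogroup has at least one
    out <- list(make_isotig(1L, sort(ids)[1L]))
  }
  attr(out, "truncated") <- truncated
  out
}

component_has_cycle <- function(ids, links, directed) {
  if (nrow(links) == 0L) return(FALSE)
  if (directed) {
    from <- ifelse(links$orientation == "forward",
                   links$contig_a, links$contig_b)
    to <- ifelse(links$orientation == "forward",
                 links$contig_b, links$contig_a)
    g <- igraph::graph_from_data_frame(
      unique(data.frame(from, to)), directed = TRUE,
      vertices = data.frame(name = ids))
    !igraph::is_dag(g)
  } else {
    e <- unique(data.frame(
      a = pmin(links$contig_a, links$contig_b),
      b = pmax(links$contig_a, links$contig_b)))
    # a connected undirected simple graph is acyclic iff |E| = |V| - 1
    nrow(e) > length(ids) - 1L
  }
}

#' Enumerate isotigs for every isogroup
#'
#' @param isogroups An `isogroup_set` from [cluster_isogroups()].
#' @param graph The [contig_graph()].
#' @param max_isotigs Per-isogroup enumeration cap.
#' @return The `isogroup_set` with an `isotigs` element added to each
#'   isogroup.
#' @export
enumerate_all_isotigs <- function(isogroups, graph, max_isotigs = 100L) {
  out <- lapply(isogroups, function(g) {
    g$isotigs <- enumerate_isotigs(g, graph, max_isotigs)
    g
  })
  class(out) <- "isogroup_set"
  out
}

#' Summary statistics for an assembly
#'
#' Reports counts, total lengths and mean lengths for contigs, singletons
#' and isotigs, plus the isogroup count and the number of isogroups with
#' more than one isotig.
#'
#' @param contigs Contig table (data.frame with `length`) or
#'   [Biostrings::DNAStringSet].
#' @param singletons Singleton reads, same forms as `contigs`; may be NULL.
#' @param isogroups An `isogroup_set` with isotigs enumerated (see
#'   [enumerate_all_isotigs()]); may be NULL.
#' @return A data.frame with columns `entity`, `n`, `total_length`,
#'   `mean_length`. Empty inputs yield zero counts (mean reported as 0 with
#'   a warning).
#' @export
assembly_stats <- function(contigs, singletons = NULL, isogroups = NULL) {
  get_lengths <- function(x) {
    if (is.null(x)) return(numeric(0))
    if (methods::is(x, "DNAStringSet")) return(Biostrings::width(x))
    if (is.data.frame(x)) return(x$length)
    stop("cannot extract lengths", call. = FALSE)
  }
  safe_mean <- function(v) {
    if (length(v) == 0L) {
      warning("mean length undefined for empty input; reporting 0",
              call. = FALSE)
      return(0)
    }
    mean(v)
  }
  clen <- get_lengths(contigs)
  slen <- get_lengths(singletons)
  itigs <- if (is.null(isogroups)) list() else
    unlist(lapply(isogroups, `[[`, "isotigs"), recursive = FALSE)
  ilen <- vapply(itigs, `[[`, numeric(1), "length")
  n_multi <- if (is.null(isogroups)) 0L else
    sum(vapply(isogroups, function(g) length(g$isotigs) > 1L, logical(1)))
  rows <- data.frame(
    entity = c("contigs", "singletons", "isotigs", "isogroups",
               "isogroups_multi_isotig"),
    n = c(length(clen), length(slen), length(ilen),
          if (is.null(isogroups)) 0L else length(isogroups), n_multi),
    total_length = c(sum(clen), sum(slen), sum(ilen), NA, NA),
    mean_length = c(safe_mean(clen), safe_mean(slen), safe_mean(ilen),
                    NA, NA),
    stringsAsFactors = FALSE
  )
  rows
}

#' Tabular views of an isogroup set
#'
#' @param isogroups An `isogroup_set` (with or without isotigs).
#' @return A list of two data.frames: `membership` (contig_id, isogroup_id)
#'   and `isotigs` (isotig_id, isogroup_id, n_contigs, length, path with
#'   contigs joined by `,`); the latter is empty when isotigs have not been
#'   enumerated.
#' @export
isogroup_tables <- function(isogroups) {
  membership <- do.call(rbind, lapply(isogroups, function(g) {
    data.frame(contig_id = g$contig_ids, isogroup_id = g$id,
               stringsAsFactors = FALSE)
  }))
  itig_rows <- lapply(isogroups, function(g) {
    if (is.null(g$isotigs)) return(NULL)
    do.call(rbind, lapply(g$isotigs, function(t) {
      data.frame(isotig_id = t$id, isogroup_id = g$id,
                 n_contigs = length(t$contig_ids), length = t$length,
                 path = paste(t$contig_ids, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  })
  itig <- do.call(rbind, itig_rows)
  if (is.null(itig)) {
    itig <- data.frame(isotig_id = character(0), isogroup_id = character(0),
                       n_contigs = integer(0), length = numeric(0),
                       path = character(0), stringsAsFactors = FALSE)
  }
  list(membership = membership, isotigs = itig)
}
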