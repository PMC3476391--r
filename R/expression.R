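#' Design the probe complement for an array
#'
#' Selects up to three non-overlapping 60-mers per contig, evenly spaced
#' along the sequence, and one probe per singleton. Windows containing `N`
#' are shifted to the nearest N-free window in their segment, or dropped if
#' none exists. Sequences shorter than the probe length are skipped with a
#' warning; contigs long enough for only one or two non-overlapping probes
#' get that many.
#'
#' @param contigs Named [Biostrings::DNAStringSet] (or named character
#'   vector) of contig sequences.
#' @param singletons Same, for singleton reads (may be empty/NULL).
#' @param cfg A [pipeline_config()].
#' @return A data.frame manifest: `probe_id`, `target_id`, `probe_class`
#'   (`contig`/`singleton`), `start` (1-based on target), `seq`.
#' @export
design_probes <- function(contigs, singletons = NULL,
                          cfg = pipeline_config()) {
  plen <- cfg$probe_length
  design_one <- function(seq, n_max) {
    L <- nchar(seq)
    k <- min(n_max, L %/% plen)
    if (k == 0L) return(integer(0))
    starts <- if (k == 1L) {
      as.integer((L - plen) %/% 2L) + 1L
    } else {
      as.integer(round(seq(1L, L - plen + 1L, length.out = k)))
    }
    # keep probes non-overlapping after rounding
    for (i in seq_len(k - 1L)) {
      if (i < k && starts[i + 1L] < starts[i] + plen) {
        starts[i + 1L] <- starts[i] + plen
      }
    }
    ok <- logical(k)
    for (i in seq_len(k)) {
      w <- substr(seq, starts[i], starts[i] + plen - 1L)
      if (!grepl("N", w, fixed = TRUE)) {
        ok[i] <- TRUE
        next
      }
      # slide within the free range to find an N-free window
      lo <- if (i == 1L) 1L else starts[i - 1L] + plen
      hi <- if (i == k) L - plen + 1L else starts[i + 1L] - plen
      for (s in seq2(lo, hi)) {
        w <- substr(seq, s, s + plen - 1L)
        if (!grepl("N", w, fixed = TRUE)) {
          starts[i] <- s
          ok[i] <- TRUE
          break
        }
      }
    }
    starts[ok]
  }
  build <- function(seqs, class, n_max) {
    if (is.null(seqs) || length(seqs) == 0L) return(NULL)
    ids <- names(seqs)
    seqs_chr <- unname(as.character(seqs))
    stopifnot(!is.null(ids))
    short <- nchar(seqs_chr) < plen
    if (any(short)) {
      warning(sum(short), " ", class,
              " sequence(s) shorter than the probe length were skipped",
              call. = FALSE)
    }
    rows <- lapply(which(!short), function(i) {
      starts <- design_one(seqs_chr[i], n_max)
      if (!length(starts)) return(NULL)
      data.frame(
        probe_id = sprintf("%s_p%d", ids[i], seq_along(starts)),
        target_id = ids[i],
        probe_class = class,
        start = starts,
        seq = substring(seqs_chr[i], starts, starts + plen - 1L),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  }
  out <- rbind(build(contigs, "contig", cfg$probes_per_contig),
               build(singletons, "singleton", 1L))
  if (is.null(out)) {
    out <- data.frame(probe_id = character(0), target_id = character(0),
                      probe_class = character(0), start = integer(0),
                      seq = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Probe accounting by class and per-target allocation
#'
#' @param manifest A probe manifest (from [design_probes()], possibly with
#'   `random`/`control` probes appended).
#' @return A list: `by_class` (named counts summing to the manifest size)
#'   and `contig_allocation` (data.frame `n_probes`, `n_contigs`,
#'   `total_probes` for contig-class targets).
#' @export
probe_accounting <- function(manifest) {
  by_class <- table(factor(manifest$probe_class,
                           levels = c("contig", "singleton", "random",
                                      "control")))
  ctg <- manifest[manifest$probe_class == "contig", , drop = FALSE]
  alloc <- table(table(ctg$target_id))
  contig_allocation <- data.frame(
    n_probes = as.integer(names(alloc)),
    n_contigs = as.integer(alloc)
  )
  contig_allocation$total_probes <-
    contig_allocation$n_probes * contig_allocation$n_contigs
  list(by_class = c(by_class), contig_allocation = contig_allocation)
}

#' Generate random probes from a Markov model of nucleotide composition
#'
#' Fits an order-k Markov chain (k in 0..2) to the composition of the
#' supplied sequences and samples probe sequences from it. These probes
#' match the background nucleotide statistics while targeting nothing,
#' providing an empirical null for hybridization signal.
#'
#' @param sequences [Biostrings::DNAStringSet] or character vector used to
#'   fit the chain (N bases are ignored).
#' @param n Number of probes (the array design used 2,604).
#' @param order Markov order, 0, 1 or 2.
#' @param probe_length Probe length in bp.
#' @param rng_seed Optional seed for reproducibility.
#' @return Character vector of `n` probe sequences.
#' @export
generate_random_probes <- function(sequences, n = 2604L, order = 1L,
                                   probe_length = 60L, rng_seed = NULL) {
  stopifnot(n >= 1L, order %in% 0:2)
  seqs <- toupper(as.character(sequences))
  seqs <- gsub("[^ACGT]", "", seqs)
  seqs <- seqs[nchar(seqs) > order]
  if (!length(seqs) || sum(nchar(seqs)) == 0L) {
    stop("no usable training sequence for the Markov model", call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  bases <- c("A", "C", "G", "T")
  if (order == 0L) {
    counts <- Biostrings::alphabetFrequency(
      Biostrings::DNAStringSet(seqs))[, bases, drop = FALSE]
    p <- colSums(counts)
    p <- p / sum(p)
    probes <- vapply(seq_len(n), function(i) {
      paste(sample(bases, probe_length, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    return(probes)
  }
  # transition counts: context (k-mer) -> next base
  ctx_counts <- matrix(0, nrow = 4L^order, ncol = 4L,
                       dimnames = list(all_kmers(order), bases))
  for (s in seqs) {
    L <- nchar(s)
    if (L <= order) next
    ctx <- substring(s, seq_len(L - order), seq_len(L - order) + order - 1L)
    nxt <- substring(s, seq_len(L - order) + order,
                     seq_len(L - order) + order)
    tab <- table(factor(ctx, levels = rownames(ctx_counts)),
                 factor(nxt, levels = bases))
    ctx_counts <- ctx_counts + unclass(tab)
  }
  row_tot <- rowSums(ctx_counts)
  # contexts never observed fall back to the marginal base distribution
  marg <- colSums(ctx_counts)
  marg <- marg / sum(marg)
  trans <- ctx_counts / ifelse(row_tot == 0, 1, row_tot)
  trans[row_tot == 0, ] <- rep(marg, each = sum(row_tot == 0))
  start_p <- row_tot / sum(row_tot)
  probes <- vapply(seq_len(n), function(i) {
    ctx <- sample(rownames(ctx_counts), 1L, prob = start_p)
    out <- strsplit(ctx, "")[[1]]
    while (length(out) < probe_length) {
      b <- sample(bases, 1L, prob = trans[ctx, ])
      out <- c(out, b)
      ctx <- paste0(substring(ctx, 2L), b)
    }
    paste(out[seq_len(probe_length)], collapse = "")
  }, character(1))
  probes
}

all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  if (k == 1L) return(bases)
  do.call(paste0, rev(expand.grid(rep(list(bases), k),
                                  stringsAsFactors = FALSE)))
}

#' Per-individual expression threshold from random probes
#'
#' The threshold is the empirical quantile (linear interpolation between
#' order statistics, the default "type 7" estimator) of the individual's
#' random-probe scores; by construction a random probe exceeds its own
#' individual's threshold with probability about `1 - quantile` (0.025 at
#' the default 97.5% quantile).
#'
#' @param scores Numeric matrix of normalized scores, probes in rows
#'   (rownames = probe ids), individuals in columns.
#' @param manifest Probe manifest with `probe_id` and `probe_class`.
#' @param individual Column name (or index) of the individual.
#' @param cfg A [pipeline_config()].
#' @return The score threshold (single numeric).
#' @export
individual_threshold <- function(scores, manifest, individual,
                                 cfg = pipeline_config()) {
  rnd <- manifest$probe_id[manifest$probe_class == "random"]
  rnd <- intersect(rnd, rownames(scores))
  if (!length(rnd)) {
    stop("no random probes available for individual ", individual,
         call. = FALSE)
  }
  null_threshold(scores[rnd, individual], cfg$expr_null_quantile)
}

#' Quantile threshold of a null score vector
#'
#' @param null_scores Numeric vector of null (random-probe) scores.
#' @param quantile Probability for the empirical quantile (default 0.975).
#' @return The type-7 empirical quantile.
#' @export
null_threshold <- function(null_scores, quantile = 0.975) {
  stopifnot(length(null_scores) >= 1L)
  unname(stats::quantile(null_scores, probs = quantile, type = 7,
                         names = FALSE))
}

#' Call expression for one unit
#'
#' Per individual, the unit's statistic is the median of its probe scores
#' (the single score for one-probe units; the mean of the two for
#' two-probe units). The individual is called expressed iff the statistic
#' is strictly above that individual's random-probe threshold; a tissue-sex
#' group is called iff at least `expr_min_individuals` of its
#' `expr_group_size` individuals are called; the unit is expressed overall
#' iff any group is called.
#'
#' @param scores Score matrix (probes x individuals).
#' @param manifest Probe manifest.
#' @param design Data.frame `individual`, `tissue`, `sex`; individuals must
#'   match the score columns.
#' @param unit_id Target id to call.
#' @param cfg A [pipeline_config()].
#' @param thresholds Optional precomputed named vector of per-individual
#'   thresholds (computed from the matrix if omitted).
#' @return A data.frame with one row per tissue-sex group: `unit_id`,
#'   `tissue`, `sex`, `n_called`, `called`, `any_group_called`.
#' @export
call_unit <- function(scores, manifest, design, unit_id,
                      cfg = pipeline_config(), thresholds = NULL) {
  probes <- manifest$probe_id[!is.na(manifest$target_id) &
                                manifest$target_id == unit_id]
  probes <- intersect(probes, rownames(scores))
  if (!length(probes)) {
    stop("unit ", unit_id, " has no probes in the manifest/matrix",
         call. = FALSE)
  }
  if (is.null(thresholds)) {
    thresholds <- vapply(design$individual, function(ind) {
      individual_threshold(scores, manifest, ind, cfg)
    }, numeric(1))
    names(thresholds) <- design$individual
  }
  sub <- scores[probes, design$individual, drop = FALSE]
  stat <- apply(sub, 2L, stats::median)
  ind_called <- stat > thresholds[design$individual]
  per_group <- stats::aggregate(
    ind_called,
    by = list(tissue = design$tissue, sex = design$sex),
    FUN = sum)
  names(per_group)[3] <- "n_called"
  per_group$called <- per_group$n_called >= cfg$expr_min_individuals
  data.frame(unit_id = unit_id,
             tissue = per_group$tissue, sex = per_group$sex,
             n_called = per_group$n_called, called = per_group$called,
             any_group_called = any(per_group$called),
             stringsAsFactors = FALSE)
}

#' Call expression for all units on the array
#'
#' Vectorized driver over [call_unit()]'s rule: per-individual thresholds
#' are computed once, unit statistics are medians over each unit's probes
#' (computed directly from the matrix for one-probe units), and group calls
#' apply the k-of-n replication rule.
#'
#' @inheritParams call_unit
#' @return A list: `calls` (per unit per group) and `units` (per unit:
#'   `unit_id`, `expressed` = called in at least one group).
#' @export
call_expression <- function(scores, manifest, design,
                            cfg = pipeline_config()) {
  thresholds <- vapply(design$individual, function(ind) {
    individual_threshold(scores, manifest, ind, cfg)
  }, numeric(1))
  names(thresholds) <- design$individual
  targets <- manifest[!is.na(manifest$target_id) &
                        manifest$probe_class %in% c("contig", "singleton"), ]
  targets <- targets[targets$probe_id %in% rownames(scores), ]
  probe_sets <- split(targets$probe_id, targets$target_id)
  n_probes <- lengths(probe_sets)
  cols <- design$individual
  stat <- matrix(NA_real_, nrow = length(probe_sets), ncol = length(cols),
                 dimnames = list(names(probe_sets), cols))
  single <- n_probes == 1L
  if (any(single)) {
    stat[single, ] <- scores[unlist(probe_sets[single]), cols,
                             drop = FALSE]
  }
  for (u in names(probe_sets)[!single]) {
    stat[u, ] <- apply(scores[probe_sets[[u]], cols, drop = FALSE], 2L,
                       stats::median)
  }
  called <- sweep(stat, 2L, thresholds[cols], ">")
  groups <- split(seq_along(cols), paste(design$tissue, design$sex,
                                         sep = "\r"))
  call_rows <- lapply(names(groups), function(gk) {
    idx <- groups[[gk]]
    ts <- strsplit(gk, "\r", fixed = TRUE)[[1]]
    n_called <- rowSums(called[, idx, drop = FALSE])
    data.frame(unit_id = rownames(stat), tissue = ts[1], sex = ts[2],
               n_called = as.integer(n_called),
               called = n_called >= cfg$expr_min_individuals,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, call_rows)
  expressed <- tapply(calls$called, calls$unit_id, any)
  units <- data.frame(unit_id = names(expressed),
                      expressed = as.logical(expressed),
                      stringsAsFactors = FALSE)
  rownames(units) <- NULL
  list(calls = calls, units = units)
}

#' Probability of a k-of-n replication call under independence
#'
#' Exact binomial tail `P(X >= k)` for `X ~ Binomial(n, p)`: the chance
#' that at least `k` of `n` individuals are called when each call occurs
#' independently with probability `p`. With the default per-individual
#' false-call rate of 0.025 (the 97.5% random-probe quantile rule) and a
#' 3-of-6 replication requirement this is about 2.95e-4.
#'
#' @param n Group size.
#' @param k Required number of called individuals.
#' @param p Per-individual call probability.
#' @return The tail probability.
#' @export
replication_pvalue <- function(n, k, p) {
  if (!is.numeric(p) || p < 0 || p > 1) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= n", call. = FALSE)
  stats::pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}
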