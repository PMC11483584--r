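#' Maximal tau gradient consensus
#'
#' Finds the length of the longest sequence of regions whose descending
#' density order is identical in every sample — the longest common
#' subsequence of the k per-sample rankings. Because every ranking is a
#' permutation of the same region set, the problem reduces to the
#' longest path in the precedence DAG with an edge u -> v iff u
#' precedes v in every sample; any single sample's ordering is a
#' topological order of that DAG, so a single O(k n^2) dynamic
#' programming sweep suffices. This is equivalent to the incremental
#' build-longer-patterns-from-shorter-ones formulation: a consensus of
#' length n always extends one of length n - 1.
#'
#' @param rankings a [ranking_set], or a plain list of permutations of
#'   a common id set.
#' @return list with `length` (integer) and `sequence` (one witness
#'   consensus of maximal length; ties broken deterministically towards
#'   the earliest extendable predecessor).
#' @export
max_consensus <- function(rankings) {
  ord <- ranking_orderings(rankings)
  pos <- position_matrix(ord)
  n <- ncol(pos)
  k <- nrow(pos)
  ids <- colnames(pos)
  o1 <- ord[[1]]
  dp <- integer(n)
  parent <- integer(n)  # 0 = chain start; indexes into o1 order
  pos_rest <- pos[, as.character(o1), drop = FALSE]  # columns in sample-1 order
  for (i in seq_len(n)) {
    best <- 0L
    arg <- 0L
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      ok <- rep(TRUE, i - 1L)
      for (s in seq_len(k)) if (s > 1L)
        ok <- ok & (pos_rest[s, prev] < pos_rest[s, i])
      if (any(ok)) {
        cand <- prev[ok]
        best <- max(dp[cand])
        arg <- cand[dp[cand] == best][1L]
      }
    }
    dp[i] <- best + 1L
    parent[i] <- arg
  }
  len <- max(dp)
  i <- which(dp == len)[1L]
  seq_rev <- integer(0)
  while (i > 0L) {
    seq_rev <- c(seq_rev, o1[i])
    i <- parent[i]
  }
  list(length = len, sequence = rev(seq_rev))
}

# Normalise input to a list of integer permutations of a common set.
ranking_orderings <- function(rankings) {
  ord <- if (inherits(rankings, "ranking_set")) rankings$orderings
         else rankings
  if (!is.list(ord) || length(ord) < 1L)
    stop("rankings must be a ranking_set or a non-empty list of orderings")
  ids <- sort(as.integer(ord[[1]]))
  for (o in ord)
    if (!identical(sort(as.integer(o)), ids))
      stop("non-permutation input: orderings must all permute the same id set")
  lapply(ord, as.integer)
}

# k x n matrix of the rank position of every id in every sample;
# columns named by id.
position_matrix <- function(ord) {
  ids <- sort(ord[[1]])
  pos <- matrix(0L, length(ord), length(ids),
                dimnames = list(NULL, ids))
  for (s in seq_along(ord))
    pos[s, as.character(ord[[s]])] <- seq_along(ord[[s]])
  pos
}

#' Is a sequence order-conserved in every sample?
#' @param sequence integer vector of region ids.
#' @param rankings a [ranking_set] or list of orderings.
#' @return logical scalar.
#' @export
is_order_conserved <- function(sequence, rankings) {
  ord <- ranking_orderings(rankings)
  pos <- position_matrix(ord)
  if (!all(as.character(sequence) %in% colnames(pos))) return(FALSE)
  all(vapply(seq_len(nrow(pos)), function(s)
    all(diff(pos[s, as.character(sequence)]) > 0), logical(1)))
}

#' Enumerate all consensus sequences of a given length
#'
#' Lists every sequence of exactly `length_L` regions whose order is
#' conserved in all samples (all maximum-length chains when `length_L`
#' equals the maximum). Output is in deterministic lexicographic order
#' of region ids. Enumeration can be exponential in pathological
#' inputs; `cap` aborts with an error when exceeded.
#'
#' @param rankings a [ranking_set] or list of orderings.
#' @param length_L target sequence length.
#' @param cap maximum number of sequences before aborting.
#' @return list of integer vectors (possibly empty when `length_L`
#'   exceeds the maximum consensus length).
#' @export
enumerate_sequences <- function(rankings, length_L, cap = 1e6) {
  ord <- ranking_orderings(rankings)
  pos <- position_matrix(ord)
  n <- ncol(pos)
  k <- nrow(pos)
  if (length_L < 1L) stop("length_L must be >= 1")
  ids_by_s1 <- ord[[1]]
  pos_s1 <- pos[, as.character(ids_by_s1), drop = FALSE]
  # successors of node i (indices into sample-1 order)
  succ <- vector("list", n)
  for (i in seq_len(n)) {
    later <- if (i < n) (i + 1L):n else integer(0)
    if (length(later)) {
      ok <- rep(TRUE, length(later))
      for (s in seq_len(k)) if (s > 1L)
        ok <- ok & (pos_s1[s, later] > pos_s1[s, i])
      succ[[i]] <- later[ok]
    } else succ[[i]] <- integer(0)
  }
  # longest chain starting at each node, for pruning
  lp <- integer(n)
  for (i in rev(seq_len(n)))
    lp[i] <- 1L + if (length(succ[[i]])) max(lp[succ[[i]]]) else 0L
  out <- list()
  count <- 0L
  dfs <- function(i, chain) {
    chain <- c(chain, i)
    remaining <- length_L - length(chain)
    if (remaining == 0L) {
      count <<- count + 1L
      if (count > cap) stop("enumeration cap exceeded (", cap, " sequences)")
      out[[count]] <<- ids_by_s1[chain]
      return()
    }
    for (j in succ[[i]]) if (lp[j] >= remaining) dfs(j, chain)
  }
  for (i in seq_len(n)) if (lp[i] >= length_L) dfs(i, integer(0))
  if (!length(out)) return(list())
  key <- vapply(out, function(s) paste(sprintf("%09d", s), collapse = ","),
                character(1))
  out[order(key)]
}

#' Is `a` a (not necessarily contiguous) subsequence of `b`?
#' @param a,b integer vectors.
#' @return logical scalar.
#' @keywords internal
is_subsequence <- function(a, b) {
  if (!length(a)) return(TRUE)
  j <- 1L
  for (x in b) {
    if (x == a[j]) {
      j <- j + 1L
      if (j > length(a)) return(TRUE)
    }
  }
  FALSE
}

#' Unique consensus patterns by descending length
#'
#' Starting from the maximal consensus length and walking down to
#' `min_length`, retains a length-L sequence only if it is not
#' contained in any already-retained longer sequence. Containment means
#' "is a subsequence of" by default (matching order-conservation
#' semantics); `containment = "exact"` only discards exact duplicates.
#' Sequences that partially overlap a longer one are retained.
#'
#' @param rankings a [ranking_set] or list of orderings.
#' @param min_length smallest length to enumerate (typically the
#'   permutation-null significance threshold).
#' @param max_length largest length; default the maximal consensus
#'   length.
#' @param containment `"subsequence"` or `"exact"`.
#' @param cap forwarded to [enumerate_sequences()].
#' @return named list (`"L<length>"`) of lists of retained sequences,
#'   descending length.
#' @export
unique_patterns <- function(rankings, min_length = 2L, max_length = NULL,
                            containment = c("subsequence", "exact"),
                            cap = 1e6) {
  containment <- match.arg(containment)
  if (is.null(max_length)) max_length <- max_consensus(rankings)$length
  if (min_length > max_length) return(stats::setNames(list(), character(0)))
  retained <- list()
  result <- list()
  for (L in seq(max_length, min_length)) {
    cands <- enumerate_sequences(rankings, L, cap = cap)
    keep <- list()
    for (s in cands) {
      contained <- if (containment == "subsequence") {
        any(vapply(retained, function(r) is_subsequence(s, r), logical(1)))
      } else {
        any(vapply(retained, function(r) identical(as.integer(s),
                                                   as.integer(r)), logical(1)))
      }
      if (!contained) keep[[length(keep) + 1L]] <- s
    }
    retained <- c(retained, keep)
    result[[paste0("L", L)]] <- keep
  }
  result
}

#' Permutation null of the maximal consensus length
#'
#' Empirical null distribution of the maximal order-conserved sequence
#' length when the k per-sample rankings are independent uniform random
#' permutations of n region labels. (Randomly permuting the region
#' labels of real rankings yields the same distribution, so uniform
#' permutations are drawn directly.) For each replicate the maximal
#' consensus length is recorded; `p_at[L]` is the raw tail proportion
#' of replicates with length >= L, and the significance threshold is
#' the smallest L with `p_at[L] < alpha` — an empirical
#' false-discovery-style cutoff. With n = 47 regions, k = 3 samples and
#' 10,000 replicates the tail proportion at length 8 is about 0.0269,
#' so 8 is the alpha = 0.05 threshold.
#'
#' @param n_regions number of region labels.
#' @param k_samples number of samples.
#' @param n_perm number of permutation replicates.
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return An object of class `null_distribution`: list with
#'   `max_lengths`, `p_at` (named numeric, lengths 1..n), and
#'   `threshold_length`, plus the generating parameters.
#' @export
permutation_null <- function(n_regions = 47L, k_samples = 3L,
                             n_perm = 10000L, alpha = 0.05, seed = 1L) {
  stopifnot(n_perm >= 1L, n_regions >= 1L, k_samples >= 1L)
  set.seed(seed)
  n <- as.integer(n_regions)
  k <- as.integer(k_samples)
  lens <- integer(n_perm)
  for (r in seq_len(n_perm)) {
    # relabel by sample 1's order: remaining samples are uniform
    # permutations; the consensus is the longest chain increasing in
    # every remaining sample's position simultaneously
    pos <- matrix(0L, max(k - 1L, 0L), n)
    for (s in seq_len(k - 1L)) pos[s, sample.int(n)] <- seq_len(n)
    if (k == 1L) { lens[r] <- n; next }
    dp <- integer(n)
    for (i in seq_len(n)) {
      best <- 0L
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        ok <- rep(TRUE, i - 1L)
        for (s in seq_len(k - 1L))
          ok <- ok & (pos[s, prev] < pos[s, i])
        if (any(ok)) best <- max(dp[prev[ok]])
      }
      dp[i] <- best + 1L
    }
    lens[r] <- max(dp)
  }
  p_at <- vapply(seq_len(n), function(L) mean(lens >= L), numeric(1))
  names(p_at) <- seq_len(n)
  below <- which(p_at < alpha)
  threshold <- if (length(below)) min(below) else NA_integer_
  structure(list(n_regions = n, k_samples = k, n_perm = as.integer(n_perm),
                 alpha = alpha, seed = seed, max_lengths = lens,
                 p_at = p_at, threshold_length = threshold),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("permutation null: n=%d regions, k=%d samples, %d replicates\n",
              x$n_regions, x$k_samples, x$n_perm))
  cat(sprintf("  alpha=%g threshold length: %s\n", x$alpha,
              x$threshold_length))
  if (!is.na(x$threshold_length))
    cat(sprintf("  P(length >= %d) = %.4f\n", x$threshold_length,
                x$p_at[x$threshold_length]))
  invisible(x)
}

#' Build the consensus network graph
#'
#' Nodes are the regions appearing in the retained consensus sequences;
#' each ordered adjacent pair within a sequence adds 1 to its directed
#' edge's adjacency count. Edge weight is the adjacency count plus 1,
#' and all weights are rescaled by a common factor so they sum to
#' `weight_total` (250 by default). Edges that never occur are not
#' materialised. Each node carries the rank of its mean regional
#' density (1 = densest) when densities are supplied.
#'
#' @param sequences list of integer id vectors (consensus sequences of
#'   one length, or any retained pattern set).
#' @param mean_density optional named numeric: mean regional density per
#'   id, used for the node rank attribute.
#' @param weight_total normalisation constant for the weight sum.
#' @return An object of class `consensus_graph`: list with `nodes`
#'   (data.frame `region_id`, `density_rank`), `edges` (data.frame
#'   `from`, `to`, `count`, `weight`), `weight_total`.
#' @export
build_graph <- function(sequences, mean_density = NULL, weight_total = 250) {
  if (!length(sequences)) stop("empty sequence list")
  from <- integer(0); to <- integer(0)
  for (s in sequences) {
    s <- as.integer(s)
    if (length(s) >= 2L) {
      from <- c(from, s[-length(s)])
      to <- c(to, s[-1L])
    }
  }
  if (!length(from)) stop("no adjacent pairs: all sequences have length < 2")
  key <- paste(from, to, sep = ">")
  cnt <- table(key)
  parts <- strsplit(names(cnt), ">", fixed = TRUE)
  edges <- data.frame(
    from = as.integer(vapply(parts, `[`, "", 1L)),
    to = as.integer(vapply(parts, `[`, "", 2L)),
    count = as.integer(cnt))
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  w <- edges$count + 1
  edges$weight <- w * (weight_total / sum(w))
  ids <- sort(unique(unlist(sequences)))
  rank <- rep(NA_integer_, length(ids))
  if (!is.null(mean_density)) {
    md <- mean_density[as.character(ids)]
    rank <- as.integer(rank(-md, ties.method = "first"))
  }
  structure(list(nodes = data.frame(region_id = ids, density_rank = rank),
                 edges = edges, weight_total = weight_total),
            class = "consensus_graph")
}

#' Convert a consensus graph to igraph
#' @param graph a `consensus_graph`.
#' @return an [igraph::igraph] directed graph with `weight` edge
#'   attribute and `density_rank` node attribute.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "consensus_graph"))
  igraph::graph_from_data_frame(
    data.frame(from = as.character(graph$edges$from),
               to = as.character(graph$edges$to),
               weight = graph$edges$weight),
    directed = TRUE,
    vertices = data.frame(name = as.character(graph$nodes$region_id),
                          density_rank = graph$nodes$density_rank))
}

#' Deterministic force-directed node layout
#'
#' Fruchterman–Reingold layout of the consensus graph under a fixed
#' seed; positions only, no rendering.
#'
#' @param graph a `consensus_graph` (an empty edge set is allowed via a
#'   graph with nodes only).
#' @param seed RNG seed.
#' @return numeric matrix (nodes x 2) of coordinates, rownames =
#'   region ids; a 0-row matrix for an empty graph.
#' @export
layout_graph <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "consensus_graph"))
  if (!nrow(graph$nodes))
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("x", "y"))))
  g <- as_igraph(graph)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  dimnames(xy) <- list(graph$nodes$region_id, c("x", "y"))
  xy
}
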