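#' Input orderings
#'
#' `order_by_decreasing_length()` sorts a sequence set by non-increasing
#' length, breaking ties by ascending id — the canonical input ordering for
#' greedy clustering, which wants long (information-rich) sequences to found
#' clusters. `order_by_name()` sorts lexicographically by description (falling
#' back to id), emulating pre-ordering a database by taxon name.
#'
#' @param seqs a [seq_set].
#' @return The reordered [seq_set].
#' @export
order_by_decreasing_length <- function(seqs) {
  seqs <- as_seq_set(seqs)
  len <- seq_lengths(seqs)
  seqs[order(-len, names(seqs), method = "radix")]
}

#' @rdname order_by_decreasing_length
#' @export
order_by_name <- function(seqs) {
  seqs <- as_seq_set(seqs)
  key <- seq_descriptions(seqs)
  key[!nzchar(key)] <- names(seqs)[!nzchar(key)]
  seqs[order(key, names(seqs), method = "radix")]
}

# how many representatives one vectorized alignment call scans before the
# greedy search checks for a first match; trades per-call overhead against
# a few extra counted alignments past the match
GC_SCAN_CHUNK <- 24L

#' Greedy clustering (GC)
#'
#' The single-pass scheme used by tools in the UCLUST/CD-HIT mould. The first
#' sequence of the input ordering founds the first cluster and becomes its
#' representative; each later sequence joins the first existing representative
#' (in representative-creation order) whose similarity is at least `t`, or
#' founds a new cluster. Every non-representative member therefore has
#' similarity `>= t` to its cluster's representative, and at most `N * m`
#' comparisons are performed for `m` final clusters. The caller chooses the
#' ordering (see [order_by_decreasing_length()]); `greedy_cluster()` consumes
#' its input as given.
#'
#' @param seqs a [seq_set], already ordered.
#' @param t similarity threshold in `[0, 1]`.
#' @param params a [similarity_params].
#' @param ledger a [comparison_ledger], updated in place.
#' @param best_match if `TRUE`, join the best-matching representative above
#'   `t` instead of the first (costs a full scan per sequence).
#' @return A [partition] whose representatives are the cluster founders.
#' @export
greedy_cluster <- function(seqs, t, params = similarity_params(),
                           ledger = comparison_ledger(), best_match = FALSE) {
  seqs <- as_seq_set(seqs)
  check_threshold(t)
  ids <- names(seqs)
  reps <- character(0)
  members <- list()
  for (id in ids) {
    chosen <- NA_integer_
    if (length(reps)) {
      if (best_match) {
        sims <- similarity_to_many(seqs, id, reps, params, ledger)
        if (any(sims >= t)) chosen <- which.max(sims)
      } else {
        for (start in seq(1L, length(reps), by = GC_SCAN_CHUNK)) {
          idx <- start:min(start + GC_SCAN_CHUNK - 1L, length(reps))
          sims <- similarity_to_many(seqs, id, reps[idx], params, ledger)
          hit <- which(sims >= t)
          if (length(hit)) { chosen <- idx[hit[[1L]]]; break }
        }
      }
    }
    if (is.na(chosen)) {
      reps <- c(reps, id)
      members[[length(members) + 1L]] <- id
    } else {
      members[[chosen]] <- c(members[[chosen]], id)
    }
  }
  partition(lapply(seq_along(reps), function(i)
    list(members = members[[i]], representative = reps[[i]])),
    ids = ids, algorithm = "gc", threshold = t)
}

#' Connected-component-based clustering (CCBC)
#'
#' Clusters are the connected components of the threshold graph: vertices are
#' sequences, edges join unordered pairs with similarity `>= t`. Components
#' are found by breadth-first search. When no similarity matrix is supplied,
#' the full half matrix is computed first (all N(N-1)/2 pairs — the f = 1
#' cost that motivates the multi-level algorithms). Each cluster's
#' representative is its almost-central member (see
#' [almost_central_representative()]), seeded by the cluster's first member
#' in input order; with the half matrix cached this costs no extra
#' alignments.
#'
#' @inheritParams greedy_cluster
#' @param precomputed optional symmetric similarity matrix (as from
#'   [half_matrix()]) covering all of `seqs`; no new comparisons are performed
#'   when it is supplied.
#' @param k subset size for the almost-central representative.
#' @return A [partition].
#' @export
ccbc_cluster <- function(seqs, t, params = similarity_params(),
                         ledger = comparison_ledger(), precomputed = NULL,
                         k = 10L) {
  seqs <- as_seq_set(seqs)
  check_threshold(t)
  ids <- names(seqs)
  n <- length(ids)
  if (n == 0L)
    return(partition(list(), ids = character(0),
                     algorithm = "ccbc", threshold = t))
  if (is.null(precomputed)) {
    precomputed <- half_matrix(seqs, params, ledger)
  } else {
    if (!all(ids %in% rownames(precomputed)))
      stop("precomputed matrix does not cover all sequence ids")
    precomputed <- precomputed[ids, ids, drop = FALSE]
  }
  comp <- integer(n)                      # 0 = unassigned
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    comp[s] <- ncomp
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(comp == 0L & precomputed[v, ] >= t)
      if (length(nb)) {
        comp[nb] <- ncomp
        queue <- c(queue, nb)
      }
    }
  }
  clusters <- lapply(seq_len(ncomp), function(ci) {
    mem <- ids[comp == ci]
    list(members = mem,
         representative = matrix_almost_central(precomputed, mem, mem[[1L]],
                                                k))
    })
  partition(clusters, ids = ids, algorithm = "ccbc", threshold = t)
}

# almost-central representative read off a similarity matrix: costs no
# alignments, since CCBC has the full (sub)matrix in hand anyway
matrix_almost_central <- function(m, members, seed, k) {
  n <- length(members)
  if (n == 1L) return(members)
  if (n > k) {
    ord <- members[order(-m[seed, members], members, method = "radix")]
    members <- ord[unique(floor((seq_len(k) - 1L) * n / k) + 1L)]
  }
  sub <- m[members, members, drop = FALSE]
  sums <- rowSums(sub) - diag(sub)
  sort(members[sums >= max(sums) - 1e-12])[[1L]]
}

#' Pre-order sequences by low-threshold greedy clustering
#'
#' Runs [greedy_cluster()] at a very low threshold on the length-ordered input
#' and emits the sequences grouped by low-threshold cluster: clusters in
#' creation order, each cluster's representative first, then members in
#' assignment order. Pre-clustering like this before MLC1 packs similar
#' sequences into the same blocks, shrinking the representative set the
#' expensive cross-block step must handle; its alignments land on the shared
#' ledger, so downstream f-values include the pre-clustering cost.
#'
#' @inheritParams greedy_cluster
#' @param low_t low pre-clustering threshold in `[0, 1]` (well below the
#'   clustering threshold; e.g. 0.05 for diverse protein families).
#' @return The reordered [seq_set].
#' @export
preorder_by_gc <- function(seqs, low_t, params = similarity_params(),
                           ledger = comparison_ledger()) {
  seqs <- order_by_decreasing_length(as_seq_set(seqs))
  check_threshold(low_t)
  part <- greedy_cluster(seqs, low_t, params, ledger)
  ord <- unlist(lapply(part$clusters, function(cl)
    c(cl$representative, setdiff(cl$members, cl$representative))),
    use.names = FALSE)
  seqs[ord]
}

check_threshold <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1)
    stop("threshold must be a single number in [0, 1]")
  invisible(t)
}
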