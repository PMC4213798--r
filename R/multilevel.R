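#' Multi-level clustering configuration
#'
#' Tuning knobs shared by MLC1, MLC and rMLC.
#'
#' @param block_size sequences per block in MLC1's Step 1. `NULL` (default)
#'   derives it from `block_fraction`; `0` disables blocking entirely, in
#'   which case MLC1 reduces to [ccbc_cluster()] (full matrix, f = 1).
#' @param block_fraction block size as a fraction of the input size when
#'   `block_size` is `NULL` (default 1/10, i.e. ten blocks).
#' @param k subset size for the almost-central representative (default 10,
#'   small enough that a k x k similarity matrix is negligible).
#' @param s group-size cutoff in MLC: groups smaller than `s` are finalized
#'   directly with MLC1 at the target threshold (default 300).
#' @param M size cutoff in rMLC: any intermediate set larger than `M` is
#'   clustered by a recursive rMLC call rather than by GC/CCBC directly
#'   (default 1000; must be `>= s`).
#' @param rep_mode how a group's representative is chosen: the greedy
#'   founder (`"first"`), the exact centre (`"central"`), or the
#'   almost-central heuristic (`"almost-central"`, default).
#' @return An object of class `"mlc_config"`.
#' @export
mlc_config <- function(block_size = NULL, block_fraction = 0.1,
                       k = 10L, s = 300L, M = 1000L,
                       rep_mode = c("almost-central", "central", "first")) {
  rep_mode <- match.arg(rep_mode)
  if (!is.null(block_size) && block_size < 0) stop("block_size must be >= 0")
  if (block_fraction <= 0 || block_fraction > 1)
    stop("block_fraction must be in (0, 1]")
  if (k < 1) stop("k must be >= 1")
  if (s < 1) stop("s must be >= 1")
  if (M < s) stop("M must be >= s")
  structure(list(block_size = block_size, block_fraction = block_fraction,
                 k = as.integer(k), s = as.integer(s), M = as.integer(M),
                 rep_mode = rep_mode),
            class = "mlc_config")
}

#' Threshold schedules
#'
#' An increasing sequence of thresholds `t1 < ... < tn` ending exactly at the
#' target threshold, driving the level iterations of [mlc()] and [rmlc()]:
#' coarse, cheap clustering first, refined at each level. The default rule
#' halves the remaining gap each step (`t[i+1] = t[i] + (t_final - t[i]) / 2`),
#' stops once the gap falls below 0.005, and appends the target. An explicit
#' list may be supplied instead and is validated.
#'
#' @param t_start starting threshold (`0 <= t_start <= t_final`).
#' @param t_final target threshold.
#' @param thresholds optional explicit schedule (overrides the rule; must be
#'   strictly increasing, within `[0, 1]`, ending at `t_final` if given too).
#' @return Numeric vector of class `"threshold_schedule"`.
#' @examples
#' threshold_schedule(0.95, 0.9861)
#' @export
threshold_schedule <- function(t_start, t_final = NULL, thresholds = NULL) {
  if (!is.null(thresholds)) {
    ts <- as.numeric(thresholds)
    if (length(ts) == 0L) stop("schedule must be non-empty")
    if (any(ts < 0 | ts > 1)) stop("thresholds must lie in [0, 1]")
    if (length(ts) > 1L && any(diff(ts) <= 0))
      stop("thresholds must be strictly increasing")
    if (!is.null(t_final) && ts[length(ts)] != t_final)
      stop("explicit schedule must end at the target threshold")
    return(structure(ts, class = "threshold_schedule"))
  }
  if (is.null(t_final)) stop("t_final is required")
  check_threshold(t_start); check_threshold(t_final)
  if (t_start > t_final) stop("t_start must not exceed t_final")
  ts <- numeric(0)
  cur <- t_start
  while (t_final - cur >= 0.005) {
    ts <- c(ts, cur)
    cur <- cur + (t_final - cur) / 2
  }
  structure(c(ts, t_final), class = "threshold_schedule")
}

as_schedule <- function(x) {
  if (inherits(x, "threshold_schedule")) return(x)
  threshold_schedule(thresholds = x)
}

#' Central and almost-central representatives
#'
#' The central sequence of a group maximizes the summed similarity to the
#' other members — the member most representative of the group's
#' distribution. Computing it exactly needs all within-group pairs, so for
#' large groups `almost_central_representative()` approximates it: members
#' are ranked by descending similarity to the group's greedy representative
#' `gc_rep` (ties by ascending id), `k` members are taken at evenly spaced
#' ranks across that ordering (always including rank 1), and the exact centre
#' of that k-subset is returned. For groups of at most `k` members the two
#' functions agree.
#'
#' @param seqs a [seq_set] holding exactly the group's members.
#' @param params a [similarity_params].
#' @param ledger a [comparison_ledger], updated in place.
#' @return A single member id.
#' @export
central_representative <- function(seqs, params = similarity_params(),
                                   ledger = comparison_ledger()) {
  seqs <- as_seq_set(seqs)
  if (length(seqs) == 0L) stop("group must be non-empty")
  if (length(seqs) == 1L) return(names(seqs))
  m <- half_matrix(seqs, params, ledger)
  sums <- rowSums(m) - 1     # drop the unit self-similarity
  ids <- names(seqs)
  best <- max(sums)
  sort(ids[sums >= best - 1e-12])[[1L]]
}

#' @rdname central_representative
#' @param gc_rep the group's current (greedy) representative id; rank-1 anchor
#'   of the subsample ordering.
#' @param k subset size (default 10).
#' @export
almost_central_representative <- function(seqs, gc_rep, k = 10L,
                                          params = similarity_params(),
                                          ledger = comparison_ledger()) {
  seqs <- as_seq_set(seqs)
  n <- length(seqs)
  if (n == 0L) stop("group must be non-empty")
  if (!gc_rep %in% names(seqs)) stop("gc_rep '", gc_rep, "' not in the group")
  if (n <= k) return(central_representative(seqs, params, ledger))
  sims <- similarity_to_many(seqs, gc_rep, names(seqs), params, ledger)
  ord <- names(seqs)[order(-sims, names(seqs), method = "radix")]
  ranks <- unique(floor((seq_len(k) - 1L) * n / k) + 1L)
  central_representative(seqs[ord[ranks]], params, ledger)
}

#' Partition an ordering into contiguous blocks
#'
#' Chunks a sequence set (or any vector) into consecutive blocks of
#' `block_size` elements; the last block may be smaller. Concatenating the
#' blocks reproduces the input order. `block_size = 0` is the degenerate
#' "no blocking" signal and yields a single block.
#'
#' @param x a [seq_set] or vector.
#' @param block_size non-negative integer.
#' @return List of blocks (subsets of `x`).
#' @export
partition_into_blocks <- function(x, block_size) {
  if (block_size < 0) stop("block_size must be >= 0")
  n <- length(x)
  if (n == 0L) return(list())
  if (block_size == 0L || block_size >= n) return(list(x))
  idx <- split(seq_len(n), ceiling(seq_len(n) / block_size))
  lapply(unname(idx), function(i) x[i])
}

# choose a group's representative after greedy clustering of a block
group_representative <- function(seqs, members, gc_rep, config, params,
                                 ledger) {
  if (length(members) == 1L) return(members)
  switch(config$rep_mode,
         "first" = gc_rep,
         "central" = central_representative(seqs[members], params, ledger),
         "almost-central" = almost_central_representative(
           seqs[members], gc_rep = gc_rep, k = config$k,
           params = params, ledger = ledger))
}

# representative for a merged final cluster: almost-central over the previous
# group representatives when the union is large (bounds cost at O(k^2)),
# else over all members; seeded by the largest constituent group's rep
merged_representative <- function(seqs, member_sets, group_reps, config,
                                  params, ledger) {
  members <- unlist(member_sets, use.names = FALSE)
  if (length(members) == 1L) return(members)
  sizes <- lengths(member_sets)
  seed <- group_reps[[which.max(sizes)]]
  pool <- if (length(members) > 10L * config$k) unique(group_reps) else members
  if (length(pool) == 1L) return(pool)
  almost_central_representative(seqs[pool], gc_rep = seed, k = config$k,
                                params = params, ledger = ledger)
}

#' MultiLevel Clustering with one level (MLC1)
#'
#' The one-level scheme all multi-level algorithms build on: (i) the ordered
#' input is cut into blocks; (ii) each block is clustered by greedy clustering
#' at threshold `t` and each resulting group gets a representative
#' (per `config$rep_mode`); (iii) the representatives of all blocks are
#' clustered by CCBC at `t`; (iv) each final cluster is the union of the
#' groups whose representatives landed in the same connected component, with
#' a fresh almost-central representative. Only representatives cross block
#' boundaries, so most of the N(N-1)/2 comparisons of a full matrix are never
#' performed. With `block_size = 0` blocking is disabled and the function
#' returns the CCBC clustering of the whole input (f = 1).
#'
#' @inheritParams greedy_cluster
#' @param config an [mlc_config].
#' @param ordering `"length"` (decreasing length; default), `"name"`
#'   (lexicographic by description), or `"given"` (input order, e.g. after
#'   [preorder_by_gc()]).
#' @param big_handler internal recursion hook used by [rmlc()]: a function
#'   `f(seqs, t)` returning a [partition], applied instead of GC/CCBC to any
#'   Step-1 block or Step-2 representative set larger than `config$M`.
#' @return A [partition].
#' @export
mlc1 <- function(seqs, t, config = mlc_config(),
                 params = similarity_params(),
                 ledger = comparison_ledger(),
                 ordering = c("length", "name", "given"),
                 big_handler = NULL) {
  seqs <- as_seq_set(seqs)
  check_threshold(t)
  ordering <- match.arg(ordering)
  n <- length(seqs)
  if (n == 0L)
    return(partition(list(), ids = character(0),
                     algorithm = "mlc1", threshold = t))
  seqs <- switch(ordering,
                 length = order_by_decreasing_length(seqs),
                 name = order_by_name(seqs),
                 given = seqs)
  bs <- if (!is.null(config$block_size)) config$block_size else
    max(1L, ceiling(n * config$block_fraction))
  if (bs == 0L) {
    res <- ccbc_cluster(seqs, t, params, ledger, k = config$k)
    res$algorithm <- "mlc1"
    return(res)
  }
  blocks <- partition_into_blocks(seqs, bs)

  # Step 1: cluster within blocks, pick one representative per group
  member_sets <- list(); gc_reps <- character(0); reps <- character(0)
  for (blk in blocks) {
    bp <- if (!is.null(big_handler) && length(blk) > config$M)
      big_handler(blk, t)
    else
      greedy_cluster(blk, t, params, ledger)
    for (cl in bp$clusters) {
      member_sets[[length(member_sets) + 1L]] <- cl$members
      gc_reps <- c(gc_reps, cl$representative)
      reps <- c(reps, group_representative(seqs, cl$members,
                                           cl$representative, config,
                                           params, ledger))
    }
  }

  # Step 2: cluster the representatives across blocks
  rep_seqs <- seqs[reps]
  rep_part <- if (!is.null(big_handler) && length(reps) > config$M &&
                  length(reps) < n)
    big_handler(rep_seqs, t)
  else
    ccbc_cluster(rep_seqs, t, params, ledger, k = config$k)

  # Step 3: regroup every sequence with its representative's component
  group_of_rep <- stats::setNames(seq_along(reps), reps)
  clusters <- lapply(rep_part$clusters, function(rc) {
    gidx <- sort(unname(group_of_rep[rc$members]))
    msets <- member_sets[gidx]
    # a component holding a single group keeps the representative that
    # rep_mode just chose for exactly this member set; only genuine merges
    # warrant recomputation
    rep_id <- if (length(gidx) == 1L) reps[gidx] else
      merged_representative(seqs, msets, reps[gidx], config, params, ledger)
    mem <- unlist(msets, use.names = FALSE)
    list(members = c(rep_id, setdiff(mem, rep_id)), representative = rep_id)
  })
  # number clusters by first member appearance in the input ordering
  pos <- stats::setNames(seq_len(n), names(seqs))
  first_pos <- vapply(clusters, function(cl) min(pos[cl$members]), numeric(1))
  partition(clusters[order(first_pos)], ids = names(seqs),
            algorithm = "mlc1", threshold = t)
}

#' MultiLevel Clustering (MLC) and its recursive form (rMLC)
#'
#' `mlc()` iterates [mlc1()] over an increasing [threshold_schedule()]: one
#' group (the whole dataset) enters level 1; at level `i`, any group smaller
#' than `config$s` is finalized by MLC1 at the target threshold, while larger
#' groups are clustered by MLC1 at the level threshold `t[i]` and their
#' subgroups passed on; groups surviving the last level are finalized at the
#' target threshold. Because early levels are coarse, groups shrink quickly
#' and the expensive high-threshold work only ever sees small sets — MLC
#' avoids more comparisons than MLC1 while clustering at the same final
#' threshold.
#'
#' `rmlc()` behaves exactly like `mlc()` for inputs of at most `config$M`
#' sequences. Above that, wherever MLC1 would hand a set larger than `M` to
#' GC or CCBC (a Step-1 block or the Step-2 representative set), rMLC is
#' applied recursively to that set instead, with a schedule re-derived by the
#' gap-halving rule from the current level's threshold; each recursive call
#' receives a strictly smaller set, so the recursion is finite. All batches
#' respect the ledger's `batch_limit`, which bounds peak memory.
#'
#' When a group is re-clustered at the next level, its sequences are
#' presented with the group representative first (the greedy seed), then the
#' remaining members.
#'
#' @inheritParams mlc1
#' @param schedule a [threshold_schedule()] (or numeric vector of strictly
#'   increasing thresholds); the last element is the target threshold.
#' @return A [partition] at the target threshold.
#' @export
mlc <- function(seqs, schedule, config = mlc_config(),
                params = similarity_params(),
                ledger = comparison_ledger(),
                ordering = c("length", "name", "given")) {
  mlc_engine(seqs, schedule, config, params, ledger, match.arg(ordering),
             recursive = FALSE)
}

#' @rdname mlc
#' @export
rmlc <- function(seqs, schedule, config = mlc_config(),
                 params = similarity_params(),
                 ledger = comparison_ledger(),
                 ordering = c("length", "name", "given")) {
  seqs <- as_seq_set(seqs)
  res <- if (length(seqs) <= config$M)
    mlc_engine(seqs, schedule, config, params, ledger, match.arg(ordering),
               recursive = FALSE)
  else
    mlc_engine(seqs, schedule, config, params, ledger, match.arg(ordering),
               recursive = TRUE)
  res$algorithm <- "rmlc"
  res
}

mlc_engine <- function(seqs, schedule, config, params, ledger, ordering,
                       recursive) {
  seqs <- as_seq_set(seqs)
  schedule <- as_schedule(schedule)
  t_final <- schedule[length(schedule)]
  n <- length(seqs)
  if (n == 0L)
    return(partition(list(), ids = character(0),
                     algorithm = "mlc", threshold = t_final))
  seqs <- switch(ordering,
                 length = order_by_decreasing_length(seqs),
                 name = order_by_name(seqs),
                 given = seqs)

  sub_mlc1 <- function(group_ids, tt, level_start) {
    handler <- if (recursive)
      function(sub_seqs, t_sub)
        rmlc(sub_seqs, threshold_schedule(min(level_start, t_sub), t_sub),
             config, params, ledger, ordering = "given")
    else NULL
    mlc1(seqs[group_ids], tt, config, params, ledger, ordering = "given",
         big_handler = handler)
  }

  # each group: members in presentation order (representative first)
  groups <- list(list(members = names(seqs)))
  final <- list()
  for (li in seq_along(schedule)) {
    t_i <- schedule[li]
    level_start <- schedule[max(1L, li - 1L)]
    nxt <- list()
    for (g in groups) {
      if (length(g$members) < config$s) {
        fp <- sub_mlc1(g$members, t_final, level_start)
        final <- c(final, fp$clusters)
      } else {
        sp <- sub_mlc1(g$members, t_i, level_start)
        for (cl in sp$clusters)
          nxt[[length(nxt) + 1L]] <-
            list(members = c(cl$representative,
                             setdiff(cl$members, cl$representative)))
      }
    }
    groups <- nxt
    if (length(groups) == 0L) break
  }
  for (g in groups) {
    fp <- sub_mlc1(g$members, t_final, schedule[length(schedule)])
    final <- c(final, fp$clusters)
  }
  pos <- stats::setNames(seq_len(n), names(seqs))
  first_pos <- vapply(final, function(cl) min(pos[cl$members]), numeric(1))
  clusters <- lapply(final[order(first_pos)], function(cl)
    list(members = cl$members, representative = cl$representative))
  partition(clusters, ids = names(seqs), algorithm = "mlc",
            threshold = t_final)
}
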