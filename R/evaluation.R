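#' Clustering F-measure
#'
#' Compares a computed partition `K = (K1, ..., Km)` against a reference
#' standard partition `C = (C1, ..., Cl)` of the same sequences. Each
#' reference class is matched with the predicted cluster maximizing the
#' harmonic mean of precision and recall, and the matches are averaged
#' weighted by class size:
#' \deqn{F(K, C) = \frac{1}{n} \sum_j n^j \max_i \frac{2 n_i^j}{n_i + n^j}}
#' where `n` is the dataset size, `n_i = |K_i|`, `n^j = |C_j|` and
#' `n_i^j = |K_i \cap C_j|`. The value lies in `[0, 1]`, equals 1 exactly
#' when the clustering reproduces the reference up to relabeling, and is
#' invariant under cluster renumbering.
#'
#' @param K a [partition] (or named membership vector).
#' @param C a [reference_partition] (or [partition], or named label vector)
#'   covering the same id set.
#' @return F-measure in `[0, 1]`.
#' @examples
#' ref <- reference_partition(c(a = "x", b = "x", c = "y", d = "y"))
#' K <- partition(list(list(members = c("a", "b", "c", "d"))))
#' f_measure(K, ref)   # 2/3
#' @export
f_measure <- function(K, C) {
  k_lab <- partition_labels(K)
  c_lab <- partition_labels(C)
  if (!setequal(names(k_lab), names(c_lab)))
    stop("partition and reference cover different id sets")
  ids <- names(c_lab)
  n <- length(ids)
  if (n == 0L) stop("cannot evaluate an empty partition")
  tab <- table(k = k_lab[ids], c = c_lab[ids])
  n_i <- rowSums(tab)
  n_j <- colSums(tab)
  hm <- 2 * tab / outer(n_i, n_j, `+`)     # harmonic mean of precision/recall
  sum(n_j * apply(hm, 2L, max)) / n
}

partition_labels <- function(x) {
  if (inherits(x, "partition")) return(membership(x))
  if (inherits(x, "reference_partition"))
    return(stats::setNames(as.character(unclass(x)), names(x)))
  if ((is.character(x) || is.numeric(x)) && !is.null(names(x)))
    return(stats::setNames(as.character(x), names(x)))
  stop("expected a partition, reference_partition or named label vector")
}

#' f-value: comparison-cost fraction
#'
#' The cost of a clustering run measured as the number of pairwise alignments
#' performed divided by the `N(N-1)/2` alignments of a full half similarity
#' matrix. Algorithms that require the full matrix (CCBC on a cold cache)
#' have f = 1; the multi-level algorithms aim for f well below 1. When a run
#' includes pre-ordering (e.g. [preorder_by_gc()]), performing it on the same
#' ledger makes the f-value include that cost.
#'
#' @param ledger a [comparison_ledger] after the run (or a plain comparison
#'   count).
#' @param n dataset size (N >= 2).
#' @return Non-negative real.
#' @export
f_value <- function(ledger, n) {
  count <- if (inherits(ledger, "comparison_ledger")) ledger_count(ledger)
  else as.numeric(ledger)
  if (n < 2) stop("f-value requires at least two sequences")
  count / (n * (n - 1) / 2)
}

#' Run one clustering algorithm by name
#'
#' Shared dispatcher behind the threshold scan and the command-line
#' interface.
#'
#' @inheritParams mlc1
#' @param algorithm one of `"gc"`, `"ccbc"`, `"mlc1"`, `"mlc"`, `"rmlc"`.
#' @param t target threshold.
#' @param start_threshold schedule start for `mlc`/`rmlc` (default: the
#'   target threshold itself, i.e. a single-level schedule).
#' @param schedule optional explicit [threshold_schedule()] for `mlc`/`rmlc`
#'   (overrides `start_threshold`).
#' @param best_match passed to [greedy_cluster()].
#' @return A [partition].
#' @export
run_algorithm <- function(seqs, algorithm, t,
                          config = mlc_config(),
                          params = similarity_params(),
                          ledger = comparison_ledger(),
                          ordering = c("length", "name", "given"),
                          start_threshold = NULL, schedule = NULL,
                          best_match = FALSE) {
  ordering <- match.arg(ordering)
  seqs <- as_seq_set(seqs)
  ord_seqs <- switch(ordering,
                     length = order_by_decreasing_length(seqs),
                     name = order_by_name(seqs),
                     given = seqs)
  algorithm <- match.arg(algorithm, c("gc", "ccbc", "mlc1", "mlc", "rmlc"))
  if (algorithm %in% c("mlc", "rmlc")) {
    if (is.null(schedule)) {
      start <- if (is.null(start_threshold)) t else min(start_threshold, t)
      schedule <- threshold_schedule(start, t)
    } else {
      schedule <- as_schedule(schedule)
      if (schedule[length(schedule)] != t)
        stop("schedule must end at the requested threshold")
    }
  }
  switch(algorithm,
         gc = greedy_cluster(ord_seqs, t, params, ledger,
                             best_match = best_match),
         ccbc = ccbc_cluster(ord_seqs, t, params, ledger, k = config$k),
         mlc1 = mlc1(ord_seqs, t, config, params, ledger, ordering = "given"),
         mlc = mlc(ord_seqs, schedule, config, params, ledger,
                   ordering = "given"),
         rmlc = rmlc(ord_seqs, schedule, config, params, ledger,
                     ordering = "given"))
}

#' Optimal-threshold scan
#'
#' Clusters the dataset at every threshold of a grid, evaluates each result
#' against a reference partition, and reports the threshold with the highest
#' F-measure (ties broken toward the lowest threshold, favouring coarser
#' clusterings). Each threshold is run on a fresh comparison ledger so its
#' f-value reflects that run alone. Note that for MLC1/MLC the optimum
#' depends on the block size, schedule and input ordering, so the
#' configuration is recorded with the result.
#'
#' @inheritParams run_algorithm
#' @param reference a [reference_partition] covering `seqs`.
#' @param grid numeric vector of thresholds in `[0, 1]` (e.g.
#'   `seq(0, 1, by = 0.01)`).
#' @param batch_limit ledger batch limit for each run.
#' @return An object of class `"threshold_scan"`: a list with
#'   `optimal_threshold`, `best_f_measure`, the per-threshold `table`
#'   (threshold, f_measure, f_value, comparisons, groups) and the scan
#'   settings.
#' @export
optimal_threshold_scan <- function(seqs, reference, grid,
                                   algorithm = "ccbc",
                                   config = mlc_config(),
                                   params = similarity_params(),
                                   ordering = c("length", "name", "given"),
                                   start_threshold = NULL,
                                   batch_limit = 1e6) {
  seqs <- as_seq_set(seqs)
  ordering <- match.arg(ordering)
  if (length(grid) == 0L) stop("threshold grid must be non-empty")
  if (any(grid < 0 | grid > 1)) stop("grid thresholds must lie in [0, 1]")
  grid <- sort(unique(as.numeric(grid)))
  n <- length(seqs)
  rows <- lapply(grid, function(t) {
    led <- comparison_ledger(batch_limit = batch_limit)
    part <- run_algorithm(seqs, algorithm, t, config, params, led,
                          ordering = ordering,
                          start_threshold = start_threshold)
    data.frame(threshold = t,
               f_measure = f_measure(part, reference),
               f_value = if (n >= 2) f_value(led, n) else NA_real_,
               comparisons = ledger_count(led),
               groups = n_clusters(part))
  })
  tab <- do.call(rbind, rows)
  best <- which(tab$f_measure >= max(tab$f_measure) - 1e-12)[[1L]]
  structure(list(optimal_threshold = tab$threshold[best],
                 best_f_measure = tab$f_measure[best],
                 table = tab,
                 algorithm = algorithm,
                 config = config,
                 ordering = ordering,
                 start_threshold = start_threshold),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("threshold scan (%s): optimal t = %.4f, best F-measure = %.4f\n",
              x$algorithm, x$optimal_threshold, x$best_f_measure))
  print(utils::head(x$table, 15L), row.names = FALSE)
  if (nrow(x$table) > 15L) cat("...\n")
  invisible(x)
}
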