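#' Cluster partitions
#'
#' Every clustering algorithm in `mlclust` returns a `partition`: a list of
#' clusters, each holding a non-empty set of member ids and one member
#' designated as the cluster's representative. The clusters are pairwise
#' disjoint and together cover the dataset exactly. Clusters are numbered in
#' order of first member appearance in the input ordering.
#'
#' @param clusters list of clusters; each a list with elements `members`
#'   (character vector of ids) and `representative` (one member id).
#' @param ids character vector of all dataset ids covered by the partition.
#' @param algorithm,threshold optional provenance recorded on the object.
#' @return An object of class `"partition"`.
#' @export
partition <- function(clusters, ids = NULL,
                      algorithm = NA_character_, threshold = NA_real_) {
  clusters <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    if (is.null(cl$members) || length(cl$members) == 0L)
      stop("cluster ", i, " has no members")
    if (is.null(cl$representative)) cl$representative <- cl$members[[1L]]
    if (!cl$representative %in% cl$members)
      stop("cluster ", i, " representative not among its members")
    list(cluster_id = i, members = as.character(cl$members),
         representative = as.character(cl$representative))
  })
  all_members <- unlist(lapply(clusters, `[[`, "members"), use.names = FALSE)
  if (anyDuplicated(all_members))
    stop("clusters overlap: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  if (is.null(ids)) ids <- all_members
  if (!setequal(ids, all_members))
    stop("clusters do not cover the dataset exactly")
  structure(list(clusters = clusters, ids = as.character(ids),
                 algorithm = algorithm, threshold = threshold),
            class = "partition")
}

#' @rdname partition
#' @param x a `partition`.
#' @export
n_clusters <- function(x) {
  stopifnot(inherits(x, "partition"))
  length(x$clusters)
}

#' @rdname partition
#' @return `membership()` returns a named integer vector mapping each id to
#'   its cluster number.
#' @export
membership <- function(x) {
  stopifnot(inherits(x, "partition"))
  mem <- unlist(lapply(x$clusters, function(cl)
    stats::setNames(rep.int(cl$cluster_id, length(cl$members)), cl$members)))
  if (is.null(mem)) mem <- stats::setNames(integer(0), character(0))
  mem
}

#' @rdname partition
#' @export
representatives <- function(x) {
  stopifnot(inherits(x, "partition"))
  vapply(x$clusters, `[[`, character(1), "representative")
}

#' @export
print.partition <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), integer(1))
  cat(sprintf("partition: %d sequence(s) in %d cluster(s)%s\n",
              length(x$ids), length(x$clusters),
              if (!is.na(x$algorithm))
                sprintf(" [%s, t = %s]", x$algorithm, format(x$threshold))
              else ""))
  if (length(sizes))
    cat("  cluster sizes:", paste(utils::head(sort(sizes, decreasing = TRUE),
                                              10L), collapse = ", "),
        if (length(sizes) > 10L) "..." else "", "\n")
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.partition <- function(x, ...) {
  rows <- lapply(x$clusters, function(cl)
    data.frame(sequence_id = cl$members,
               cluster_id = cl$cluster_id,
               representative_id = cl$representative,
               stringsAsFactors = FALSE))
  df <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(sequence_id = character(0), cluster_id = integer(0),
               representative_id = character(0))
  df$algorithm <- x$algorithm
  df$threshold <- x$threshold
  df
}

# check invariants; used by tests and defensive callers
validate_partition <- function(x, ids = NULL) {
  stopifnot(inherits(x, "partition"))
  mem <- unlist(lapply(x$clusters, `[[`, "members"), use.names = FALSE)
  if (anyDuplicated(mem)) stop("partition clusters overlap")
  if (!setequal(mem, x$ids)) stop("partition does not cover its id set")
  if (!is.null(ids) && !setequal(x$ids, ids))
    stop("partition id set does not match the dataset")
  for (cl in x$clusters)
    if (!cl$representative %in% cl$members)
      stop("representative outside cluster ", cl$cluster_id)
  invisible(TRUE)
}

#' Two partitions are equivalent when they induce the same grouping,
#' regardless of cluster numbering or representative choice.
#' @rdname partition
#' @param y a second `partition`.
#' @export
same_grouping <- function(x, y) {
  mx <- membership(x); my <- membership(y)
  if (!setequal(names(mx), names(my))) return(FALSE)
  ids <- names(mx)
  key <- function(m) {
    g <- split(ids, m[ids])
    sort(vapply(g, function(v) paste(sort(v), collapse = "\r"), character(1)))
  }
  identical(key(mx), key(my))
}

#' Reference partitions
#'
#' A reference (gold-standard) partition maps every sequence id to exactly one
#' cluster label. `read_reference()` reads the two-column tab-separated format
#' `sequence-id<TAB>label` (a header line is skipped when its first field is
#' `id`, `sequence_id` or `sequence-id`, case-insensitively);
#' `write_reference()` writes it.
#'
#' @param labels named character vector: `labels[id] = cluster label`; or a
#'   two-column data.frame (id, label).
#' @return `reference_partition()` returns a named character vector of class
#'   `"reference_partition"`.
#' @export
reference_partition <- function(labels) {
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2L) stop("need two columns: id, label")
    labels <- stats::setNames(as.character(labels[[2L]]),
                              as.character(labels[[1L]]))
  }
  labels <- stats::setNames(as.character(labels), names(labels))
  if (length(labels) && (is.null(names(labels)) || any(!nzchar(names(labels)))))
    stop("every label must be named by a sequence id")
  if (anyDuplicated(names(labels)))
    stop("duplicate id(s) in reference: ",
         paste(unique(names(labels)[duplicated(names(labels))]), collapse = ", "))
  structure(labels, class = "reference_partition")
}

#' @rdname reference_partition
#' @param path file path.
#' @export
read_reference <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(reference_partition(stats::setNames(character(0), character(0))))
  if (grepl("^(id|sequence[-_]?id)\t", lines[[1L]], ignore.case = TRUE))
    lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad))
    stop("malformed reference table at line ", bad[[1L]],
         ": expected two tab-separated columns")
  reference_partition(stats::setNames(
    vapply(parts, `[[`, character(1), 2L),
    vapply(parts, `[[`, character(1), 1L)))
}

#' @rdname reference_partition
#' @param ref a `reference_partition`.
#' @export
write_reference <- function(ref, path) {
  utils::write.table(
    data.frame(sequence_id = names(ref), label = as.character(unclass(ref))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# coerce a reference to a partition (for F-measure symmetry etc.)
as_partition <- function(x) {
  if (inherits(x, "partition")) return(x)
  if (inherits(x, "reference_partition") ||
      (is.character(x) && !is.null(names(x)))) {
    groups <- split(names(x), as.character(unclass(x)))
    return(partition(lapply(unname(groups), function(g)
      list(members = g, representative = g[[1L]]))))
  }
  stop("cannot interpret object as a partition")
}

#' Write a cluster table
#'
#' Serializes a partition as a tab-separated table with columns
#' `sequence_id`, `cluster_id`, `representative_id`,
#' `similarity_to_representative`, `algorithm`, `threshold`. The similarity
#' column is filled from the supplied sequences and parameters (cache hits
#' when the clustering just ran on the same ledger) or left `NA`.
#'
#' @param part a [partition].
#' @param path output file path.
#' @param seqs,params,ledger optionally recompute each member's similarity to
#'   its cluster representative.
#' @export
write_clusters <- function(part, path, seqs = NULL,
                           params = similarity_params(),
                           ledger = comparison_ledger()) {
  df <- as.data.frame(part)
  df$similarity_to_representative <- NA_real_
  if (!is.null(seqs) && nrow(df)) {
    seqs <- as_seq_set(seqs)
    for (cl in part$clusters) {
      sims <- similarity_to_many(seqs, cl$representative, cl$members,
                                 params, ledger)
      df$similarity_to_representative[match(cl$members, df$sequence_id)] <- sims
    }
  }
  df <- df[, c("sequence_id", "cluster_id", "representative_id",
               "similarity_to_representative", "algorithm", "threshold")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
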