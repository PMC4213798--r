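#' Pairwise similarity parameters
#'
#' Bundles the scoring scheme used to compute percent identity between two
#' sequences. The defaults mirror common BLAST-style settings: for DNA,
#' match +1 / mismatch -2 with affine gap penalties 5 (open) and 2 (extend);
#' for protein, BLOSUM62 with gap penalties 11/1. Percent identity is the
#' number of identical, unambiguous columns divided by the total number of
#' alignment columns (gap columns included); ambiguity codes (N, X, ...)
#' never count as identities.
#'
#' The default alignment scope is global (Needleman-Wunsch). Local
#' (Smith-Waterman) scoring is available, but its identity is computed on
#' the clipped optimal region only: for divergent pairs the optimal local
#' alignment collapses to a short near-perfect window whose identity
#' approaches 1 regardless of overall homology, which makes local identity
#' unsafe as the edge criterion of transitive (connected-component)
#' clustering. Global identity is monotone in whole-sequence homology and is
#' what the clustering thresholds here refer to. Because absolute identity
#' values depend on all of these settings, thresholds tuned under one
#' parameter set are not portable to another.
#'
#' @param mode `"dna"` or `"protein"`; selects alphabet and default scoring.
#' @param match,mismatch integer match/mismatch scores (DNA mode; ignored when
#'   a substitution matrix is used).
#' @param gap_open,gap_extend non-negative gap penalties (subtracted from the
#'   alignment score).
#' @param scope `"global"` (default) or `"local"` alignment.
#' @param substitution_matrix optional numeric substitution matrix (defaults
#'   to BLOSUM62 in protein mode, match/mismatch matrix in DNA mode).
#' @param sim_fun optional replacement similarity backend: a function
#'   `f(a, b)` taking one residue string `a` and a character vector `b`,
#'   returning a numeric vector of similarities in `[0, 1]`. The clustering
#'   algorithms are agnostic to how pairwise similarity is computed; this hook
#'   lets any measure drive them (with the ledger still counting every pair
#'   evaluated).
#' @return An object of class `"similarity_params"`.
#' @examples
#' p <- similarity_params("dna")
#' @export
similarity_params <- function(mode = c("dna", "protein"),
                              match = 1L, mismatch = -2L,
                              gap_open = NULL, gap_extend = NULL,
                              scope = c("global", "local"),
                              substitution_matrix = NULL,
                              sim_fun = NULL) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (is.null(gap_open)) gap_open <- if (mode == "dna") 5 else 11
  if (is.null(gap_extend)) gap_extend <- if (mode == "dna") 2 else 1
  gap_open <- abs(gap_open); gap_extend <- abs(gap_extend)
  if (is.null(substitution_matrix)) {
    if (mode == "dna") {
      letters <- c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V")
      m <- matrix(as.numeric(mismatch), length(letters), length(letters),
                  dimnames = list(letters, letters))
      for (ch in c("A", "C", "G", "T", "U")) m[ch, ch] <- as.numeric(match)
      # N and other ambiguity codes score as mismatches even against
      # themselves (conservative, deterministic)
      substitution_matrix <- m
    } else {
      substitution_matrix <- get_blosum62()
    }
  }
  structure(list(mode = mode, match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 scope = scope, substitution_matrix = substitution_matrix,
                 sim_fun = sim_fun),
            class = "similarity_params")
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Comparison ledger
#'
#' A mutable record of every distinct pairwise alignment performed during a
#' clustering run. The count is the numerator of the f-value cost metric
#' (comparisons performed divided by the N(N-1)/2 comparisons of a full half
#' matrix). An optional cache stores each unordered pair's similarity so a
#' pair is aligned (and counted) at most once while its entry is live; batch
#' computation never evaluates more than `batch_limit` uncached pairs per
#' alignment call.
#'
#' @param cache keep a pair -> similarity cache (default `TRUE`).
#' @param batch_limit maximum number of uncached pairs evaluated per batch.
#' @return An object of class `"comparison_ledger"` (environment-backed, so
#'   it is updated in place by the clustering functions).
#' @examples
#' led <- comparison_ledger()
#' ledger_count(led)
#' @export
comparison_ledger <- function(cache = TRUE, batch_limit = 1e6) {
  stopifnot(batch_limit >= 1)
  env <- new.env(parent = emptyenv())
  env$comparisons <- 0
  env$cache <- if (isTRUE(cache)) new.env(parent = emptyenv()) else NULL
  env$batch_limit <- as.numeric(batch_limit)
  class(env) <- "comparison_ledger"
  env
}

#' @rdname comparison_ledger
#' @param ledger a `comparison_ledger`.
#' @export
ledger_count <- function(ledger) {
  stopifnot(inherits(ledger, "comparison_ledger"))
  ledger$comparisons
}

#' @rdname comparison_ledger
#' @export
ledger_reset <- function(ledger) {
  stopifnot(inherits(ledger, "comparison_ledger"))
  ledger$comparisons <- 0
  if (!is.null(ledger$cache)) ledger$cache <- new.env(parent = emptyenv())
  invisible(ledger)
}

#' @export
print.comparison_ledger <- function(x, ...) {
  cat("comparison_ledger:", format(x$comparisons, big.mark = ","),
      "pairwise comparison(s)",
      if (is.null(x$cache)) "(cache off)" else
        paste0("(", length(ls(x$cache)), " cached)"), "\n")
  invisible(x)
}

pair_key <- function(id_a, id_b) {
  swap <- id_a > id_b
  lo <- ifelse(swap, id_b, id_a)
  hi <- ifelse(swap, id_a, id_b)
  paste(lo, hi, sep = "\r")
}

# Align one sequence against many and return identities; no ledger/cache.
align_identity <- function(a, bs, params) {
  if (length(bs) == 0L) return(numeric(0))
  if (!is.null(params$sim_fun)) {
    sims <- as.numeric(params$sim_fun(a, bs))
    if (length(sims) != length(bs))
      stop("sim_fun must return one similarity per pair")
    if (any(sims < 0 | sims > 1)) stop("sim_fun similarities must lie in [0,1]")
    return(sims)
  }
  type <- if (params$scope == "local") "local" else "global"
  if (params$mode == "dna") {
    subj <- Biostrings::DNAString(chartr("U.", "T-", a))
    pats <- Biostrings::DNAStringSet(chartr("U.", "T-", bs))
    mat <- params$substitution_matrix
    rn <- intersect(rownames(mat), setdiff(rownames(mat), "U"))
    mat <- mat[rn, rn]
  } else {
    subj <- Biostrings::AAString(a)
    pats <- Biostrings::AAStringSet(bs)
    mat <- params$substitution_matrix
  }
  aln <- Biostrings::pairwiseAlignment(
    pats, subj, type = type, substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  paired <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  cols <- if (type == "global") {
    # every residue of both sequences occupies a column
    nchar(bs) + nchar(a) - paired
  } else {
    ind <- Biostrings::nindel(aln)
    paired + Biostrings::insertion(ind)[, "WidthSum"] +
      Biostrings::deletion(ind)[, "WidthSum"]
  }
  matches <- Biostrings::nmatch(aln)
  # nmatch counts raw character equality; ambiguity codes (N, X, ...) must
  # not count as identities, so recount those pairs from the aligned strings
  ambig <- grepl(ambiguity_regex(params$mode), bs) |
    grepl(ambiguity_regex(params$mode), a)
  if (any(ambig)) {
    keep <- unambiguous_chars(params$mode)
    ap <- as.character(Biostrings::alignedPattern(aln[ambig]))
    sp <- as.character(Biostrings::alignedSubject(aln[ambig]))
    matches[ambig] <- vapply(seq_along(ap), function(i) {
      pc <- strsplit(ap[i], "")[[1]]
      sc <- strsplit(sp[i], "")[[1]]
      sum(pc == sc & pc %in% keep)
    }, numeric(1))
    if (type == "global")
      cols[ambig] <- nchar(ap)
  }
  ifelse(cols > 0, matches / cols, 0)
}

ambiguity_regex <- function(mode) {
  if (mode == "dna") "[^ACGTU]" else "[^ACDEFGHIKLMNPQRSTVWY]"
}

# Similarity of sequence `id_a` to each of `ids_b` within seq_set `seqs`,
# honouring the ledger cache and batch limit. The workhorse behind every
# clustering operation.
similarity_to_many <- function(seqs, id_a, ids_b, params, ledger) {
  n <- length(ids_b)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  keys <- pair_key(rep_len(id_a, n), ids_b)
  self <- ids_b == id_a
  out[self] <- 1
  todo <- which(!self)
  if (!is.null(ledger$cache) && length(todo)) {
    cached <- lapply(keys[todo], get0, envir = ledger$cache, inherits = FALSE)
    hit <- !vapply(cached, is.null, logical(1))
    if (any(hit)) {
      out[todo[hit]] <- unlist(cached[hit])
      todo <- todo[!hit]
    }
  }
  if (length(todo)) {
    a_res <- unclass(seqs)[[id_a]]
    b_res <- unname(unclass(seqs)[ids_b[todo]])
    lim <- max(1, ledger$batch_limit)
    for (chunk in split(seq_along(todo), ceiling(seq_along(todo) / lim))) {
      idx <- todo[chunk]
      sims <- align_identity(a_res, b_res[chunk], params)
      out[idx] <- sims
      ledger$comparisons <- ledger$comparisons + length(idx)
      if (!is.null(ledger$cache))
        for (j in seq_along(idx))
          assign(keys[idx[j]], sims[j], envir = ledger$cache)
    }
  }
  out
}

#' Percent identity between two sequences
#'
#' Aligns two sequences under `params` and returns the fraction of alignment
#' columns whose residues are identical (and unambiguous), counting gap
#' columns in the denominator. The result is symmetric in its arguments and
#' lies in `[0, 1]`; it is 1 exactly when an alignment with no mismatches and
#' no gap columns exists. A cache miss increments `ledger` by one; a cached
#' pair costs nothing.
#'
#' @param a,b single sequences: length-1 named character vectors (or
#'   length-1 [seq_set]s). Unnamed plain strings are keyed by their content.
#' @param params a [similarity_params] object.
#' @param ledger a [comparison_ledger]; created fresh (and discarded) when
#'   omitted.
#' @return Similarity in `[0, 1]`.
#' @examples
#' percent_identity(c(a = "ACGTACGTAC"), c(b = "ACGTTCGTAC"))
#' @export
percent_identity <- function(a, b, params = similarity_params(),
                             ledger = comparison_ledger()) {
  as_one <- function(x, default_id) {
    if (inherits(x, "seq_set")) {
      if (length(x) != 1L) stop("expected a single sequence")
      return(x)
    }
    id <- names(x)
    x <- as.character(x)
    if (length(x) != 1L) stop("expected a single sequence")
    if (is.null(id) || !nzchar(id)) id <- toupper(x)
    seq_set(stats::setNames(toupper(x), id))
  }
  a <- as_one(a); b <- as_one(b)
  if (is.null(params$sim_fun)) {
    check_alphabet(a, params$mode)
    check_alphabet(b, params$mode)
  }
  both <- if (names(a) == names(b)) a else
    seq_set(c(unclass(a), unclass(b)),
            descriptions = c(seq_descriptions(a), seq_descriptions(b)))
  similarity_to_many(both, names(a), names(b), params, ledger)[1L]
}

#' Half pairwise-similarity matrix
#'
#' Computes the similarity of every unordered pair of sequences, the quantity
#' whose cost (N(N-1)/2 alignments on a cold cache) is the denominator of the
#' f-value. Pairs are evaluated in batches of at most `ledger$batch_limit`
#' uncached alignments; batching never changes the result.
#'
#' @param seqs a [seq_set] (N >= 1, unique ids).
#' @inheritParams percent_identity
#' @return A symmetric N x N numeric matrix with unit diagonal and sequence
#'   ids as dimnames.
#' @examples
#' s <- seq_set(c(a = "ACGTACGTACGT", b = "ACGTTCGTACGT", c = "TTTTGGGGCCCC"))
#' half_matrix(s)
#' @export
half_matrix <- function(seqs, params = similarity_params(),
                        ledger = comparison_ledger()) {
  seqs <- as_seq_set(seqs)
  if (length(seqs) < 1L) stop("need at least one sequence")
  if (is.null(params$sim_fun)) check_alphabet(seqs, params$mode)
  ids <- names(seqs)
  n <- length(ids)
  m <- matrix(if (n) 1 else numeric(0), n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    sims <- similarity_to_many(seqs, ids[i], ids[(i + 1L):n], params, ledger)
    m[i, (i + 1L):n] <- sims
    m[(i + 1L):n, i] <- sims
  }
  m
}
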