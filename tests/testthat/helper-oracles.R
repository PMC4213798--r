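# Independent oracles, deliberately naive: these re-derive expected results
# by brute force and never share code with the package internals.

# --- alignment oracle -------------------------------------------------------
# Enumerate every global alignment of two short strings recursively and
# return the best score plus the set of identities among co-optimal
# alignments. Affine gaps: opening a gap costs gap_open + gap_extend,
# extending costs gap_extend. Feasible for sequences up to ~7 residues.
brute_global_alignments <- function(a, b, match = 1, mismatch = -2,
                                    gap_open = 5, gap_extend = 2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$idents <- numeric(0)
  recurse <- function(i, j, score, cols, matches, state) {
    if (i > length(a) && j > length(b)) {
      if (score > best$score + 1e-9) {
        best$score <- score
        best$idents <- if (cols > 0) matches / cols else 0
      } else if (abs(score - best$score) <= 1e-9) {
        best$idents <- unique(c(best$idents,
                                if (cols > 0) matches / cols else 0))
      }
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      recurse(i + 1L, j + 1L, score + s, cols + 1L,
              matches + (a[i] == b[j]), "m")
    }
    if (i <= length(a)) {      # gap in b (consume a)
      pen <- gap_extend + if (state == "da") 0 else gap_open
      recurse(i + 1L, j, score - pen, cols + 1L, matches, "da")
    }
    if (j <= length(b)) {      # gap in a (consume b)
      pen <- gap_extend + if (state == "db") 0 else gap_open
      recurse(i, j + 1L, score - pen, cols + 1L, matches, "db")
    }
  }
  recurse(1L, 1L, 0, 0L, 0L, "start")
  list(score = best$score, identities = best$idents)
}

# --- connected components oracle -------------------------------------------
# Union-find over the thresholded similarity matrix.
uf_components <- function(sim_matrix, t) {
  n <- nrow(sim_matrix)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      if (sim_matrix[i, j] >= t) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
  roots <- vapply(seq_len(n), find, integer(1))
  split(rownames(sim_matrix), match(roots, unique(roots)))
}

# canonical form of a grouping for comparison
canon_groups <- function(groups) {
  sort(unname(vapply(groups, function(g) paste(sort(g), collapse = "|"),
                     character(1))))
}

canon_partition <- function(part) {
  canon_groups(lapply(part$clusters, `[[`, "members"))
}

# --- F-measure oracle -------------------------------------------------------
# Literal nested-loop evaluation of the size-weighted best-harmonic-mean
# formula, from labeled membership vectors.
brute_f_measure <- function(k_lab, c_lab) {
  ids <- names(c_lab)
  n <- length(ids)
  total <- 0
  for (cj in unique(c_lab)) {
    Cj <- ids[c_lab[ids] == cj]
    best <- 0
    for (ki in unique(k_lab)) {
      Ki <- ids[k_lab[ids] == ki]
      ov <- length(intersect(Ki, Cj))
      hm <- 2 * ov / (length(Ki) + length(Cj))
      if (hm > best) best <- hm
    }
    total <- total + length(Cj) * best
  }
  total / n
}

# all set partitions of a vector (Bell-number enumeration)
all_set_partitions <- function(items) {
  if (length(items) == 0L) return(list(list()))
  first <- items[[1L]]
  rest <- all_set_partitions(items[-1L])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(first, q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(first), p)
  }
  out
}

partition_to_labels <- function(p, ids) {
  lab <- character(0)
  for (i in seq_along(p))
    lab[p[[i]]] <- paste0("g", i)
  stats::setNames(lab[ids], ids)
}

# --- central representative oracle -----------------------------------------
brute_central <- function(sim_matrix) {
  sums <- rowSums(sim_matrix) - diag(sim_matrix)
  ids <- rownames(sim_matrix)
  sort(ids[sums >= max(sums) - 1e-12])[[1L]]
}
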