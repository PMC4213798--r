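# shared fixtures, all generated in code

validate_partition_ok <- function(part, ids) {
  mem <- membership(part)
  testthat::expect_setequal(names(mem), ids)
  testthat::expect_false(anyDuplicated(names(mem)) > 0)
  for (cl in part$clusters)
    testthat::expect_true(cl$representative %in% cl$members)
}

random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seq_set(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1)),
    ids = sprintf("s%03d", seq_len(n)))
}

planted <- function(families, per_family, seed, len = 150,
                    within = 0.99, between = 0.70) {
  generate_families(family_spec(families, per_family, seq_length = len,
                                within_identity = within,
                                between_identity = between, seed = seed))
}

# similarity backend driven by an explicit pair table keyed on residues;
# lets tests stipulate exact similarities between tiny synthetic sequences
table_sim_fun <- function(pairs) {
  # pairs: data.frame(a, b, sim) on residue strings
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "/")
  lut <- stats::setNames(pairs$sim, key(pairs$a, pairs$b))
  function(a, b) {
    k <- key(rep_len(a, length(b)), b)
    s <- unname(lut[k])
    s[is.na(s)] <- 0
    s
  }
}

# distinct homopolymer sequences of chosen lengths (up to 4), for
# stipulated-similarity tests (ids A, B, C, ...)
distinct_seqs <- function(lengths) {
  stopifnot(length(lengths) <= 4L)
  bases <- c("A", "C", "G", "T")
  res <- vapply(seq_along(lengths), function(i)
    strrep(bases[i], lengths[i]), character(1))
  seq_set(res, ids = LETTERS[seq_along(lengths)])
}

as_ref_partition <- function(ref) {
  groups <- split(names(ref), as.character(unclass(ref)))
  partition(lapply(unname(groups), function(g) list(members = g)))
}
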