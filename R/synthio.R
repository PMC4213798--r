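#' Synthetic sequence-family specification
#'
#' Parameters of the planted-partition generator used to validate the
#' clustering algorithms without external gold-standard datasets: a set of
#' families, each derived from its own ancestor sequence, with controlled
#' within-family and between-family percent identity so that a threshold
#' strictly between the two levels must recover the planted families.
#'
#' @param num_families number of families (>= 1).
#' @param seqs_per_family members per family: one integer, or a length-2
#'   range sampled uniformly per family.
#' @param seq_length ancestor length in residues: one integer (>= 20), or a
#'   length-2 range sampled per family. Default 150, a typical barcode-marker
#'   scale that keeps full-matrix baselines affordable.
#' @param within_identity target identity of each member to its family
#'   ancestor (so member pairs sit near `2 * within_identity - 1`).
#' @param between_identity approximate identity between members of different
#'   families; must be strictly below `within_identity`.
#' @param alphabet `"dna"` or `"protein"`.
#' @param indel_rate fraction of positions receiving a single-residue
#'   insertion or deletion during member derivation (default 0; capped at
#'   0.02). Indels make aligned identity deviate slightly from the point-
#'   mutation calibration, so leave them off when exact identities matter.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return An object of class `"family_spec"`.
#' @export
family_spec <- function(num_families, seqs_per_family, seq_length = 150L,
                        within_identity = 0.99, between_identity = 0.70,
                        alphabet = c("dna", "protein"),
                        indel_rate = 0, seed = 1L) {
  alphabet <- match.arg(alphabet)
  if (num_families < 1L) stop("need at least one family")
  if (any(seqs_per_family < 1L)) stop("families must be non-empty")
  if (any(seq_length < 20L)) stop("seq_length must be >= 20")
  if (within_identity <= between_identity)
    stop("within_identity must exceed between_identity")
  if (within_identity <= 0 || within_identity > 1 ||
      between_identity < 0 || between_identity >= 1)
    stop("identities must lie in [0, 1] with within > between")
  if (indel_rate < 0 || indel_rate > 0.02)
    stop("indel_rate must lie in [0, 0.02]")
  structure(list(num_families = as.integer(num_families),
                 seqs_per_family = as.integer(seqs_per_family),
                 seq_length = as.integer(seq_length),
                 within_identity = within_identity,
                 between_identity = between_identity,
                 alphabet = alphabet,
                 indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "family_spec")
}

alphabet_chars <- function(alphabet) {
  if (alphabet == "dna") c("A", "C", "G", "T")
  else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}

random_residues <- function(length, alphabet) {
  paste(sample(alphabet_chars(alphabet), length, replace = TRUE),
        collapse = "")
}

draw_from_range <- function(x) {
  if (length(x) == 1L) x else sample(seq(x[[1L]], x[[2L]]), 1L)
}

#' Mutate a sequence toward a target ungapped identity
#'
#' Applies exactly `ceiling((1 - target_identity) * length)` substitutions at
#' distinct positions (each new residue differs from the old one), followed
#' by optional single-residue indels. With indels off, the ungapped identity
#' of the result to its parent equals the target exactly (when
#' `(1 - target) * length` is integral). Uses the current R random number
#' state.
#'
#' @param residues a single residue string.
#' @param target_identity value in `(0, 1]`.
#' @param alphabet `"dna"` or `"protein"`.
#' @param indel_rate fraction of positions receiving an indel (default 0).
#' @return The mutated residue string.
#' @export
mutate_sequence <- function(residues, target_identity,
                            alphabet = c("dna", "protein"),
                            indel_rate = 0) {
  alphabet <- match.arg(alphabet)
  if (target_identity <= 0 || target_identity > 1)
    stop("target_identity must lie in (0, 1]")
  chars <- strsplit(toupper(residues), "")[[1]]
  len <- length(chars)
  nsub <- ceiling((1 - target_identity) * len)
  if (nsub > 0L) {
    pos <- sample.int(len, nsub)
    ab <- alphabet_chars(alphabet)
    for (p in pos)
      chars[p] <- sample(setdiff(ab, chars[p]), 1L)
  }
  if (indel_rate > 0) {
    nind <- floor(indel_rate * len)
    for (i in seq_len(nind)) {
      p <- sample.int(length(chars), 1L)
      if (stats::runif(1) < 0.5 && length(chars) > 20L) {
        chars <- chars[-p]                                   # deletion
      } else {
        ins <- sample(alphabet_chars(alphabet), 1L)          # insertion
        chars <- append(chars, ins, after = p)
      }
    }
  }
  paste(chars, collapse = "")
}

#' Generate synthetic sequence families with planted ground truth
#'
#' Draws one random root sequence, derives each family's ancestor from it by
#' heavy mutation (to identity `(1 + between_identity) / 2`, so ancestor
#' pairs sit near the between-family target), then derives each member from
#' its ancestor by point mutation to `within_identity` (plus optional
#' indels). Ids are `F<family>_S<member>`; the description records the family
#' label. The planted truth maps every sequence to its family.
#'
#' @param spec a [family_spec].
#' @return A list with `sequences` (a [seq_set]) and `truth`
#'   (a [reference_partition]).
#' @examples
#' sim <- generate_families(family_spec(3, 4, seed = 42))
#' sim$sequences
#' @export
generate_families <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  ancestor_identity <- (1 + spec$between_identity) / 2
  root_len <- max(spec$seq_length)
  root <- random_residues(root_len, spec$alphabet)
  ids <- character(0); res <- character(0); desc <- character(0)
  labels <- character(0)
  for (fam in seq_len(spec$num_families)) {
    fam_label <- sprintf("fam%03d", fam)
    fam_len <- draw_from_range(spec$seq_length)
    anc <- substr(root, 1L, fam_len)
    anc <- mutate_sequence(anc, ancestor_identity, spec$alphabet)
    n_mem <- draw_from_range(spec$seqs_per_family)
    for (j in seq_len(n_mem)) {
      ids <- c(ids, sprintf("F%03d_S%03d", fam, j))
      res <- c(res, mutate_sequence(anc, spec$within_identity,
                                    spec$alphabet, spec$indel_rate))
      desc <- c(desc, fam_label)
      labels <- c(labels, fam_label)
    }
  }
  sequences <- seq_set(res, ids = ids, descriptions = desc)
  truth <- reference_partition(stats::setNames(labels, ids))
  list(sequences = sequences, truth = truth)
}
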