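#' Sequence sets
#'
#' `mlclust` represents a dataset as a *sequence set*: a named character
#' vector of uppercase residue strings, one element per sequence, with the
#' sequence identifier as the name and an optional per-sequence description
#' stored in the `"description"` attribute. Identifiers must be non-empty and
#' unique; every sequence must contain at least one residue.
#'
#' @param residues character vector of residue strings.
#' @param ids character vector of unique sequence identifiers. Defaults to
#'   `names(residues)`.
#' @param descriptions optional character vector of free-text descriptions
#'   (recycled empty string when omitted).
#' @return A character vector of class `"seq_set"`.
#' @examples
#' s <- seq_set(c(a = "ACGTACGT", b = "ACGTTCGT"))
#' seq_ids(s)
#' @export
seq_set <- function(residues, ids = names(residues), descriptions = NULL) {
  force(ids)
  residues <- toupper(as.character(residues))
  n <- length(residues)
  if (is.null(ids) && n > 0L)
    stop("sequence ids are required (name the residue vector or pass `ids`)")
  ids <- as.character(ids)
  if (length(ids) != n)
    stop("`ids` must have one entry per sequence")
  if (n > 0L && any(!nzchar(ids)))
    stop("sequence ids must be non-empty")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(residues)))
    stop("empty sequence(s): ", paste(ids[!nzchar(residues)], collapse = ", "))
  if (is.null(descriptions)) descriptions <- character(n)
  descriptions <- rep_len(as.character(descriptions), n)
  structure(stats::setNames(residues, ids),
            description = stats::setNames(descriptions, ids),
            class = "seq_set")
}

#' @rdname seq_set
#' @param x object to coerce: a `seq_set`, a named character vector, or a
#'   `Biostrings::XStringSet` (names are parsed as "id description").
#' @export
as_seq_set <- function(x) {
  if (inherits(x, "seq_set")) return(x)
  if (methods::is(x, "XStringSet")) {
    hdr <- names(x)
    if (is.null(hdr)) stop("XStringSet must be named")
    id <- sub("\\s.*$", "", hdr)
    desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
    return(seq_set(as.character(x), ids = id, descriptions = desc))
  }
  if (is.character(x)) return(seq_set(x))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to a seq_set")
}

#' @rdname seq_set
#' @export
seq_ids <- function(x) names(as_seq_set(x))

#' @rdname seq_set
#' @export
seq_lengths <- function(x) {
  x <- as_seq_set(x)
  stats::setNames(nchar(unname(unclass(x))), names(x))
}

#' @rdname seq_set
#' @export
seq_descriptions <- function(x) attr(as_seq_set(x), "description")

#' @export
`[.seq_set` <- function(x, i, ...) {
  r <- unclass(x)[i]
  if (anyNA(names(r))) stop("unknown sequence id in subset")
  d <- attr(x, "description")[i]
  seq_set(r, descriptions = d)
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set of", length(x), "sequence(s)\n")
  if (length(x)) {
    show <- utils::head(seq_along(x), 6L)
    for (i in show) {
      r <- unclass(x)[[i]]
      cat(sprintf("  %s (%d nt/aa) %s\n", names(x)[i], nchar(r),
                  if (nchar(r) > 40) paste0(substr(r, 1, 40), "...") else r))
    }
    if (length(x) > 6L) cat("  ...\n")
  }
  invisible(x)
}

DNA_CHARS <- c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "-", ".")
PROTEIN_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                   "B", "J", "O", "U", "X", "Z", "*", "-", ".")

# residues identical at an alignment column must also be unambiguous to count
# as a match (so N/N or X/X columns are not identities)
unambiguous_chars <- function(mode) {
  if (mode == "dna") c("A", "C", "G", "T", "U")
  else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}

check_alphabet <- function(x, mode) {
  x <- as_seq_set(x)
  ok_chars <- if (mode == "dna") DNA_CHARS else PROTEIN_CHARS
  bad <- vapply(unclass(x), function(s) {
    ch <- unique(strsplit(s, "")[[1]])
    length(setdiff(ch, ok_chars)) > 0L
  }, logical(1))
  if (any(bad))
    stop("sequence(s) not consistent with mode '", mode, "': ",
         paste(utils::head(names(x)[bad], 5L), collapse = ", "))
  invisible(x)
}

#' Read and write FASTA files
#'
#' `read_fasta()` parses a standard FASTA file (header lines `>id description`,
#' wrapped or unwrapped sequence lines) into a [seq_set]; the id is the first
#' whitespace-delimited token of the header. Sequences are uppercased on read
#' and duplicate ids are rejected. `write_fasta()` is its inverse
#' (write then read restores ids, descriptions and residues exactly).
#'
#' @param path file path.
#' @return `read_fasta()` returns a [seq_set] (empty for an empty file).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' write_fasta(seq_set(c(a = "ACGT")), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(seq_set(character(0), ids = character(0)))
  is_hdr <- startsWith(trimws(lines), ">")
  if (!is_hdr[nonblank[1L]])
    stop("malformed FASTA at line ", nonblank[1L],
         ": sequence data before the first header")
  hdr_idx <- which(is_hdr)
  # an empty record is a header followed directly by another header or EOF
  nxt <- c(hdr_idx[-1L], length(lines) + 1L)
  for (k in seq_along(hdr_idx)) {
    body <- setdiff(seq(hdr_idx[k] + 1L, length.out = nxt[k] - hdr_idx[k] - 1L),
                    integer(0))
    if (!any(nzchar(trimws(lines[body]))))
      stop("malformed FASTA at line ", hdr_idx[k], ": empty record")
  }
  xs <- Biostrings::readBStringSet(path)
  as_seq_set(xs)
}

#' @rdname read_fasta
#' @param x a [seq_set] (or coercible object).
#' @param width line width for wrapping residues.
#' @export
write_fasta <- function(x, path, width = 70L) {
  x <- as_seq_set(x)
  desc <- seq_descriptions(x)
  hdr <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
  xs <- Biostrings::BStringSet(unclass(x))
  names(xs) <- hdr
  Biostrings::writeXStringSet(xs, path, width = width)
  invisible(path)
}
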