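# Sequence identity and redundancy stripping for database balancing.

identity_submat <- function() {
  letters <- c(AA_ALPHABET, "X")
  m <- matrix(0, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m["X", "X"] <- 0  # unknown residues never count as a match
  m
}

#' Pairwise sequence identity under global alignment
#'
#' Aligns two sequences globally (match 1, mismatch 0, linear gap penalty -1)
#' and returns the number of identical aligned positions divided by the
#' length of the shorter sequence. Symmetric in its arguments.
#'
#' @param seq_a,seq_b Non-empty amino-acid sequences (strings) or
#'   [protein_entry()] objects.
#' @return Identity fraction in \[0, 1\].
#' @export
#' @examples
#' pairwise_identity("ACDEFGHIKL", "ACDEFGHIKL")  # 1
#' pairwise_identity("AAAA", "CCCC")              # 0
pairwise_identity <- function(seq_a, seq_b) {
  a <- if (inherits(seq_a, "protein_entry")) seq_a$sequence else
    canonicalize_sequence(seq_a)
  b <- if (inherits(seq_b, "protein_entry")) seq_b$sequence else
    canonicalize_sequence(seq_b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    a, b,
    substitutionMatrix = identity_submat(),
    gapOpening = 0, gapExtension = 1,
    type = "global"
  )
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Greedy identity stripping
#'
#' Walks the entries in input order and keeps an entry only if its pairwise
#' identity to every already-kept entry, and to every entry of an optional
#' reference set, does not exceed `max_identity`. The result therefore has
#' all pairwise identities at or below the ceiling, but which member of a
#' redundant group survives depends on input order (earlier entries win).
#'
#' @param entries A [chezod_db()] or list of [protein_entry()] objects.
#' @param max_identity Identity ceiling (default 0.5).
#' @param reference Optional [chezod_db()] or entry list that kept entries
#'   must also be non-redundant against.
#' @return Same container type as `entries`, filtered.
#' @export
strip_identity <- function(entries, max_identity = 0.5, reference = NULL) {
  as_db <- inherits(entries, "chezod_db")
  lst <- if (as_db) entries$entries else entries
  ref <- if (is.null(reference)) list() else {
    if (inherits(reference, "chezod_db")) reference$entries else reference
  }
  kept <- list()
  for (e in lst) {
    against <- c(ref, kept)
    redundant <- FALSE
    for (other in against) {
      if (pairwise_identity(e, other) > max_identity) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept[[length(kept) + 1L]] <- e
  }
  if (as_db) chezod_db(kept) else kept
}
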