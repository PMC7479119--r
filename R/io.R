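#' Construct a protein entry
#'
#' A `protein_entry` holds one protein sequence together with optional
#' per-residue CheZOD Z-scores and database metadata. Z-scores quantify local
#' order from NMR secondary chemical shifts: low values indicate disorder,
#' high values order, with 8.0 the conventional order/disorder threshold.
#'
#' @param id Entry identifier (non-empty string; must be unique within a
#'   database).
#' @param sequence Amino-acid sequence. Upper-cased on input; letters outside
#'   the 20 standard codes are replaced by `"X"` with a warning.
#' @param zscores Optional numeric vector of per-residue Z-scores, same length
#'   as the sequence. `NA` marks residues without an assigned Z-score.
#' @param acsr Optional non-negative scalar: the average number of assigned
#'   chemical shifts per residue, a data-completeness measure used by the
#'   database-balancing filters.
#'
#' @return An object of class `protein_entry` with fields `id`, `sequence`,
#'   `zscores`, `acsr`.
#' @export
#' @examples
#' protein_entry("p1", "ACDEFG")
protein_entry <- function(id, sequence, zscores = NULL, acsr = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- canonicalize_sequence(sequence, id = id)
  n <- nchar(sequence)
  if (n < 1L) stop("entry '", id, "': sequence must have length >= 1")
  if (!is.null(zscores)) {
    zscores <- as.numeric(zscores)
    if (length(zscores) != n) {
      stop("entry '", id, "': ", length(zscores), " Z-scores for ", n,
           " residues")
    }
  }
  if (!is.null(acsr)) {
    stopifnot(is.numeric(acsr), length(acsr) == 1L, is.finite(acsr), acsr >= 0)
    acsr <- as.numeric(acsr)
  }
  structure(
    list(id = id, sequence = sequence, zscores = zscores, acsr = acsr),
    class = "protein_entry"
  )
}

# Upper-case and map any letter outside the standard alphabet (plus X) to 'X'.
canonicalize_sequence <- function(sequence, id = "?") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(gsub("[[:space:]*]", "", sequence))
  chars <- seq_chars(sequence)
  bad <- !(chars %in% c(AA_ALPHABET, "X"))
  if (any(bad)) {
    warning("entry '", id, "': ", sum(bad),
            " non-standard residue letter(s) (",
            paste(unique(chars[bad]), collapse = ","),
            ") replaced by 'X'", call. = FALSE)
    chars[bad] <- "X"
    sequence <- paste(chars, collapse = "")
  }
  sequence
}

#' @export
print.protein_entry <- function(x, ...) {
  cat("<protein_entry> ", x$id, ": ", nchar(x$sequence), " aa",
      if (!is.null(x$zscores)) {
        paste0(", ", sum(!is.na(x$zscores)), " Z-scores")
      },
      if (!is.null(x$acsr)) paste0(", ACSR ", format(x$acsr)),
      "\n", sep = "")
  invisible(x)
}

#' Construct a CheZOD-style database
#'
#' An ordered collection of [protein_entry()] objects with unique ids and an
#' optional cross-validation subset assignment.
#'
#' @param entries List of `protein_entry` objects.
#' @param subset_assignment Optional named integer vector mapping every entry
#'   id to a fold index (used by the 10-fold cross-validation protocol).
#'
#' @return An object of class `chezod_db`.
#' @export
chezod_db <- function(entries, subset_assignment = NULL) {
  stopifnot(is.list(entries))
  lapply(entries, function(e) stopifnot(inherits(e, "protein_entry")))
  ids <- vapply(entries, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate entry ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(entries) <- ids
  if (!is.null(subset_assignment)) {
    subset_assignment <- check_subset_assignment(subset_assignment, ids)
  }
  structure(
    list(entries = entries, subset_assignment = subset_assignment),
    class = "chezod_db"
  )
}

check_subset_assignment <- function(assignment, ids) {
  if (is.null(names(assignment)) || !setequal(names(assignment), ids) ||
      length(assignment) != length(ids)) {
    stop("subset_assignment must cover every entry id exactly once")
  }
  storage.mode(assignment) <- "integer"
  assignment[ids]
}

#' @export
length.chezod_db <- function(x) length(x$entries)

#' @export
`[.chezod_db` <- function(x, i) {
  chezod_db(x$entries[i],
            subset_assignment = if (!is.null(x$subset_assignment)) {
              ids <- vapply(x$entries[i], `[[`, character(1), "id")
              x$subset_assignment[ids]
            })
}

#' @export
print.chezod_db <- function(x, ...) {
  nz <- sum(vapply(x$entries, function(e) !is.null(e$zscores), logical(1)))
  cat("<chezod_db> ", length(x), " entries (", nz, " with Z-scores)",
      if (!is.null(x$subset_assignment)) {
        paste0(", ", max(x$subset_assignment), "-fold assignment")
      },
      "\n", sep = "")
  invisible(x)
}

#' Pooled Z-scores of a database
#'
#' @param db A [chezod_db()].
#' @param na_rm Drop missing per-residue Z-scores (default `TRUE`).
#' @return Numeric vector of all non-missing Z-scores across entries.
#' @export
pooled_zscores <- function(db, na_rm = TRUE) {
  z <- unlist(lapply(db$entries, `[[`, "zscores"), use.names = FALSE)
  if (na_rm) z <- z[!is.na(z)]
  z
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and letters outside the 20-letter amino-acid
#' alphabet are replaced by `"X"` with a warning.
#'
#' @param path Path to a FASTA file.
#' @return List of [protein_entry()] objects, one per record.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no FASTA records in '", path, "'")
  seqs <- as.character(set)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  if (any(!nzchar(seqs))) {
    stop("empty FASTA record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  unname(Map(protein_entry, ids, seqs))
}

#' Read and write the CheZOD flat-file format
#'
#' The flat dialect stores one `">"` header line with the entry id (and
#' optionally `ACSR=<value>`), followed by one whitespace-separated row per
#' residue: 1-based residue index, one-letter amino acid, and the Z-score
#' printed with 4 decimals, with `nan` marking residues without an assigned
#' Z-score. `write_chezod()` followed by `read_chezod()` is the identity on
#' ids, sequences and Z-scores to the stored precision.
#'
#' @param path File path.
#' @return `read_chezod()` returns a [chezod_db()]; `write_chezod()` returns
#'   `path` invisibly.
#' @export
read_chezod <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no entries in '", path, "'")
  bounds <- c(heads, length(lines) + 1L)
  entries <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    header <- trimws(sub("^>", "", lines[heads[k]]))
    fields <- strsplit(header, "[[:space:]]+")[[1]]
    id <- fields[1L]
    if (!nzchar(id)) stop("empty header at line ", heads[k], " of '", path, "'")
    acsr <- NULL
    acsr_field <- grep("^ACSR=", fields[-1L], value = TRUE)
    if (length(acsr_field)) acsr <- as.numeric(sub("^ACSR=", "", acsr_field[1L]))
    body <- lines[seq.int(heads[k] + 1L, bounds[k + 1L] - 1L)]
    if (length(body) == 0L) stop("entry '", id, "' has no residue rows")
    rows <- strsplit(trimws(body), "[[:space:]]+")
    if (any(lengths(rows) != 3L)) {
      stop("entry '", id, "': malformed residue row(s) (expect index, aa, Z)")
    }
    idx <- as.integer(vapply(rows, `[[`, character(1), 1L))
    if (!identical(idx, seq_along(idx))) {
      stop("entry '", id, "': residue indices are not 1..",
           length(idx), " - sequence/Z-score row count mismatch")
    }
    aa <- vapply(rows, `[[`, character(1), 2L)
    z <- suppressWarnings(as.numeric(vapply(rows, `[[`, character(1), 3L)))
    entries[[k]] <- protein_entry(id, paste(aa, collapse = ""),
                                  zscores = z, acsr = acsr)
  }
  chezod_db(entries)
}

#' @param db A [chezod_db()].
#' @rdname read_chezod
#' @export
write_chezod <- function(db, path) {
  stopifnot(inherits(db, "chezod_db"))
  con <- file(path, "w")
  on.exit(close(con))
  for (e in db$entries) {
    header <- paste0(">", e$id,
                     if (!is.null(e$acsr)) sprintf(" ACSR=%.4f", e$acsr))
    writeLines(header, con)
    chars <- seq_chars(e$sequence)
    z <- e$zscores
    if (is.null(z)) z <- rep(NA_real_, length(chars))
    zs <- ifelse(is.na(z), "nan", sprintf("%.4f", z))
    writeLines(paste(seq_along(chars), chars, zs), con)
  }
  invisible(path)
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' The first row is taken as the query; its ungapped sequence must match the
#' target entry when the MSA is consumed by the evolutionary featurizer.
#'
#' @param path Path to an aligned FASTA file (gaps as `"-"` or `"."`).
#' @return An object of class `msa`: a character matrix (rows x columns) of
#'   single letters with row names from the record ids.
#' @export
read_msa <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no alignment rows in '", path, "'")
  rows <- toupper(chartr(".", "-", as.character(set)))
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows differ in length in '", path, "'")
  }
  msa_from_strings(rows, ids = names(set))
}

#' Build an MSA object from aligned strings
#'
#' @param rows Character vector of equal-length aligned sequences (first row
#'   is the query).
#' @param ids Optional row identifiers.
#' @return An object of class `msa`.
#' @export
msa_from_strings <- function(rows, ids = NULL) {
  stopifnot(is.character(rows), length(rows) >= 1L)
  rows <- toupper(chartr(".", "-", rows))
  if (length(unique(nchar(rows))) != 1L) stop("alignment rows differ in length")
  m <- do.call(rbind, lapply(rows, seq_chars))
  bad <- !(m %in% c(AA_ALPHABET, "X", "-"))
  m[bad] <- "X"
  rownames(m) <- if (is.null(ids)) paste0("row", seq_len(nrow(m))) else ids
  structure(m, class = c("msa", class(m)))
}

#' Fraction of residues with Z-scores below 5
#'
#' `f_IDR5`, the per-entry fraction of residues whose Z-score is below 5.0,
#' computed over residues with an assigned Z-score. It is the disorder-content
#' measure used by the staged database-balancing filters.
#'
#' @param entry A [protein_entry()] with at least one non-missing Z-score.
#' @return A value in \[0, 1\].
#' @export
f_idr5 <- function(entry) {
  stopifnot(inherits(entry, "protein_entry"))
  z <- entry$zscores[!is.na(entry$zscores)]
  if (length(z) == 0L) {
    stop("entry '", entry$id, "' has no non-missing Z-scores")
  }
  mean(z < 5.0)
}

#' Interpret a CheZOD Z-score as an order category
#'
#' Z below 3 is fully disordered; 3 to 8 reflects fractional formation of
#' local ordered structure; 8 to 11 corresponds to flexible loops; 11 and
#' above to regular secondary structure or rigid loops. Intervals are
#' half-open and lower-inclusive.
#'
#' @param z Numeric vector of finite Z-scores.
#' @return Character vector with levels `fully_disordered`,
#'   `fractional_order`, `flexible_loop`, `ordered`.
#' @export
#' @examples
#' interpret_zscore(c(2, 5, 9.5, 12))
interpret_zscore <- function(z) {
  stopifnot(is.numeric(z))
  if (any(!is.finite(z))) stop("non-finite Z-score")
  cut_labels <- c("fully_disordered", "fractional_order", "flexible_loop",
                  "ordered")
  as.character(cut(z, breaks = c(-Inf, 3, 8, 11, Inf), labels = cut_labels,
                   right = FALSE))
}

#' Staged acceptance rule for database balancing
#'
#' Decides whether a candidate entry enters the database at a given balancing
#' stage, from its disorder content (`f_IDR5`) and chemical-shift completeness
#' (ACSR). The stages add sequences with progressively more order under
#' increasingly strict completeness demands:
#' * `seed`: `f_IDR5 > 0.5` and `ACSR > 2.0`
#' * `i`:   `0.3 < f_IDR5 < 0.5` and `ACSR > 4.0`
#' * `ii`:  `0.2 < f_IDR5 < 0.3` and `ACSR > 5.0`
#' * `iii`: `0.1 < f_IDR5 < 0.2` and `ACSR > 6.0`
#' * `iv`:  `0.05 < f_IDR5 < 0.1` and `ACSR > 6.0`
#' * `refdb`: `ACSR > 6`, or `ACSR > 5.5` and `f_IDR5 > 0.05`
#'
#' All inequalities are strict.
#'
#' @param stage One of `"seed"`, `"i"`, `"ii"`, `"iii"`, `"iv"`, `"refdb"`.
#' @param f_idr5_value Fraction of residues with Z < 5 (in \[0, 1\]).
#' @param acsr_value Average assigned chemical shifts per residue (>= 0).
#' @return Logical: accept the candidate at this stage.
#' @export
accept_candidate <- function(stage, f_idr5_value, acsr_value) {
  stopifnot(is.numeric(f_idr5_value), is.numeric(acsr_value),
            length(f_idr5_value) == 1L, length(acsr_value) == 1L)
  f <- f_idr5_value
  a <- acsr_value
  switch(match.arg(stage, c("seed", "i", "ii", "iii", "iv", "refdb")),
    seed  = f > 0.5 && a > 2.0,
    i     = f > 0.3 && f < 0.5 && a > 4.0,
    ii    = f > 0.2 && f < 0.3 && a > 5.0,
    iii   = f > 0.1 && f < 0.2 && a > 6.0,
    iv    = f > 0.05 && f < 0.1 && a > 6.0,
    refdb = a > 6 || (a > 5.5 && f > 0.05)
  )
}

#' Filter a candidate set through one balancing stage
#'
#' Applies [accept_candidate()] to every entry (entries lacking Z-scores or
#' ACSR are rejected), then strips sequence redundancy with
#' [strip_identity()] against both the accepted candidates themselves and an
#' optional reference database. For stage `"iv"` only the 100 longest
#' accepted sequences are kept (ties broken by id) before identity stripping.
#'
#' @param db Candidate [chezod_db()].
#' @param stage Balancing stage, see [accept_candidate()].
#' @param reference Optional [chezod_db()] of previously accepted entries.
#' @param max_identity Identity ceiling passed to [strip_identity()].
#' @param keep_longest Cap on accepted entries for stage `"iv"` (default 100).
#' @return Filtered [chezod_db()].
#' @export
filter_stage <- function(db, stage, reference = NULL, max_identity = 0.5,
                         keep_longest = 100L) {
  stopifnot(inherits(db, "chezod_db"))
  ok <- vapply(db$entries, function(e) {
    if (is.null(e$zscores) || all(is.na(e$zscores)) || is.null(e$acsr)) {
      return(FALSE)
    }
    accept_candidate(stage, f_idr5(e), e$acsr)
  }, logical(1))
  kept <- db$entries[ok]
  if (identical(stage, "iv") && length(kept) > keep_longest) {
    len <- vapply(kept, function(e) nchar(e$sequence), integer(1))
    ord <- order(-len, vapply(kept, `[[`, character(1), "id"))
    kept <- kept[sort(ord[seq_len(keep_longest)])]
  }
  strip_identity(chezod_db(kept), max_identity = max_identity,
                 reference = reference)
}

#' Summary statistics of a CheZOD database
#'
#' @param db A [chezod_db()].
#' @return A list with the number of entries, total residues, pooled-Z range,
#'   and quartiles of the per-entry `f_IDR5` distribution.
#' @export
db_stats <- function(db) {
  stopifnot(inherits(db, "chezod_db"))
  z <- pooled_zscores(db)
  has_z <- vapply(db$entries,
                  function(e) !is.null(e$zscores) && any(!is.na(e$zscores)),
                  logical(1))
  fidr <- vapply(db$entries[has_z], f_idr5, numeric(1))
  list(
    n_entries = length(db),
    n_residues = sum(vapply(db$entries, function(e) nchar(e$sequence),
                            integer(1))),
    n_zscores = length(z),
    z_min = if (length(z)) min(z) else NA_real_,
    z_max = if (length(z)) max(z) else NA_real_,
    f_idr5_quartiles = if (length(fidr)) {
      stats::quantile(fidr, c(0, 0.25, 0.5, 0.75, 1))
    } else NULL
  )
}
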