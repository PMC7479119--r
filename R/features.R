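# Per-residue sequence featurization: 130 sequence-intrinsic columns plus an
# optional 27-column block derived from a multiple sequence alignment.
# Column order and names are frozen in the version-1 manifest so that trained
# models and feature matrices stay compatible.

FEATURE_WINDOWS <- c(5L, 11L, 21L)

# ---- windowed helpers -------------------------------------------------------

# Mean of x over a centred window of width w, truncated at the termini.
# NA values (unknown residues) are excluded from numerator and denominator;
# windows with no valid residue yield 0.
win_mean <- function(x, w) {
  L <- length(x)
  h <- (w - 1L) %/% 2L
  val <- ifelse(is.na(x), 0, x)
  cs <- cumsum(c(0, val))
  cn <- cumsum(c(0, as.numeric(!is.na(x))))
  i <- seq_len(L)
  lo <- pmax(1L, i - h)
  hi <- pmin(L, i + h)
  s <- cs[hi + 1L] - cs[lo]
  n <- cn[hi + 1L] - cn[lo]
  ifelse(n > 0, s / n, 0)
}

# L x 20 windowed amino-acid count matrix (X excluded entirely)
win_counts <- function(chars, w) {
  L <- length(chars)
  h <- (w - 1L) %/% 2L
  i <- seq_len(L)
  lo <- pmax(1L, i - h)
  hi <- pmin(L, i + h)
  out <- matrix(0, L, length(AA_ALPHABET),
                dimnames = list(NULL, AA_ALPHABET))
  for (a in AA_ALPHABET) {
    cs <- cumsum(c(0, as.numeric(chars == a)))
    out[, a] <- cs[hi + 1L] - cs[lo]
  }
  out
}

# Shannon entropy (bits) of a count matrix row
count_entropy <- function(counts) {
  tot <- rowSums(counts)
  p <- counts / ifelse(tot > 0, tot, 1)
  lp <- ifelse(p > 0, log2(p), 0)
  -rowSums(p * lp)
}

# length of the maximal run of TRUE covering each position (0 where FALSE)
run_length_at <- function(mask) {
  r <- rle(mask)
  rep(ifelse(r$values, r$lengths, 0L), r$lengths)
}

# ---- feature groups ---------------------------------------------------------

#' Windowed amino-acid composition features
#'
#' For every window size and every standard amino acid, the frequency of that
#' amino acid within the window centred on each residue. Windows are
#' truncated at the termini and normalized by the number of standard (non-X)
#' residues they contain. Additional columns give the whole-sequence
#' frequency of each amino acid and windowed fractions of the
#' disorder-promoting (G,P,S,Q,E,K), order-promoting (W,I,F,Y,L,V) and
#' aromatic (F,W,Y,H) residue classes.
#'
#' @param sequence Amino-acid sequence string.
#' @param windows Odd window widths (default 5, 11, 21).
#' @return Numeric matrix, one row per residue, with named columns.
#' @export
composition_features <- function(sequence, windows = FEATURE_WINDOWS) {
  chars <- seq_chars(canonicalize_sequence(sequence))
  L <- length(chars)
  cols <- list()
  for (w in windows) {
    counts <- win_counts(chars, w)
    tot <- rowSums(counts)
    freq <- counts / ifelse(tot > 0, tot, 1)
    colnames(freq) <- sprintf("comp_%s_w%d", AA_ALPHABET, w)
    cols[[length(cols) + 1L]] <- freq
  }
  n_std <- sum(chars != "X")
  glob <- vapply(AA_ALPHABET, function(a) {
    if (n_std > 0) sum(chars == a) / n_std else 0
  }, numeric(1))
  gm <- matrix(rep(glob, each = L), nrow = L,
               dimnames = list(NULL, sprintf("comp_%s_global", AA_ALPHABET)))
  cols[[length(cols) + 1L]] <- gm
  classes <- list(disorder_promoting = DISORDER_PROMOTING_SET,
                  order_promoting = ORDER_PROMOTING_SET,
                  aromatic = AROMATIC_SET)
  for (cl in names(classes)) {
    ind <- ifelse(chars == "X", NA_real_, as.numeric(chars %in% classes[[cl]]))
    m <- vapply(windows, function(w) win_mean(ind, w), numeric(L))
    m <- matrix(m, nrow = L,
                dimnames = list(NULL, sprintf("frac_%s_w%d", cl, windows)))
    cols[[length(cols) + 1L]] <- m
  }
  do.call(cbind, cols)
}

#' Windowed physico-chemical features
#'
#' Windowed Shannon entropy of the amino-acid composition (bits), net charge
#' at pH 7 (K,R = +1, D,E = -1, H = +0.1), Kyte-Doolittle hydropathy,
#' isoelectric point and flexibility, plus the lengths of the same-sign
#' charge runs covering each residue and three positional columns (relative
#' position, log distance to the nearer terminus, log sequence length).
#'
#' @inheritParams composition_features
#' @return Numeric matrix, one row per residue, with named columns.
#' @export
physchem_features <- function(sequence, windows = FEATURE_WINDOWS) {
  chars <- seq_chars(canonicalize_sequence(sequence))
  L <- length(chars)
  cols <- list()
  for (w in windows) {
    e <- count_entropy(win_counts(chars, w))
    cols[[length(cols) + 1L]] <- matrix(e, dimnames = list(NULL,
                                        sprintf("entropy_w%d", w)))
  }
  scales <- list(net_charge = AA_CHARGE, hydropathy_kd = KYTE_DOOLITTLE,
                 isoelectric_point = AA_PI, flexibility = AA_FLEXIBILITY)
  for (nm in names(scales)) {
    x <- unname(scales[[nm]][chars])  # NA for X
    m <- vapply(windows, function(w) win_mean(x, w), numeric(L))
    cols[[length(cols) + 1L]] <- matrix(m, nrow = L, dimnames = list(NULL,
                                        sprintf("%s_w%d", nm, windows)))
  }
  charge <- unname(AA_CHARGE[chars])
  charge[is.na(charge)] <- 0
  pos_run <- run_length_at(charge > 0)
  neg_run <- run_length_at(charge < 0)
  i <- seq_len(L)
  positional <- cbind(
    pos_charge_run = as.numeric(pos_run),
    neg_charge_run = as.numeric(neg_run),
    rel_position = (i - 0.5) / L,
    terminal_distance = log10(1 + pmin(i - 1L, L - i)),
    log_length = rep(log10(L), L)
  )
  cols[[length(cols) + 1L]] <- positional
  do.call(cbind, cols)
}

# per-residue beta-aggregation propensity surrogate: hydrophobicity rescaled
# to [0,1], attenuated by side-chain charge, zeroed at the backbone breakers
# Pro and Gly
beta_agg_scale <- function() {
  h01 <- (KYTE_DOOLITTLE + 4.5) / 9
  s <- h01 * (1 - pmin(1, abs(AA_CHARGE)))
  s[c("P", "G")] <- 0
  s
}

#' Windowed secondary-structure and hydrophobic-cluster features
#'
#' Windowed Chou-Fasman helix, sheet and turn propensities; a windowed
#' beta-aggregation propensity channel (hydrophobicity attenuated by charge
#' with Pro/Gly zeroed, playing the role of an aggregation predictor); and
#' hydrophobic-cluster descriptors from the binary mask of V,I,L,F,M,Y,W:
#' the length of the cluster (run of at least 2 masked residues) covering the
#' residue, the distance to the nearest cluster, and windowed cluster
#' density.
#'
#' @inheritParams composition_features
#' @return Numeric matrix, one row per residue, with named columns.
#' @export
structure_features <- function(sequence, windows = FEATURE_WINDOWS) {
  chars <- seq_chars(canonicalize_sequence(sequence))
  L <- length(chars)
  cols <- list()
  scales <- list(cf_helix = CHOU_FASMAN_HELIX, cf_sheet = CHOU_FASMAN_SHEET,
                 cf_turn = CHOU_FASMAN_TURN, beta_agg = beta_agg_scale())
  for (nm in names(scales)) {
    x <- unname(scales[[nm]][chars])
    m <- vapply(windows, function(w) win_mean(x, w), numeric(L))
    cols[[length(cols) + 1L]] <- matrix(m, nrow = L, dimnames = list(NULL,
                                        sprintf("%s_w%d", nm, windows)))
  }
  mask <- chars %in% HYDROPHOBIC_SET
  run <- run_length_at(mask)
  in_cluster <- run >= 2L
  clen <- ifelse(in_cluster, run, 0L)
  if (any(in_cluster)) {
    idx <- which(in_cluster)
    dist <- vapply(seq_len(L), function(i) min(abs(idx - i)), numeric(1))
  } else {
    dist <- rep.int(L, L)
  }
  dens <- vapply(windows, function(w) win_mean(as.numeric(in_cluster), w),
                 numeric(L))
  cols[[length(cols) + 1L]] <- cbind(
    hydrophobic_cluster_len = as.numeric(clen),
    hydrophobic_cluster_dist = as.numeric(dist)
  )
  cols[[length(cols) + 1L]] <- matrix(dens, nrow = L, dimnames = list(NULL,
    sprintf("hydrophobic_cluster_density_w%d", windows)))
  do.call(cbind, cols)
}

# positions covered by exact tandem repeats (period 1..max_period, >= min_copies
# full copies); returns per-residue copy count (0 where uncovered)
tandem_repeat_copies <- function(chars, max_period = 6L, min_copies = 3L) {
  L <- length(chars)
  copies <- numeric(L)
  for (p in seq_len(min(max_period, L %/% min_copies))) {
    same <- chars[seq_len(L - p)] == chars[seq_len(L - p) + p] &
      chars[seq_len(L - p)] != "X"
    r <- rle(same)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      q <- r$lengths[k]
      if (q >= (min_copies - 1L) * p) {
        span <- starts[k]:(ends[k] + p)
        n_cop <- (q + p) %/% p
        copies[span] <- pmax(copies[span], n_cop)
      }
    }
  }
  copies
}

#' Sequence-pattern features
#'
#' Per residue: an indicator and the copy count of exact tandem repeats
#' (period 1-6, at least 3 copies) covering the residue; the number of
#' bundled short-linear-motif regular expressions (version 1 set) whose
#' matches overlap the residue; and a low-complexity indicator (window-21
#' compositional entropy below `lc_cutoff` bits).
#'
#' @inheritParams composition_features
#' @param lc_cutoff Entropy cutoff in bits for the low-complexity flag
#'   (default 2.5).
#' @return Numeric matrix, one row per residue, with named columns.
#' @export
pattern_features <- function(sequence, lc_cutoff = 2.5) {
  chars <- seq_chars(canonicalize_sequence(sequence))
  L <- length(chars)
  seqstr <- paste(chars, collapse = "")
  copies <- tandem_repeat_copies(chars)
  motif_count <- numeric(L)
  for (pat in SLIM_MOTIFS_V1) {
    m <- gregexpr(pat, seqstr, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      len <- attr(m, "match.length")
      for (j in seq_along(m)) {
        span <- m[j]:(m[j] + len[j] - 1L)
        motif_count[span] <- motif_count[span] + 1
      }
    }
  }
  ent21 <- count_entropy(win_counts(chars, 21L))
  cbind(
    tandem_repeat = as.numeric(copies > 0),
    tandem_repeat_copies = copies,
    slim_motif_count = motif_count,
    low_complexity = as.numeric(ent21 < lc_cutoff)
  )
}

#' Evolutionary profile features from a multiple sequence alignment
#'
#' Computes 27 per-residue columns over the query (ungapped) positions of an
#' alignment: the 20 amino-acid profile frequencies (rows weighted
#' uniformly, gaps and unknowns excluded), the profile entropy, the gap
#' fraction, the agreement between query and profile, the number of aligned
#' sequences (constant column), windowed profile entropy (windows 5 and 11)
#' and the conservation of the query's hydrophobicity class.
#'
#' @param entry A [protein_entry()] whose sequence equals the degapped first
#'   alignment row.
#' @param msa An [msa_from_strings()]/[read_msa()] alignment.
#' @return Numeric matrix with 27 named columns, one row per query residue.
#' @export
evo_features <- function(entry, msa) {
  stopifnot(inherits(entry, "protein_entry"), inherits(msa, "msa"))
  query <- msa[1L, ]
  keep <- query != "-"
  if (paste(query[keep], collapse = "") != entry$sequence) {
    stop("entry '", entry$id,
         "': degapped MSA query row does not match the entry sequence")
  }
  m <- msa[, keep, drop = FALSE]
  n_rows <- nrow(m)
  L <- ncol(m)
  prof <- matrix(0, L, length(AA_ALPHABET),
                 dimnames = list(NULL, sprintf("profile_%s", AA_ALPHABET)))
  gap_frac <- numeric(L)
  agree <- numeric(L)
  hclass <- numeric(L)
  qchars <- m[1L, ]
  for (i in seq_len(L)) {
    col <- m[, i]
    gap_frac[i] <- mean(col == "-")
    std <- col[col %in% AA_ALPHABET]
    if (length(std)) {
      tab <- table(factor(std, levels = AA_ALPHABET))
      prof[i, ] <- as.numeric(tab) / length(std)
    }
    q <- qchars[i]
    agree[i] <- if (q %in% AA_ALPHABET) prof[i, paste0("profile_", q)] else 0
    nong <- col[col != "-"]
    if (length(nong)) {
      hclass[i] <- mean((nong %in% HYDROPHOBIC_SET) ==
                          (q %in% HYDROPHOBIC_SET))
    }
  }
  ent <- count_entropy(prof * 1)  # frequencies work like counts for entropy
  cbind(
    prof,
    profile_entropy = ent,
    gap_fraction = gap_frac,
    query_agreement = agree,
    n_eff = rep(as.numeric(n_rows), L),
    profile_entropy_w5 = win_mean(ent, 5L),
    profile_entropy_w11 = win_mean(ent, 11L),
    hclass_conservation = hclass
  )
}

# ---- manifest and assembly --------------------------------------------------

#' Feature manifest
#'
#' The frozen (version 1) ordered list of feature columns and their group
#' tags. 130 sequence-intrinsic columns; 157 when the evolutionary block is
#' included.
#'
#' @param evolution Include the 27 alignment-profile columns.
#' @param windows Window widths used by the windowed groups.
#' @return `data.frame` with columns `name` and `group` (one of
#'   `composition`, `physchem`, `structure`, `pattern`, `evolution`).
#' @export
feature_manifest <- function(evolution = FALSE, windows = FEATURE_WINDOWS) {
  comp <- c(
    as.vector(vapply(windows,
                     function(w) sprintf("comp_%s_w%d", AA_ALPHABET, w),
                     character(length(AA_ALPHABET)))),
    sprintf("comp_%s_global", AA_ALPHABET),
    as.vector(t(vapply(c("disorder_promoting", "order_promoting", "aromatic"),
                       function(cl) sprintf("frac_%s_w%d", cl, windows),
                       character(length(windows)))))
  )
  phys <- c(
    sprintf("entropy_w%d", windows),
    as.vector(t(vapply(c("net_charge", "hydropathy_kd", "isoelectric_point",
                         "flexibility"),
                       function(nm) sprintf("%s_w%d", nm, windows),
                       character(length(windows))))),
    "pos_charge_run", "neg_charge_run", "rel_position", "terminal_distance",
    "log_length"
  )
  struc <- c(
    as.vector(t(vapply(c("cf_helix", "cf_sheet", "cf_turn", "beta_agg"),
                       function(nm) sprintf("%s_w%d", nm, windows),
                       character(length(windows))))),
    "hydrophobic_cluster_len", "hydrophobic_cluster_dist",
    sprintf("hydrophobic_cluster_density_w%d", windows)
  )
  patt <- c("tandem_repeat", "tandem_repeat_copies", "slim_motif_count",
            "low_complexity")
  df <- data.frame(
    name = c(comp, phys, struc, patt),
    group = rep(c("composition", "physchem", "structure", "pattern"),
                c(length(comp), length(phys), length(struc), length(patt))),
    stringsAsFactors = FALSE
  )
  if (evolution) {
    evo <- c(sprintf("profile_%s", AA_ALPHABET), "profile_entropy",
             "gap_fraction", "query_agreement", "n_eff",
             "profile_entropy_w5", "profile_entropy_w11",
             "hclass_conservation")
    df <- rbind(df, data.frame(name = evo, group = "evolution",
                               stringsAsFactors = FALSE))
  }
  df
}

#' Build the per-residue feature matrix for one entry
#'
#' Concatenates the composition, physico-chemical, structure and pattern
#' groups (130 columns), plus the 27-column evolutionary block when an MSA is
#' supplied and `evolution = TRUE`, in the fixed order given by
#' [feature_manifest()]. Deterministic: the same entry always yields the
#' identical matrix.
#'
#' @param entry A [protein_entry()] (or a plain sequence string).
#' @param msa Optional alignment for the evolutionary block.
#' @param evolution Compute the evolutionary block (requires `msa`).
#' @param windows Window widths.
#' @param lc_cutoff Low-complexity entropy cutoff (bits).
#' @return An object of class `feature_matrix`: list with `values` (L x F
#'   matrix), `names`, and `group`.
#' @export
build_feature_matrix <- function(entry, msa = NULL, evolution = !is.null(msa),
                                 windows = FEATURE_WINDOWS, lc_cutoff = 2.5) {
  if (is.character(entry)) entry <- protein_entry("seq", entry)
  stopifnot(inherits(entry, "protein_entry"))
  if (evolution && is.null(msa)) {
    stop("evolution = TRUE requires an MSA")
  }
  blocks <- list(
    composition_features(entry$sequence, windows),
    physchem_features(entry$sequence, windows),
    structure_features(entry$sequence, windows),
    pattern_features(entry$sequence, lc_cutoff)
  )
  if (evolution) blocks[[length(blocks) + 1L]] <- evo_features(entry, msa)
  values <- do.call(cbind, blocks)
  manifest <- feature_manifest(evolution = evolution, windows = windows)
  values <- values[, manifest$name, drop = FALSE]
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite feature value: feature '",
         manifest$name[bad[1, 2]], "', residue ", bad[1, 1],
         " of entry '", entry$id, "'")
  }
  structure(
    list(values = values, names = manifest$name, group = manifest$group,
         entry_id = entry$id),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " residues x ", ncol(x$values),
      " features (", paste(unique(x$group), collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' Fit and apply per-feature normalization
#'
#' `fit_normalizer()` pools the residues of the supplied training matrices
#' and records each feature's mean and standard deviation;
#' `apply_normalizer()` standardizes a matrix as `(x - mean) / sd`. Features
#' that are constant in the training pool (sd = 0) are flagged and emitted as
#' all-zero columns.
#'
#' @param matrices List of `feature_matrix` objects (or numeric matrices with
#'   identical columns).
#' @return `fit_normalizer()` returns an object of class `normalizer` with
#'   fields `mean`, `sd`, `constant`, `names`.
#' @export
fit_normalizer <- function(matrices) {
  if (inherits(matrices, "feature_matrix") || is.matrix(matrices)) {
    matrices <- list(matrices)
  }
  stopifnot(length(matrices) >= 1L)
  vals <- lapply(matrices, function(m) {
    if (inherits(m, "feature_matrix")) m$values else m
  })
  pool <- do.call(rbind, vals)
  if (nrow(pool) < 2L) stop("need at least 2 training residues")
  mu <- colMeans(pool)
  sd_ <- apply(pool, 2L, stats::sd)
  constant <- sd_ == 0 | !is.finite(sd_)
  structure(
    list(mean = mu, sd = sd_, constant = constant, names = colnames(pool)),
    class = "normalizer"
  )
}

#' @param matrix A `feature_matrix` or numeric matrix to standardize.
#' @param normalizer A fitted `normalizer`.
#' @rdname fit_normalizer
#' @export
apply_normalizer <- function(matrix, normalizer) {
  stopifnot(inherits(normalizer, "normalizer"))
  vals <- if (inherits(matrix, "feature_matrix")) matrix$values else matrix
  if (!is.null(normalizer$names) && !is.null(colnames(vals)) &&
      !identical(colnames(vals), normalizer$names)) {
    stop("feature columns do not match the normalizer's manifest")
  }
  sd_safe <- ifelse(normalizer$constant, 1, normalizer$sd)
  out <- sweep(vals, 2L, normalizer$mean, "-")
  out <- sweep(out, 2L, sd_safe, "/")
  out[, normalizer$constant] <- 0
  out
}
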