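# Seeded generator of CheZOD-like databases with known ground truth.
#
# Each entry alternates ordered and disordered segments via a two-state
# Markov chain. Residue letters are drawn from state-biased amino-acid
# compositions (disorder-promoting residues enriched in disordered
# segments, bulky hydrophobics in ordered ones) so that the sequence-to-Z
# mapping is learnable. Z-scores are drawn from the state's skew-normal
# mixture component through serially correlated standard-normal
# innovations, which makes Z vary smoothly along the chain, as in real
# profiles, while preserving the skew-normal marginal exactly.

#' Configuration of the synthetic CheZOD-like generator
#'
#' Defaults emulate the fitted regime of real pooled Z-scores: disordered
#' component centred low (location 1, scale 2, skewness +2), ordered
#' component near 11 (scale 2, skewness -2), disordered fraction 0.36,
#' segment persistence 0.95 and innovation autocorrelation 0.8.
#'
#' @param n_entries Number of entries.
#' @param length_range Integer pair, entry lengths drawn uniformly
#'   (minimum 20).
#' @param persistence Markov-chain stay probability in (0, 1); leave rates
#'   are scaled so that the stationary disordered fraction equals
#'   `mixture$f_d`.
#' @param mixture Generative [disorder_mixture()].
#' @param bias Composition enrichment factor for the state-preferred
#'   residue classes (default 4).
#' @param rho Lag-1 autocorrelation of the Z innovations in \[0, 1).
#' @param seed Integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_entries = 200L, length_range = c(80L, 200L),
                             persistence = 0.95,
                             mixture = disorder_mixture(1, 2, 2, 11, 2, -2,
                                                        0.36),
                             bias = 4, rho = 0.8, seed = 1L) {
  stopifnot(n_entries >= 1, length_range[1] >= 20,
            length_range[2] >= length_range[1],
            persistence > 0, persistence < 1,
            inherits(mixture, "disorder_mixture"),
            bias > 0, rho >= 0, rho < 1)
  w_dis <- rep(1, 20); names(w_dis) <- AA_ALPHABET
  w_ord <- w_dis
  w_dis[DISORDER_PROMOTING_SET] <- bias
  w_ord[ORDER_PROMOTING_SET] <- bias
  structure(
    list(n_entries = as.integer(n_entries),
         length_range = as.integer(length_range),
         persistence = persistence, mixture = mixture,
         weights = list(disordered = w_dis / sum(w_dis),
                        ordered = w_ord / sum(w_ord)),
         rho = rho, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# stationary AR(1) standard-normal series
ar1_normal <- function(n, rho) {
  e <- stats::rnorm(n)
  if (rho == 0 || n == 1L) return(e)
  x <- numeric(n)
  x[1] <- e[1]
  scale <- sqrt(1 - rho^2)
  for (i in 2:n) x[i] <- rho * x[i - 1] + scale * e[i]
  x
}

#' Generate one synthetic entry
#'
#' Draws segment states from the two-state Markov chain, residue letters
#' from the state-biased composition, and Z-scores from the state's
#' skew-normal component using serially correlated innovations. The latent
#' segment states are attached as attribute `states`.
#'
#' @param config A [synthetic_config()].
#' @param id Entry identifier.
#' @param seed Optional seed; when `NULL` the current RNG state is used
#'   (as inside [generate_database()]).
#' @return A [protein_entry()] with Z-scores and attribute `states`
#'   (`"D"`/`"O"` per residue).
#' @export
generate_entry <- function(config, id = "syn1", seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_entry(config, id = id)))
  }
  f_d <- config$mixture$f_d
  leave <- 1 - config$persistence
  # scale leave rates so the stationary disordered fraction equals f_d
  leave_d <- min(1, 2 * leave * (1 - f_d))
  leave_o <- min(1, 2 * leave * f_d)
  L <- if (config$length_range[1] == config$length_range[2]) {
    config$length_range[1]
  } else {
    sample(config$length_range[1]:config$length_range[2], 1L)
  }
  states <- character(L)
  states[1] <- if (stats::runif(1) < f_d) "D" else "O"
  for (i in seq_len(L - 1L)) {
    p_leave <- if (states[i] == "D") leave_d else leave_o
    states[i + 1L] <- if (stats::runif(1) < p_leave) {
      if (states[i] == "D") "O" else "D"
    } else {
      states[i]
    }
  }
  chars <- character(L)
  is_d <- states == "D"
  if (any(is_d)) {
    chars[is_d] <- sample(AA_ALPHABET, sum(is_d), replace = TRUE,
                          prob = config$weights$disordered)
  }
  if (any(!is_d)) {
    chars[!is_d] <- sample(AA_ALPHABET, sum(!is_d), replace = TRUE,
                           prob = config$weights$ordered)
  }
  u0 <- ar1_normal(L, config$rho)
  u1 <- ar1_normal(L, config$rho)
  d <- config$mixture$disordered
  o <- config$mixture$ordered
  z <- numeric(L)
  z[is_d] <- rskewnorm(mu = d$mu, sigma = d$sigma, alpha = d$alpha,
                       u0 = u0[is_d], u1 = u1[is_d])
  z[!is_d] <- rskewnorm(mu = o$mu, sigma = o$sigma, alpha = o$alpha,
                        u0 = u0[!is_d], u1 = u1[!is_d])
  acsr <- stats::runif(1, 2, 12)
  entry <- protein_entry(id, paste(chars, collapse = ""), zscores = z,
                         acsr = acsr)
  attr(entry, "states") <- states
  entry
}

#' Generate a synthetic CheZOD-like database
#'
#' @param config A [synthetic_config()]; `config$seed` makes the database
#'   fully reproducible.
#' @return A [chezod_db()] whose entries carry Z-scores, ACSR values and
#'   latent segment states.
#' @export
generate_database <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  entries <- withr::with_seed(config$seed, {
    lapply(seq_len(config$n_entries), function(i) {
      generate_entry(config, id = sprintf("syn%04d", i))
    })
  })
  chezod_db(entries)
}

#' Mixture-implied fraction of residues below a Z threshold
#'
#' @param mixture A [disorder_mixture()].
#' @param threshold Z threshold (default 8).
#' @return The mixture's probability mass below the threshold.
#' @export
mixture_fraction_below <- function(mixture, threshold = 8.0) {
  stats::integrate(function(x) dmixture(x, mixture), -Inf, threshold,
                   rel.tol = 1e-8)$value
}

#' Simulate a toy MSA by mutating a query sequence
#'
#' Produces an alignment whose first row is the (ungapped) query and whose
#' remaining rows are independently mutated copies, with optional gap
#' introduction. Intended for exercising the evolutionary featurizer in
#' tests; it does not emulate real homolog divergence.
#'
#' @param entry A [protein_entry()] (or sequence string).
#' @param n_rows Total number of rows including the query.
#' @param mutation_rate Per-position substitution probability.
#' @param gap_rate Per-position gap probability in non-query rows.
#' @param seed Integer seed.
#' @return An `msa` object.
#' @export
mutate_msa <- function(entry, n_rows = 5L, mutation_rate = 0.1,
                       gap_rate = 0.02, seed = 1L) {
  if (is.character(entry)) entry <- protein_entry("query", entry)
  chars <- seq_chars(entry$sequence)
  L <- length(chars)
  rows <- withr::with_seed(seed, {
    lapply(seq_len(n_rows - 1L), function(i) {
      r <- chars
      mut <- stats::runif(L) < mutation_rate
      r[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE)
      gap <- stats::runif(L) < gap_rate
      r[gap] <- "-"
      paste(r, collapse = "")
    })
  })
  msa_from_strings(c(entry$sequence, unlist(rows)),
                   ids = c(entry$id, sprintf("hom%d", seq_len(n_rows - 1L))))
}
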