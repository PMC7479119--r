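# Two-component skew-normal mixture model of the CheZOD Z-score
# distribution and the conversion of predicted Z-scores with calibrated
# uncertainty into per-residue probabilities of disorder.

#' Skew-normal density
#'
#' Density of the skew-normal distribution with location `mu`, scale
#' `sigma` and skewness `alpha`:
#' `(2/sigma) * dnorm(z) * pnorm(alpha * z)` with `z = (x - mu)/sigma`.
#' With `alpha = 0` it reduces to the normal density.
#'
#' @param x Numeric vector of quantiles.
#' @param mu Location.
#' @param sigma Scale (> 0).
#' @param alpha Skewness.
#' @return Non-negative densities integrating to 1.
#' @export
#' @examples
#' dskewnorm(0, 0, 1, 0)  # dnorm(0)
dskewnorm <- function(x, mu = 0, sigma = 1, alpha = 0) {
  if (!(is.numeric(sigma) && all(sigma > 0))) stop("sigma must be > 0")
  z <- (x - mu) / sigma
  (2 / sigma) * stats::dnorm(z) * stats::pnorm(alpha * z)
}

#' Sample from a skew-normal distribution
#'
#' Uses the two-Gaussian representation
#' `z = delta * |u0| + sqrt(1 - delta^2) * u1`, `delta = alpha /
#' sqrt(1 + alpha^2)`, so the marginal is exactly skew-normal. Supplying
#' correlated standard-normal inputs `u0`, `u1` yields serially correlated
#' draws with the same marginal (used by the synthetic generator).
#'
#' @param n Number of draws (ignored when `u0`/`u1` are given).
#' @inheritParams dskewnorm
#' @param u0,u1 Optional standard-normal innovation vectors.
#' @return Numeric vector of draws.
#' @export
rskewnorm <- function(n, mu = 0, sigma = 1, alpha = 0, u0 = NULL,
                      u1 = NULL) {
  if (is.null(u0)) u0 <- stats::rnorm(n)
  if (is.null(u1)) u1 <- stats::rnorm(length(u0))
  delta <- alpha / sqrt(1 + alpha^2)
  mu + sigma * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
}

# mean of a skew-normal component
skewnorm_mean <- function(mu, sigma, alpha) {
  mu + sigma * alpha / sqrt(1 + alpha^2) * sqrt(2 / pi)
}

#' Construct a two-component disorder mixture
#'
#' The Z-score distribution is modelled as
#' `d(x) = f_D * psi(x; mu_D, sigma_D, alpha_D) + (1 - f_D) * psi(x; mu_O,
#' sigma_O, alpha_O)` with the disordered component located below the
#' ordered one.
#'
#' @param mu_d,sigma_d,alpha_d Disordered-component parameters.
#' @param mu_o,sigma_o,alpha_o Ordered-component parameters.
#' @param f_d Fraction of disordered residues, in (0, 1).
#' @return An object of class `disorder_mixture`.
#' @export
disorder_mixture <- function(mu_d, sigma_d, alpha_d, mu_o, sigma_o, alpha_o,
                             f_d) {
  stopifnot(sigma_d > 0, sigma_o > 0, f_d > 0, f_d < 1)
  if (skewnorm_mean(mu_d, sigma_d, alpha_d) >=
      skewnorm_mean(mu_o, sigma_o, alpha_o)) {
    stop("disordered component must lie below the ordered component")
  }
  structure(
    list(disordered = list(mu = mu_d, sigma = sigma_d, alpha = alpha_d),
         ordered = list(mu = mu_o, sigma = sigma_o, alpha = alpha_o),
         f_d = f_d),
    class = "disorder_mixture"
  )
}

#' @export
print.disorder_mixture <- function(x, ...) {
  cat(sprintf(
    "<disorder_mixture> f_D = %.4f\n  disordered: mu %.3f sigma %.3f alpha %.3f\n  ordered:    mu %.3f sigma %.3f alpha %.3f\n",
    x$f_d, x$disordered$mu, x$disordered$sigma, x$disordered$alpha,
    x$ordered$mu, x$ordered$sigma, x$ordered$alpha))
  invisible(x)
}

#' Mixture density
#'
#' @param x Numeric vector of Z-scores.
#' @param mixture A [disorder_mixture()].
#' @return Densities `f_D * psi_D(x) + (1 - f_D) * psi_O(x)`.
#' @export
dmixture <- function(x, mixture) {
  stopifnot(inherits(mixture, "disorder_mixture"))
  d <- mixture$disordered
  o <- mixture$ordered
  mixture$f_d * dskewnorm(x, d$mu, d$sigma, d$alpha) +
    (1 - mixture$f_d) * dskewnorm(x, o$mu, o$sigma, o$alpha)
}

# parameter vector <-> mixture, on an unconstrained scale
mix_par_pack <- function(m) {
  c(m$disordered$mu, log(m$disordered$sigma), m$disordered$alpha,
    m$ordered$mu, log(m$ordered$sigma), m$ordered$alpha,
    stats::qlogis(m$f_d))
}
mix_par_unpack <- function(p) {
  list(mu_d = p[1], sigma_d = exp(p[2]), alpha_d = p[3],
       mu_o = p[4], sigma_o = exp(p[5]), alpha_o = p[6],
       f_d = stats::plogis(p[7]))
}

mix_negloglik <- function(p, z) {
  q <- mix_par_unpack(p)
  if (!all(is.finite(unlist(q))) || q$sigma_d <= 0 || q$sigma_o <= 0) {
    return(1e12)  # reject numerically degenerate parameter points
  }
  dens <- q$f_d * dskewnorm(z, q$mu_d, q$sigma_d, q$alpha_d) +
    (1 - q$f_d) * dskewnorm(z, q$mu_o, q$sigma_o, q$alpha_o)
  -sum(log(pmax(dens, 1e-300)))
}

#' Fit the two-component skew-normal mixture by maximum likelihood
#'
#' Numerical maximum-likelihood fit with seeded multi-starts. Initial values
#' come from moments of the data split at Z = 8 (the order/disorder
#' threshold), jittered across restarts. The component with the lower mean
#' is labelled disordered. When the data are effectively single-component
#' the fitted weight is driven to a boundary; a weight above 0.999 (or
#' below 0.001) is flagged with a warning.
#'
#' @param zscores Numeric vector of Z-scores (at least 1000 values
#'   recommended for stable skewness estimates).
#' @param init Optional [disorder_mixture()] used as one starting point.
#' @param n_starts Number of multi-starts (default 5).
#' @param seed Seed for the start jitter.
#' @return The fitted [disorder_mixture()], with attributes `loglik` and
#'   `convergence`.
#' @export
fit_mixture <- function(zscores, init = NULL, n_starts = 5L, seed = 1L) {
  z <- zscores[is.finite(zscores)]
  if (length(z) < 10L) stop("need at least 10 finite Z-scores")
  lo <- z[z < 8]
  hi <- z[z >= 8]
  if (length(lo) < 2L) lo <- z[z <= stats::median(z)]
  if (length(hi) < 2L) hi <- z[z > stats::median(z)]
  base <- c(mean(lo), log(max(stats::sd(lo), 0.1)), 0,
            mean(hi), log(max(stats::sd(hi), 0.1)), 0,
            stats::qlogis(min(max(length(lo) / length(z), 0.01), 0.99)))
  starts <- list(base)
  if (!is.null(init)) starts <- c(starts, list(mix_par_pack(init)))
  withr::with_seed(seed, {
    while (length(starts) < n_starts) {
      jit <- base + stats::rnorm(7L, sd = c(0.5, 0.2, 1, 0.5, 0.2, 1, 0.3))
      starts[[length(starts) + 1L]] <- jit
    }
  })
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, mix_negloglik, z = z, method = "BFGS",
                   control = list(maxit = 500L)),
      error = function(e) NULL
    )
    if (is.null(fit) || !all(is.finite(fit$par))) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("mixture fit failed to converge from any start")
  q <- mix_par_unpack(best$par)
  # label components so that the disordered one has the lower mean
  m1 <- skewnorm_mean(q$mu_d, q$sigma_d, q$alpha_d)
  m2 <- skewnorm_mean(q$mu_o, q$sigma_o, q$alpha_o)
  if (m1 > m2) {
    q <- list(mu_d = q$mu_o, sigma_d = q$sigma_o, alpha_d = q$alpha_o,
              mu_o = q$mu_d, sigma_o = q$sigma_d, alpha_o = q$alpha_d,
              f_d = 1 - q$f_d)
  }
  q$f_d <- min(max(q$f_d, 1e-6), 1 - 1e-6)
  sep <- abs(skewnorm_mean(q$mu_d, q$sigma_d, q$alpha_d) -
               skewnorm_mean(q$mu_o, q$sigma_o, q$alpha_o))
  if (q$f_d > 0.99 || q$f_d < 0.01 || sep < 0.5 * stats::sd(z)) {
    warning("degenerate two-component fit (f_D = ",
            format(q$f_d, digits = 4), ", component separation ",
            format(sep, digits = 3), "); data look single-component")
  }
  out <- disorder_mixture(q$mu_d, q$sigma_d, q$alpha_d,
                          q$mu_o, q$sigma_o, q$alpha_o, q$f_d)
  attr(out, "loglik") <- -best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Hellinger distance between data and mixture
#'
#' Discrete Hellinger distance `sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2))`
#' between the binned empirical probability vector of the data and the
#' mixture's probability mass in the same bins (computed by quadrature of
#' the density). Both vectors are normalized over the binning range, so the
#' result lies in \[0, 1\]. The default binning uses width-0.5 bins over
#' \[-6, 17\].
#'
#' @param zscores Numeric Z-scores.
#' @param mixture A [disorder_mixture()].
#' @param breaks Numeric vector of bin edges (at least 3, i.e. 2 bins).
#' @return Distance in \[0, 1\].
#' @export
hellinger_distance <- function(zscores, mixture,
                               breaks = seq(-6, 17, by = 0.5)) {
  z <- zscores[is.finite(zscores)]
  if (length(z) == 0L) stop("no finite Z-scores")
  if (length(breaks) < 3L) stop("need at least 2 bins")
  breaks <- sort(breaks)
  counts <- graphics::hist(pmin(pmax(z, breaks[1]), breaks[length(breaks)]),
                           breaks = breaks, plot = FALSE)$counts
  p <- counts / sum(counts)
  q <- vapply(seq_len(length(breaks) - 1L), function(i) {
    stats::integrate(function(x) dmixture(x, mixture),
                     breaks[i], breaks[i + 1L],
                     rel.tol = 1e-8, stop.on.error = FALSE)$value
  }, numeric(1))
  q <- q / sum(q)
  hellinger_discrete(p, q)
}

#' @param p,q Probability vectors of equal length (each summing to 1).
#' @rdname hellinger_distance
#' @export
hellinger_discrete <- function(p, q) {
  stopifnot(length(p) == length(q))
  sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2))
}

#' Probability of disorder from a predicted Z-score
#'
#' Converts a predicted Z-score and its calibrated uncertainty into a
#' probability of disorder under the fitted mixture:
#' `p_D = pi_D / (pi_D + pi_O)` with
#' `pi_S = w_S * integral psi(Z; mu_S, sigma_S, alpha_S) *
#' phi((Z - Z_pred)/Z_err) dZ`, where the state weights are the reference
#' disordered fraction `w_D = f_Dref` and `w_O = 1 - f_Dref`. The integral
#' is evaluated on a fixed grid over Z in \[-25, 35\] with step 0.01 (the
#' Gaussian kernel's normalization cancels in the ratio). `Z_err = 0`
#' evaluates the closed-form limit
#' `w_D * psi_D(Z_pred) / (w_D * psi_D(Z_pred) + w_O * psi_O(Z_pred))`.
#'
#' @param z_pred Numeric vector of predicted Z-scores.
#' @param z_err Calibrated prediction errors (>= 0), scalar or vector.
#' @param mixture A fitted [disorder_mixture()].
#' @param f_dref Reference fraction of disordered residues (default 0.333).
#' @param grid_range,grid_step Quadrature grid for the integral.
#' @return Probabilities of disorder in \[0, 1\].
#' @export
disorder_probability <- function(z_pred, z_err, mixture, f_dref = 0.333,
                                 grid_range = c(-25, 35), grid_step = 0.01) {
  stopifnot(inherits(mixture, "disorder_mixture"),
            f_dref > 0, f_dref < 1)
  if (any(z_err < 0)) stop("z_err must be non-negative")
  n <- length(z_pred)
  z_err <- rep_len(z_err, n)
  d <- mixture$disordered
  o <- mixture$ordered
  w_d <- f_dref
  w_o <- 1 - f_dref
  out <- numeric(n)
  # kernels narrower than the grid resolution are numerically a point mass:
  # evaluate those (and z_err = 0) in the closed-form limit
  zero <- z_err < grid_step
  if (any(zero)) {
    pd <- w_d * dskewnorm(z_pred[zero], d$mu, d$sigma, d$alpha)
    po <- w_o * dskewnorm(z_pred[zero], o$mu, o$sigma, o$alpha)
    out[zero] <- pd / (pd + po)
  }
  if (any(!zero)) {
    grid <- seq(grid_range[1], grid_range[2], by = grid_step)
    psi_d <- dskewnorm(grid, d$mu, d$sigma, d$alpha)
    psi_o <- dskewnorm(grid, o$mu, o$sigma, o$alpha)
    idx <- which(!zero)
    for (i in idx) {
      kern <- stats::dnorm((grid - z_pred[i]) / z_err[i])
      pi_d <- w_d * sum(psi_d * kern)
      pi_o <- w_o * sum(psi_o * kern)
      out[i] <- pi_d / (pi_d + pi_o)
    }
  }
  out
}

#' Binary disorder call from a Z-score
#'
#' A residue is called disordered when its Z-score is strictly below the
#' threshold (default 8.0); residues at exactly the threshold are ordered.
#'
#' @param z Numeric vector of finite Z-scores.
#' @param threshold Order/disorder threshold (default 8.0).
#' @return Logical vector: `TRUE` = disordered.
#' @export
#' @examples
#' classify_disorder(c(7.9, 8, 8.1))
classify_disorder <- function(z, threshold = 8.0) {
  stopifnot(is.numeric(z))
  if (any(!is.finite(z))) stop("non-finite Z-score")
  z < threshold
}
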