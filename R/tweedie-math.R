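#' Gamma body-mass mark from moments
#'
#' Converts the moment parameterization of an individual prey body-mass
#' distribution (mean mass `w`, coefficient of variation `v`) into the
#' shape--scale parameterization of a gamma distribution. A prey item drawn
#' from `Gamma(shape = k, scale = theta)` with `k = v^-2` and `theta = w v^2`
#' has mean `w` and coefficient of variation `v`.
#'
#' @param w Mean individual prey mass (kg), strictly positive. Vectorized.
#' @param v Coefficient of variation of individual mass, strictly positive.
#'
#' @return A tibble with columns `w`, `v`, `k` (gamma shape) and `theta`
#'   (gamma scale, kg), one row per input element.
#'
#' @examples
#' gamma_mark(w = 1.2, v = 1)
#' @export
gamma_mark <- function(w, v) {
  if (!is.numeric(w) || !is.numeric(v) || any(!is.finite(w)) || any(!is.finite(v))) {
    rlang::abort("`w` and `v` must be finite numerics.", class = "dietglm_domain_error")
  }
  if (any(w <= 0) || any(v <= 0)) {
    rlang::abort("`w` and `v` must be strictly positive.", class = "dietglm_domain_error")
  }
  n <- max(length(w), length(v))
  w <- rep_len(w, n)
  v <- rep_len(v, n)
  tibble::tibble(w = w, v = v, k = v^-2, theta = w * v^2)
}

#' Compound Poisson-gamma to Tweedie parameters
#'
#' A sample's biomass of one prey is the sum of a Poisson(`lam`) number of
#' independent Gamma(`k`, `theta`) body masses. This compound Poisson-gamma
#' (CPG) variable is exactly Tweedie distributed with power `p` strictly
#' between 1 and 2:
#' \deqn{\mu = \lambda k \theta, \quad p = (k+2)/(k+1), \quad
#'       \phi = \theta (k+1) \mu^{-1/(k+1)},}
#' so that \eqn{Var(Y) = \phi \mu^p = \lambda k (k+1) \theta^2}.
#'
#' @param lam Poisson mean count of consumed prey items, strictly positive.
#'   A zero intensity gives a degenerate all-zero distribution which has no
#'   Tweedie representation (the Tweedie mean must be positive) and is
#'   signalled as an error.
#' @param k Gamma shape of the individual-mass mark, strictly positive.
#' @param theta Gamma scale of the individual-mass mark (kg), strictly
#'   positive.
#'
#' @return A tibble with columns `mu`, `phi`, `p`, one row per input element.
#' @seealso [tweedie_to_cpg()] for the exact inverse, [gamma_mark()] for the
#'   mark parameterization.
#' @examples
#' cpg_to_tweedie(lam = 1, k = 1, theta = 1.2)
#' @export
cpg_to_tweedie <- function(lam, k, theta) {
  n <- max(length(lam), length(k), length(theta))
  lam <- rep_len(lam, n)
  k <- rep_len(k, n)
  theta <- rep_len(theta, n)
  if (any(!is.finite(lam)) || any(lam < 0)) {
    rlang::abort("`lam` must be finite and non-negative.", class = "dietglm_domain_error")
  }
  if (any(lam == 0)) {
    rlang::abort(
      paste(
        "`lam` = 0 gives a degenerate (always-zero) biomass distribution",
        "with no Tweedie representation; handle empty intensities upstream."
      ),
      class = "dietglm_degenerate_error"
    )
  }
  if (any(k <= 0) || any(theta <= 0)) {
    rlang::abort("`k` and `theta` must be strictly positive.", class = "dietglm_domain_error")
  }
  mu <- lam * k * theta
  tibble::tibble(
    mu = mu,
    phi = theta * (k + 1) * mu^(-1 / (k + 1)),
    p = (k + 2) / (k + 1)
  )
}

#' Tweedie to compound Poisson-gamma parameters
#'
#' Exact algebraic inverse of [cpg_to_tweedie()]: recovers the latent Poisson
#' intensity and gamma mark of the compound representation,
#' \deqn{\lambda = \mu^{2-p} / (\phi (2-p)), \quad k = (2-p)/(p-1), \quad
#'       \theta = \phi (p-1) \mu^{p-1}.}
#'
#' @param mu Tweedie mean, strictly positive.
#' @param phi Tweedie scale (dispersion), strictly positive.
#' @param p Tweedie power, strictly inside (1, 2).
#'
#' @return A tibble with columns `lam`, `k`, `theta`.
#' @examples
#' tw <- cpg_to_tweedie(lam = 1, k = 1, theta = 1.2)
#' tweedie_to_cpg(tw$mu, tw$phi, tw$p)
#' @export
tweedie_to_cpg <- function(mu, phi, p) {
  n <- max(length(mu), length(phi), length(p))
  mu <- rep_len(mu, n)
  phi <- rep_len(phi, n)
  p <- rep_len(p, n)
  check_tweedie_params(mu, phi, p)
  tibble::tibble(
    lam = mu^(2 - p) / (phi * (2 - p)),
    k = (2 - p) / (p - 1),
    theta = phi * (p - 1) * mu^(p - 1)
  )
}

# p must be strictly interior to (1,2); the foraging derivation cannot reach
# the boundaries (k in (0, Inf)), and the series density assumes it.
check_tweedie_params <- function(mu, phi, p) {
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    rlang::abort("`mu` must be finite and strictly positive.", class = "dietglm_domain_error")
  }
  if (any(!is.finite(phi)) || any(phi <= 0)) {
    rlang::abort("`phi` must be finite and strictly positive.", class = "dietglm_domain_error")
  }
  if (any(!is.finite(p)) || any(p <= 1) || any(p >= 2)) {
    rlang::abort("`p` must lie strictly inside (1, 2).", class = "dietglm_domain_error")
  }
  invisible(TRUE)
}

# Interior buffer used wherever p is optimized.
.p_lower <- 1 + 1e-6
.p_upper <- 2 - 1e-6

#' Tweedie (compound Poisson-gamma) density
#'
#' Evaluates the Tweedie density for power 1 < p < 2 through its compound
#' Poisson-gamma representation. The point mass at zero is `exp(-lambda)`
#' with `lambda` the latent Poisson intensity; for y > 0 the density is the
#' series over the latent count N >= 1 of gamma-convolution densities,
#' \deqn{f(y) = e^{-\lambda} \sum_{n \ge 1} \frac{\lambda^n}{n!}
#'   \mathrm{dgamma}(y; nk, \theta),}
#' summed in log space with adaptive truncation: terms are accumulated from
#' n = 1 past the index maximizing the summand until they fall below 1e-12 of
#' the running sum.
#'
#' @param y Non-negative observed biomass. Vectorized; recycled against the
#'   parameters.
#' @inheritParams tweedie_to_cpg
#' @param log If `TRUE`, return the log density.
#'
#' @return Numeric vector of (log) densities. At `y = 0` this is the discrete
#'   zero mass, not a density.
#' @examples
#' dtweedie_cpg(c(0, 0.5, 2), mu = 1.2, phi = 1.5, p = 1.5)
#' @export
dtweedie_cpg <- function(y, mu, phi, p, log = FALSE) {
  n <- max(length(y), length(mu), length(phi), length(p))
  y <- rep_len(y, n)
  mu <- rep_len(mu, n)
  phi <- rep_len(phi, n)
  p <- rep_len(p, n)
  check_tweedie_params(mu, phi, p)
  if (any(y < 0)) {
    rlang::abort("`y` must be non-negative.", class = "dietglm_domain_error")
  }
  cpg <- tweedie_to_cpg(mu, phi, p)
  out <- numeric(n)
  zero <- y == 0
  out[zero] <- -cpg$lam[zero]
  if (any(!zero)) {
    out[!zero] <- cpg_series_logpdf(
      y[!zero], cpg$lam[!zero], cpg$k[!zero], cpg$theta[!zero]
    )
  }
  if (log) out else exp(out)
}

# Log series density for y > 0, vectorized over observations. The summand
# over n peaks near n* = y^(2-p)/(phi(2-p)) = y/(k*theta) * k/(k+1)-ish; we
# sum a common 1..J band in log space, growing J until every row's tail term
# is negligible (< peak - 36 on the log scale, i.e. < 1e-12 relative, the
# adaptive-truncation tolerance adopted throughout).
cpg_series_logpdf <- function(y, lam, k, theta) {
  stopifnot(all(y > 0))
  n <- length(y)
  log_lam <- log(lam)
  log_y <- log(y)
  log_theta <- log(theta)
  y_over_theta <- y / theta
  scalar_k <- length(unique(k)) == 1L
  # crude peak index of the summand per observation
  n_peak <- pmax(1, y / (theta * k) * k / (k + 1))
  J <- max(ceiling(max(n_peak)) + 25L, 40L)
  repeat {
    js <- seq_len(J)
    # terms[i, j] = log{ lam_i^j / j! * dgamma(y_i; j k_i, theta_i) }
    if (scalar_k) {
      k1 <- k[1]
      slope <- log_lam + k1 * (log_y - log_theta)      # per-row linear rate in j
      const_j <- -lgamma(js + 1) - lgamma(js * k1)     # shared across rows
      terms <- outer(slope, js) +
        matrix(const_j, n, J, byrow = TRUE) - log_y - y_over_theta
    } else {
      terms <- outer(log_lam, js, `*`) - rep(lgamma(js + 1), each = n) +
        (outer(k * log_y - k * log_theta, js, `*`)) - log_y -
        lgamma(outer(k, js, `*`)) - y_over_theta
    }
    row_max <- terms[cbind(seq_len(n), max.col(terms, ties.method = "first"))]
    tail_gap <- row_max - terms[, J]
    if (all(tail_gap > 36) || J > 1e5) break
    J <- J * 2L
  }
  -lam + row_max + log(rowSums(exp(terms - row_max)))
}

#' Tweedie (compound Poisson-gamma) distribution function
#'
#' Cumulative distribution by the same latent-count series as
#' [dtweedie_cpg()]: `P(Y <= y) = exp(-lambda) + sum_n Pois(n; lambda)
#' pgamma(y; n k, theta)`.
#'
#' @inheritParams dtweedie_cpg
#' @return Numeric vector of probabilities.
#' @export
ptweedie_cpg <- function(y, mu, phi, p) {
  n <- max(length(y), length(mu), length(phi), length(p))
  y <- rep_len(y, n)
  mu <- rep_len(mu, n)
  phi <- rep_len(phi, n)
  p <- rep_len(p, n)
  check_tweedie_params(mu, phi, p)
  cpg <- tweedie_to_cpg(mu, phi, p)
  purrr::pmap_dbl(
    list(y, cpg$lam, cpg$k, cpg$theta),
    function(yi, lam, k, theta) {
      if (yi < 0) return(0)
      jmax <- ceiling(lam + 10 * sqrt(lam) + 25)
      js <- seq_len(jmax)
      sum(stats::dpois(js, lam) * stats::pgamma(yi, shape = js * k, scale = theta)) +
        exp(-lam)
    }
  )
}

#' Probability of an empty sample
#'
#' The Tweedie distribution on 1 < p < 2 places a point mass at zero equal to
#' the probability that the latent Poisson count of consumed prey items is
#' zero: `exp(-mu^(2-p) / (phi (2-p)))`.
#'
#' @inheritParams tweedie_to_cpg
#' @return Probability in (0, 1), vectorized.
#' @examples
#' prob_zero(mu = 1.2, phi = 2.19, p = 1.5)
#' @export
prob_zero <- function(mu, phi, p) {
  check_tweedie_params(mu, phi, p)
  exp(-mu^(2 - p) / (phi * (2 - p)))
}

#' Simulate Tweedie biomass by compound Poisson-gamma composition
#'
#' Draws each observation as the sum of a Poisson(`lambda`) number of
#' independent Gamma(`k`, `theta`) body masses; the sum of `N` gamma variables
#' sharing a scale is Gamma(`N k`, `theta`), so the draw is exact.
#'
#' @param n Number of draws.
#' @inheritParams tweedie_to_cpg
#' @param seed Optional integer seed. When supplied the draw is made inside
#'   [withr::with_seed()] so it is reproducible without touching the global
#'   random-number state.
#'
#' @return Numeric vector of length `n` of non-negative biomasses.
#' @examples
#' simulate_tweedie(5, mu = 1.2, phi = 2.19, p = 1.5, seed = 1)
#' @export
simulate_tweedie <- function(n, mu, phi, p, seed = NULL) {
  check_tweedie_params(mu, phi, p)
  cpg <- tweedie_to_cpg(mu, phi, p)
  draw <- function() {
    counts <- stats::rpois(n, rep_len(cpg$lam, n))
    y <- numeric(n)
    pos <- counts > 0
    if (any(pos)) {
      y[pos] <- stats::rgamma(
        sum(pos),
        shape = counts[pos] * rep_len(cpg$k, n)[pos],
        scale = rep_len(cpg$theta, n)[pos]
      )
    }
    y
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
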