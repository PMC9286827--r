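#' Simulate a diet dataset from the stacked Tweedie GLM
#'
#' Generates long-format diet records exactly from the fitted model: each
#' sample carries covariates, the log mean of category `c` in sample `i` is
#' `beta_0c + sum_k beta_kc x_ik`, and responses are Tweedie draws with
#' common scale `phi` and power `p`. A truth sidecar records the generating
#' parameters and the true proportions at every sample, so recovery tests
#' never re-derive truth from internals.
#'
#' @param n_samples Number of samples.
#' @param n_categories Number of prey categories.
#' @param beta Coefficient matrix, `n_categories` x (1 + n_covariates):
#'   first column the per-category intercepts, remaining columns the
#'   per-category slopes.
#' @param phi,p True Tweedie scale and power.
#' @param covariate_fn Function of `n_samples` returning a tibble of
#'   covariates (one row per sample); defaults to a single standard-normal
#'   covariate `x`.
#' @param seed Integer seed (mandatory for reproducibility).
#'
#' @return A list of class `diet_simulation`: `data` (tibble `sample_id`,
#'   `group`, `response`, covariates) and `truth` (`beta`, `phi`, `p`, and
#'   tibble `pi` of true proportions per sample).
#' @export
gen_glm_dataset <- function(n_samples, n_categories, beta, phi = 1, p = 1.6,
                            covariate_fn = NULL, seed) {
  beta <- as.matrix(beta)
  if (nrow(beta) != n_categories) {
    rlang::abort("`beta` must have one row per category.", class = "dietglm_domain_error")
  }
  check_tweedie_params(1, phi, p)
  if (is.null(covariate_fn)) {
    covariate_fn <- function(n) tibble::tibble(x = stats::rnorm(n))
  }
  withr::with_seed(seed, {
    covs <- tibble::as_tibble(covariate_fn(n_samples))
    n_cov <- ncol(beta) - 1
    if (ncol(covs) < n_cov) {
      rlang::abort("`covariate_fn` returned fewer covariates than `beta` columns.",
                   class = "dietglm_domain_error")
    }
    covs <- covs[, seq_len(max(n_cov, 1)), drop = FALSE]
    if (n_cov == 0) covs <- covs[, 0, drop = FALSE]
    groups <- paste0("prey_", seq_len(n_categories))
    Xs <- cbind(1, as.matrix(covs))
    eta <- Xs %*% t(beta)          # n_samples x n_categories
    mu <- exp(eta)
    data <- tidyr::expand_grid(
      sample_id = paste0("s", seq_len(n_samples)),
      group = groups
    )
    mu_vec <- as.vector(t(mu))     # matches expand_grid row order
    data$response <- simulate_tweedie(length(mu_vec), mu_vec, phi, p)
    data <- dplyr::bind_cols(
      data,
      covs[rep(seq_len(n_samples), each = n_categories), , drop = FALSE]
    )
    pi_true <- mu / rowSums(mu)
    colnames(pi_true) <- groups
    truth_pi <- dplyr::bind_cols(
      tibble::tibble(sample_id = paste0("s", seq_len(n_samples))),
      tibble::as_tibble(pi_true)
    )
    structure(
      list(data = data,
           truth = list(beta = beta, phi = phi, p = p, groups = groups,
                        pi = truth_pi)),
      class = "diet_simulation"
    )
  })
}

#' Simulate a provisioning time series of diet samples
#'
#' Emulates the shape of a multi-decade seabird chick-provisioning series:
#' one continuous environmental covariate per year (an AR(1)
#' sea-surface-temperature-like anomaly), per-category log-linear covariate
#' effects, and a smooth per-category year trend realized as a fixed
#' sinusoid. Responses are Tweedie biomasses; several samples are taken per
#' year. The default span of 37 years matches a 1982-2018-style series.
#'
#' @param n_years Number of years (>= 3); default 37.
#' @param n_categories Number of prey categories.
#' @param sst_effect Numeric vector (length `n_categories`) of per-category
#'   log-linear effects of the covariate.
#' @param samples_per_year Samples collected each year.
#' @param phi,p True Tweedie scale and power.
#' @param trend_amplitude Amplitude of the sinusoidal per-category year
#'   trend on the log scale.
#' @param seed Integer seed.
#'
#' @return A `diet_simulation` list; `data` has columns `sample_id`,
#'   `group`, `response`, `year`, `sst`.
#' @export
gen_timeseries_diet <- function(n_years = 37, n_categories = 4,
                                sst_effect = NULL, samples_per_year = 10,
                                phi = 1, p = 1.6, trend_amplitude = 0.6,
                                seed) {
  if (n_years < 3) {
    rlang::abort("`n_years` must be >= 3.", class = "dietglm_domain_error")
  }
  if (is.null(sst_effect)) {
    sst_effect <- seq(-0.5, 0.5, length.out = n_categories)
  }
  withr::with_seed(seed, {
    rho <- 0.6
    innov <- stats::rnorm(n_years, sd = sqrt(1 - rho^2))
    sst <- as.numeric(stats::filter(innov, rho, method = "recursive"))
    groups <- paste0("prey_", seq_len(n_categories))
    years <- seq_len(n_years)
    phase <- 2 * pi * seq_len(n_categories) / n_categories
    period <- max(n_years / 2, 8)
    log_mu <- outer(years, seq_len(n_categories), function(t, c) {
      trend_amplitude * sin(2 * pi * t / period + phase[c]) +
        sst[t] * sst_effect[c]
    })
    mu <- exp(log_mu)  # n_years x n_categories
    grid <- tidyr::expand_grid(year = years, rep = seq_len(samples_per_year),
                               group = groups)
    mu_vec <- mu[cbind(grid$year, match(grid$group, groups))]
    grid$response <- simulate_tweedie(nrow(grid), mu_vec, phi, p)
    data <- tibble::tibble(
      sample_id = paste0("y", grid$year, "_r", grid$rep),
      group = grid$group,
      response = grid$response,
      year = grid$year,
      sst = sst[grid$year]
    )
    pi_true <- mu / rowSums(mu)
    colnames(pi_true) <- groups
    truth_pi <- dplyr::bind_cols(tibble::tibble(year = years, sst = sst),
                                 tibble::as_tibble(pi_true))
    structure(
      list(data = data,
           truth = list(sst_effect = sst_effect, phi = phi, p = p,
                        groups = groups, pi = truth_pi)),
      class = "diet_simulation"
    )
  })
}

#' Simulate spatially indexed diet samples
#'
#' Emulates scat-sample diet data across a landscape: sample locations are
#' uniform on the unit square, each prey category has a smooth intensity
#' surface built from two-dimensional Gaussian bumps, and responses are
#' Tweedie biomasses. With the default single bump per category the log
#' intensity is exactly quadratic in the coordinates, so a GLM with a
#' user-supplied quadratic spatial basis (`x`, `y`, `x^2`, `y^2`, `xy`) is
#' correctly specified -- the configuration used for end-to-end recovery
#' checks. More bumps per category give surfaces a quadratic basis can only
#' approximate.
#'
#' @param n_sites Number of sample locations (>= 10).
#' @param n_categories Number of prey categories.
#' @param n_bumps Gaussian bumps per category surface (default 1).
#' @param bump_sd Standard deviation of each bump (shared).
#' @param peak_mu Peak expected biomass (kg) at a bump center.
#' @param phi,p True Tweedie scale and power.
#' @param seed Integer seed.
#'
#' @return A `diet_simulation` list; `data` has columns `sample_id`,
#'   `group`, `response`, `x`, `y`, `x2`, `y2`, `xy` (the quadratic basis is
#'   included ready for fitting). The truth sidecar carries the bump
#'   configuration and true proportions at every site.
#' @export
gen_spatial_diet <- function(n_sites, n_categories = 3, n_bumps = 1,
                             bump_sd = 0.45, peak_mu = 2, phi = 0.5, p = 1.5,
                             seed) {
  if (n_sites < 10) {
    rlang::abort("`n_sites` must be >= 10.", class = "dietglm_domain_error")
  }
  withr::with_seed(seed, {
    groups <- paste0("prey_", seq_len(n_categories))
    # bump centers: spread around a circle inside the unit square, jittered
    centers <- purrr::map(seq_len(n_categories), function(c) {
      ang <- 2 * pi * (c - 1) / n_categories + 2 * pi * (seq_len(n_bumps) - 1) /
        max(n_bumps * n_categories, 1)
      cbind(0.5 + 0.3 * cos(ang) + stats::rnorm(n_bumps, sd = 0.03),
            0.5 + 0.3 * sin(ang) + stats::rnorm(n_bumps, sd = 0.03))
    })
    heights <- purrr::map(seq_len(n_categories), function(c) {
      rep(peak_mu, n_bumps) * stats::runif(n_bumps, 0.8, 1.2)
    })
    surface_mu <- function(x, y) {
      vapply(seq_len(n_categories), function(c) {
        rowSums(vapply(seq_len(n_bumps), function(m) {
          heights[[c]][m] * exp(-((x - centers[[c]][m, 1])^2 +
                                    (y - centers[[c]][m, 2])^2) /
                                  (2 * bump_sd^2))
        }, numeric(length(x))))
      }, numeric(length(x)))
    }
    x <- stats::runif(n_sites)
    y <- stats::runif(n_sites)
    mu <- surface_mu(x, y)  # n_sites x n_categories
    grid <- tidyr::expand_grid(site = seq_len(n_sites), group = groups)
    mu_vec <- mu[cbind(grid$site, match(grid$group, groups))]
    grid$response <- simulate_tweedie(nrow(grid), mu_vec, phi, p)
    data <- tibble::tibble(
      sample_id = paste0("site_", grid$site),
      group = grid$group,
      response = grid$response,
      x = x[grid$site], y = y[grid$site]
    ) |>
      dplyr::mutate(x2 = .data$x^2, y2 = .data$y^2, xy = .data$x * .data$y)
    pi_true <- mu / rowSums(mu)
    colnames(pi_true) <- groups
    truth_pi <- dplyr::bind_cols(
      tibble::tibble(sample_id = paste0("site_", seq_len(n_sites)), x = x, y = y),
      tibble::as_tibble(pi_true)
    )
    structure(
      list(data = data,
           truth = list(centers = centers, heights = heights,
                        bump_sd = bump_sd, phi = phi, p = p, groups = groups,
                        pi = truth_pi)),
      class = "diet_simulation"
    )
  })
}

#' @export
print.diet_simulation <- function(x, ...) {
  cat("Simulated diet dataset:", nrow(x$data), "records,",
      length(unique(x$data$group)), "categories\n")
  print(utils::head(x$data, 6))
  invisible(x)
}

#' Write a simulated dataset to CSV with a JSON truth sidecar
#'
#' @param sim A `diet_simulation` from one of the generators.
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_diet_csv <- function(sim, path) {
  utils::write.csv(sim$data, path, row.names = FALSE)
  truth <- sim$truth
  truth$pi <- as.list(truth$pi)
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Read long-format diet records from CSV
#'
#' @param path CSV with columns `sample_id`, `group`, `response`, then
#'   covariates.
#' @return A tibble.
#' @export
read_diet_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("sample_id", "group", "response")
  if (!all(need %in% names(out))) {
    rlang::abort("CSV must contain columns sample_id, group, response.",
                 class = "dietglm_domain_error")
  }
  out
}
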