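#' Tidy a Tweedie diet GLM
#'
#' One row per coefficient: the model term, the prey category it belongs to
#' (`NA` for shared terms and sample offsets), the estimate, its standard
#' error, the Wald statistic and two-sided normal p-value. Coefficients of
#' categories with no positive biomass (separation) report `NA` standard
#' errors.
#'
#' @param x A [tweedie_glm()] fit.
#' @param ... Unused.
#' @return A tibble with columns `term`, `group`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy dietglm
#' @export
tidy.dietglm <- function(x, ...) {
  se <- sqrt(pmax(diag(x$cov_beta), 0))
  se[x$boundary] <- NA_real_
  stat <- x$beta / se
  tibble::tibble(
    term = x$coef_map$term,
    group = x$coef_map$group,
    estimate = unname(x$beta),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * stats::pnorm(-abs(stat)))
  )
}

#' Glance at a Tweedie diet GLM
#'
#' @param x A [tweedie_glm()] fit.
#' @param ... Unused.
#' @return A one-row tibble: `phi`, `p`, `p.profiled`, `logLik`, `nobs`,
#'   `n.groups`, `n.coefficients`, `converged`, `iterations`.
#' @method glance dietglm
#' @export
glance.dietglm <- function(x, ...) {
  tibble::tibble(
    phi = x$phi,
    p = x$p,
    p.profiled = identical(x$spec$power, "profile"),
    logLik = x$loglik,
    nobs = x$n_obs,
    n.groups = length(x$groups),
    n.coefficients = length(x$beta),
    converged = x$converged,
    iterations = x$iterations
  )
}
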