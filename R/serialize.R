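#' Serialize a fitted diet GLM to JSON
#'
#' Writes everything prediction needs -- coefficients, their covariance, the
#' scale and power estimates, the model spec, category and sample levels,
#' and training covariate means -- so a fit can be reloaded in a later
#' session or another process.
#'
#' @param fit A [tweedie_glm()] fit.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    beta = as.list(fit$beta),
    cov_beta = unname(as.matrix(fit$cov_beta)),
    phi = fit$phi, p = fit$p, loglik = fit$loglik,
    n_obs = fit$n_obs, converged = fit$converged,
    iterations = fit$iterations,
    boundary = fit$boundary,
    spec = fit$spec[c("covariates", "shared", "alpha", "alpha_covariates", "power")],
    coef_map = fit$coef_map,
    groups = fit$groups, samples = fit$samples,
    columns = fit$columns,
    covariate_means = fit$covariate_means
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}

#' Reload a fitted diet GLM from JSON
#'
#' @param path A JSON file written by [write_fit_json()].
#' @return A `dietglm` object usable with [predict_mu()],
#'   [predict_composition()], [composition_curve()], [tidy()] and
#'   [glance()].
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(x$beta)
  spec <- diet_spec(
    covariates = as.character(x$spec$covariates %||% character()),
    shared = as.character(x$spec$shared %||% character()),
    alpha = x$spec$alpha,
    alpha_covariates = if (length(x$spec$alpha_covariates)) as.character(x$spec$alpha_covariates),
    power = if (is.numeric(x$spec$power)) x$spec$power else "profile"
  )
  cov_beta <- matrix(as.numeric(x$cov_beta), nrow = length(beta))
  dimnames(cov_beta) <- list(names(beta), names(beta))
  structure(
    list(
      beta = beta, cov_beta = cov_beta, phi = x$phi, p = x$p,
      loglik = x$loglik, n_obs = x$n_obs, converged = x$converged,
      iterations = x$iterations, profile = NULL,
      boundary = as.logical(x$boundary),
      spec = spec, coef_map = tibble::as_tibble(x$coef_map),
      groups = as.character(x$groups), samples = as.character(x$samples),
      columns = x$columns,
      covariate_means = tibble::as_tibble(x$covariate_means),
      trace = NULL, fitted = NULL
    ),
    class = "dietglm"
  )
}
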