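#' Diet proportions from per-category means
#'
#' The predicted proportion of prey `c` is its expected biomass over the
#' total, `pi_c = mu_c / sum(mu)`. The softmax is invariant to scaling all
#' means by a common positive constant, so sample-level intercepts (area
#' swept times thinning rate) and the scale and power parameters never
#' affect proportions.
#'
#' @param mu Strictly positive numeric vector of per-category means
#'   (>= 2 categories).
#' @return Numeric vector of proportions summing to one.
#' @examples
#' proportions_from_mu(c(1, 2, 2))
#' @export
proportions_from_mu <- function(mu) {
  if (length(mu) < 2) {
    rlang::abort("Need at least two categories.", class = "dietglm_domain_error")
  }
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    rlang::abort("All `mu` must be finite and strictly positive.",
                 class = "dietglm_domain_error")
  }
  mu / sum(mu)
}

#' Total biomass and proportions reparameterization
#'
#' Exact bijection between the per-category mean vector and the pair (total
#' expected biomass, diet proportions): `total = sum(mu)`, `pi = mu / total`,
#' with inverse `mu = total * pi`.
#'
#' @inheritParams proportions_from_mu
#' @param mu Strictly positive numeric vector (a single category is allowed
#'   here; its proportion is 1).
#' @return A list with `total` (scalar) and `pi` (vector summing to one).
#' @examples
#' reparameterize_total(c(1, 2, 2))
#' @export
reparameterize_total <- function(mu) {
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    rlang::abort("All `mu` must be finite and strictly positive.",
                 class = "dietglm_domain_error")
  }
  total <- sum(mu)
  list(total = total, pi = mu / total)
}

#' Predicted diet composition with standard errors
#'
#' Back-transforms the fitted linear predictors at each covariate setting
#' into per-category proportions, with delta-method standard errors: writing
#' `eta_c` for the linear predictor of category `c` and `pi = softmax(eta)`,
#' the gradient `d pi_c / d eta_c' = pi_c (1{c = c'} - pi_c')` is chain-ruled
#' through the design rows and sandwiched with the coefficient covariance.
#' Because shared (sample-level) terms add the same constant to every
#' `eta_c`, they cancel exactly in `pi`.
#'
#' @param fit A [tweedie_glm()] fit.
#' @param newdata Tibble with one row per covariate setting (no category
#'   column; predictions are expanded over all fitted categories). If
#'   omitted, the training covariate means are used.
#' @param se How to report uncertainty: `"delta"` (default) gives the
#'   delta-method standard error of the proportion itself; `"link"`
#'   additionally reports the standard error of `log(pi_c)` and the
#'   asymmetric interval obtained by exponentiating +/- 1.96 of it
#'   (`conf.low`, `conf.high`); `"none"` skips standard errors.
#'
#' @return A tibble with the covariate columns, `group`, `proportion`, and
#'   (unless `se = "none"`) `se`.
#' @export
predict_composition <- function(fit, newdata = NULL,
                                se = c("delta", "link", "none")) {
  se <- rlang::arg_match(se)
  if (is.null(newdata)) newdata <- fit$covariate_means
  newdata <- tibble::as_tibble(newdata)
  gcol <- fit$columns$group
  if (gcol %in% names(newdata)) {
    rlang::abort(
      paste0("`newdata` must not contain the category column `", gcol,
             "`; one row per covariate setting."),
      class = "dietglm_spec_error"
    )
  }
  have_cov <- !is.null(fit$cov_beta)
  if (!have_cov && se != "none") {
    rlang::warn("Coefficient covariance unavailable; returning proportions without standard errors.")
    se <- "none"
  }
  nc <- length(fit$groups)
  rows <- purrr::map_dfr(seq_len(max(nrow(newdata), 1L)), function(i) {
    nd <- newdata[i, , drop = FALSE]
    expanded <- dplyr::bind_cols(
      nd[rep(1L, nc), , drop = FALSE],
      stats::setNames(tibble::tibble(fit$groups), gcol)
    )
    X <- design_rows(fit, expanded)
    eta <- drop(X %*% fit$beta)
    eta_c <- eta - max(eta)
    pi <- exp(eta_c) / sum(exp(eta_c))
    out <- dplyr::bind_cols(expanded, tibble::tibble(proportion = pi))
    if (se != "none") {
      G <- (diag(pi) - tcrossprod(pi)) %*% X   # d pi / d beta, nc x nbeta
      V <- G %*% fit$cov_beta %*% t(G)
      out$se <- sqrt(pmax(diag(V), 0))
      if (se == "link") {
        # delta method on log(pi_c): d log pi_c / d beta = G[c, ] / pi_c
        se_log <- sqrt(pmax(diag(V), 0)) / pi
        out$se_log <- se_log
        out$conf.low <- pi * exp(-1.96 * se_log)
        out$conf.high <- pi * exp(1.96 * se_log)
      }
    }
    out
  })
  names(rows)[names(rows) == gcol] <- "group"
  rows
}

#' Composition along a covariate grid
#'
#' Predicted diet proportions (with standard errors) along a grid of one
#' focal covariate, holding every other covariate at supplied reference
#' values (defaulting to training means). The result is ready for plotting
#' proportion +/- SE against the covariate.
#'
#' @param fit A [tweedie_glm()] fit.
#' @param covariate Name of the focal covariate.
#' @param grid Numeric grid of focal-covariate values; defaults to 25 points
#'   spanning the training range of the covariate when available, else
#'   -2..2.
#' @param at Optional one-row tibble of reference values for the non-focal
#'   covariates.
#' @inheritParams predict_composition
#'
#' @return A tibble of class `composition_curve`; the reference values used
#'   are attached as attribute `"at"`.
#' @export
composition_curve <- function(fit, covariate, grid = NULL, at = NULL,
                              se = c("delta", "link", "none")) {
  se <- rlang::arg_match(se)
  all_cov <- names(fit$covariate_means)
  if (!covariate %in% all_cov) {
    rlang::abort(paste0("`", covariate, "` is not a covariate of the fit."),
                 class = "dietglm_spec_error")
  }
  if (is.null(grid)) grid <- seq(-2, 2, length.out = 25)
  base <- fit$covariate_means
  if (!is.null(at)) {
    at <- tibble::as_tibble(at)
    for (nm in names(at)) base[[nm]] <- at[[nm]]
  }
  newdata <- base[rep(1L, length(grid)), , drop = FALSE]
  newdata[[covariate]] <- grid
  out <- predict_composition(fit, newdata, se = se)
  attr(out, "at") <- base[setdiff(all_cov, covariate)]
  attr(out, "covariate") <- covariate
  class(out) <- c("composition_curve", class(out))
  out
}

#' Plot a composition curve
#'
#' Proportion against the focal covariate, one panel per prey category, with
#' a +/- one-standard-error ribbon when standard errors are present.
#'
#' @param object A [composition_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot composition_curve
#' @export
autoplot.composition_curve <- function(object, ...) {
  covariate <- attr(object, "covariate")
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[covariate]], y = .data$proportion)) +
    ggplot2::facet_wrap(~group) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = covariate, y = "Predicted diet proportion") +
    ggplot2::theme_minimal()
  if ("se" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$proportion - .data$se, 0),
                   ymax = pmin(.data$proportion + .data$se, 1)),
      alpha = 0.25, fill = "steelblue"
    )
  }
  p
}

#' Plot the per-cell biomass distributions of a foraging experiment
#'
#' Histograms of the positive biomass draws in each (site, species) cell
#' with the empirical zero fraction annotated, mirroring the layout of a
#' sampling-distribution comparison.
#'
#' @param object A [run_foraging_experiment()] result.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot foraging_experiment
#' @export
autoplot.foraging_experiment <- function(object, bins = 25, ...) {
  pos <- dplyr::filter(object$draws, .data$y > 0)
  zf <- dplyr::mutate(
    object$cells,
    label = sprintf("P(0) = %.2f", .data$zero_frac)
  )
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$y)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60") +
    ggplot2::facet_grid(site ~ species, scales = "free") +
    ggplot2::geom_text(
      data = zf, ggplot2::aes(label = .data$label),
      x = Inf, y = Inf, hjust = 1.1, vjust = 1.5, size = 3, inherit.aes = FALSE
    ) +
    ggplot2::labs(x = "Biomass per sample (kg)", y = "Replicates") +
    ggplot2::theme_minimal()
}
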