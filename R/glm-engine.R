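#' Model specification for a diet GLM
#'
#' Describes the linear predictor of the log-link Tweedie GLM for stacked
#' diet data, `log mu_ic = alpha_i + sum_k beta_kc x_ik`: which covariates
#' interact with the prey category (their slopes differ by prey), which are
#' shared across categories, and how the sample-level intercept `alpha_i`
#' (the confounded product of area swept and thinning rate) is handled.
#'
#' @param covariates Character vector of covariate names whose effects are
#'   estimated separately for each prey category (category interactions).
#' @param shared Character vector of covariate names with a single effect
#'   common to all categories. Shared terms shift every category's linear
#'   predictor equally and therefore cancel in predicted proportions.
#' @param alpha How the sample intercept is handled: `"shared"` (a common
#'   intercept, absorbed into the per-category intercepts), `"sample"` (one
#'   fixed offset per sample, first sample as reference -- the
#'   multinomial-Poisson configuration), or `"covariate"` (model
#'   `alpha_i` through the covariates named in `alpha_covariates`).
#' @param alpha_covariates Covariate names modelling `alpha_i` when
#'   `alpha = "covariate"`; entered as shared columns.
#' @param power Either the string `"profile"` (estimate the Tweedie power
#'   `p` by profiled maximum likelihood) or a fixed numeric value in (1, 2).
#'
#' @return An object of class `diet_spec`.
#' @examples
#' diet_spec(covariates = "sst", power = "profile")
#' @export
diet_spec <- function(covariates = character(), shared = character(),
                      alpha = c("shared", "sample", "covariate"),
                      alpha_covariates = NULL, power = "profile") {
  alpha <- rlang::arg_match(alpha)
  if (alpha == "covariate" && length(alpha_covariates) == 0) {
    rlang::abort("`alpha = \"covariate\"` requires `alpha_covariates`.",
                 class = "dietglm_spec_error")
  }
  if (is.numeric(power)) {
    if (power <= 1 || power >= 2) {
      rlang::abort("A fixed `power` must lie strictly inside (1, 2).",
                   class = "dietglm_spec_error")
    }
  } else if (!identical(power, "profile")) {
    rlang::abort("`power` must be \"profile\" or a numeric in (1, 2).",
                 class = "dietglm_spec_error")
  }
  if (length(intersect(covariates, shared)) > 0) {
    rlang::abort("A covariate cannot be both category-interacted and shared.",
                 class = "dietglm_spec_error")
  }
  structure(
    list(covariates = covariates, shared = shared, alpha = alpha,
         alpha_covariates = alpha_covariates, power = power),
    class = "diet_spec"
  )
}

#' Stack a wide sample-by-category matrix into long diet records
#'
#' The stacked regression fits all prey categories at once on the vector
#' formed by stacking the columns of the sample-by-category response matrix
#' (column-major order, first category's samples first). Per-sample
#' covariates are replicated across the categories of each sample.
#'
#' @param Y Numeric matrix, samples x categories. Rows are samples, columns
#'   prey categories; dimnames are used as identifiers when present. Cells
#'   where a prey was absent must be explicit zeros, not `NA`.
#' @param covariates Optional data frame of per-sample covariates (one row
#'   per row of `Y`).
#'
#' @return A tibble with columns `sample_id`, `group`, `response`, then the
#'   covariates, ordered column-major in `Y`.
#' @export
stack_diet_matrix <- function(Y, covariates = NULL) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) {
    rlang::abort(
      "`Y` contains missing cells; prey absent from a sample must be recorded as explicit zeros.",
      class = "dietglm_domain_error"
    )
  }
  samples <- rownames(Y) %||% as.character(seq_len(nrow(Y)))
  groups <- colnames(Y) %||% paste0("category_", seq_len(ncol(Y)))
  out <- tibble::tibble(
    sample_id = rep(samples, times = ncol(Y)),
    group = rep(groups, each = nrow(Y)),
    response = as.vector(Y)
  )
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    if (nrow(covariates) != nrow(Y)) {
      rlang::abort("`covariates` must have one row per sample.",
                   class = "dietglm_domain_error")
    }
    out <- dplyr::bind_cols(
      out,
      covariates[rep(seq_len(nrow(Y)), times = ncol(Y)), , drop = FALSE]
    )
  }
  out
}

#' Build the stacked design matrix for a diet GLM
#'
#' Constructs per-category intercept columns, per-category slopes for
#' interacted covariates, single columns for shared covariates, and sample
#' offsets or alpha covariates per the spec. Checks full column rank and
#' names the offending columns otherwise.
#'
#' @param data Long-format diet data (see [stack_diet_matrix()]).
#' @param spec A [diet_spec()].
#' @param response,sample,group Column names in `data`.
#'
#' @return A list: `X` (design matrix), `coef_map` (tibble with `column`,
#'   `term`, `group`), `groups`, `samples`.
#' @export
build_design <- function(data, spec, response = "response",
                         sample = "sample_id", group = "group") {
  needed <- c(sample, group, response, spec$covariates, spec$shared,
              if (spec$alpha == "covariate") spec$alpha_covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Missing columns in `data`: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "dietglm_spec_error")
  }
  g <- data[[group]]
  groups <- if (is.factor(g)) levels(g) else unique(as.character(g))
  g <- as.character(g)
  s <- as.character(data[[sample]])
  samples <- unique(s)
  n <- nrow(data)

  cols <- list()
  map <- list()
  for (lev in groups) {
    cols[[paste0("intercept:", lev)]] <- as.numeric(g == lev)
    map[[length(map) + 1]] <- tibble::tibble(
      column = paste0("intercept:", lev), term = "intercept", group = lev)
  }
  for (cv in spec$covariates) {
    x <- as.numeric(data[[cv]])
    for (lev in groups) {
      nm <- paste0(cv, ":", lev)
      cols[[nm]] <- x * (g == lev)
      map[[length(map) + 1]] <- tibble::tibble(column = nm, term = cv, group = lev)
    }
  }
  shared_cols <- c(spec$shared, if (spec$alpha == "covariate") spec$alpha_covariates)
  for (cv in shared_cols) {
    cols[[cv]] <- as.numeric(data[[cv]])
    map[[length(map) + 1]] <- tibble::tibble(column = cv, term = cv, group = NA_character_)
  }
  if (spec$alpha == "sample") {
    # first sample is the reference level; its alpha is fixed at zero
    for (sm in samples[-1]) {
      nm <- paste0("alpha:", sm)
      cols[[nm]] <- as.numeric(s == sm)
      map[[length(map) + 1]] <- tibble::tibble(column = nm, term = "alpha", group = NA_character_)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    rlang::abort(
      paste0("Design matrix is rank deficient; collinear column(s): ",
             paste(bad, collapse = ", ")),
      class = "dietglm_rank_error"
    )
  }
  list(X = X, coef_map = dplyr::bind_rows(map), groups = groups, samples = samples)
}

# Tweedie unit deviance, valid at y = 0 for 1 < p < 2.
tweedie_deviance <- function(y, mu, p) {
  a <- ifelse(y > 0, y^(2 - p) / ((1 - p) * (2 - p)), 0)
  2 * sum(a - y * mu^(1 - p) / (1 - p) + mu^(2 - p) / (2 - p))
}

poisson_deviance <- function(y, mu) {
  a <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(a - (y - mu))
}

# Fisher-scoring / IRLS for a log-link GLM with variance function mu^p
# (p = var_power; p = 1 is the Poisson family). Step-halving enforces
# monotone deviance descent. Returns the converged beta and diagnostics.
irls_log_link <- function(X, y, var_power, max_iter = 200, tol = 1e-12,
                          eta_min = -30, track = FALSE) {
  dev_fun <- if (var_power == 1) {
    function(mu) poisson_deviance(y, mu)
  } else {
    function(mu) tweedie_deviance(y, mu, var_power)
  }
  mu <- y + 0.1 * mean(y) + 1e-8
  eta <- pmax(log(mu), eta_min)
  mu <- exp(eta)
  beta <- NULL
  dev <- dev_fun(mu)
  trace <- if (track) list() else NULL
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    z <- eta + (y - mu) / mu
    w <- mu^(2 - var_power)
    fit <- stats::lm.wfit(x = X, y = z, w = w)
    beta_new <- fit$coefficients
    beta_new[is.na(beta_new)] <- 0
    if (!is.null(beta)) {
      # step-halve until the deviance does not increase
      step <- 1
      repeat {
        beta_try <- beta + step * (beta_new - beta)
        eta_try <- pmax(drop(X %*% beta_try), eta_min)
        dev_try <- dev_fun(exp(eta_try))
        if (dev_try <= dev + 1e-10 || step < 1 / 1024) break
        step <- step / 2
      }
      beta_new <- beta_try
    }
    eta <- pmax(drop(X %*% beta_new), eta_min)
    mu <- exp(eta)
    dev_new <- dev_fun(mu)
    if (track) trace[[iter]] <- list(beta = beta_new, deviance = dev_new)
    delta <- abs(dev - dev_new) / (abs(dev_new) + 0.1)
    done <- !is.null(beta) && delta < tol &&
      max(abs(beta_new - beta)) < 1e-9 * max(1, max(abs(beta_new)))
    beta <- beta_new
    dev <- dev_new
    if (done) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  names(beta) <- colnames(X)
  list(beta = beta, eta = eta, mu = mu, weights = mu^(2 - var_power),
       deviance = dev, iterations = iter, converged = converged, trace = trace)
}

# ML estimate of phi given mu and p, by the exact series log-likelihood.
# The search is bracketed around the Pearson moment estimate (consistent for
# phi), which keeps the latent Poisson intensity -- and hence the series
# truncation length -- moderate throughout the optimization.
profile_phi_ml <- function(y, mu, p, interval = NULL) {
  if (is.null(interval)) {
    phi_pearson <- sum((y - mu)^2 / mu^p) / max(length(y) - 1, 1)
    phi_pearson <- max(phi_pearson, 1e-8)
    interval <- log(phi_pearson) + c(-5, 5)
  }
  opt <- stats::optimize(
    function(lp) -sum(dtweedie_cpg(y, mu, exp(lp), p, log = TRUE)),
    interval = interval, tol = 1e-6
  )
  list(phi = exp(opt$minimum), loglik = -opt$objective)
}

#' Control parameters for [tweedie_glm()]
#'
#' @param max_iter Maximum IRLS iterations per inner fit.
#' @param tol Relative deviance change declaring IRLS convergence.
#' @param p_grid Grid of power values for the profile-likelihood search.
#' @param p_tol Absolute tolerance of the golden-section refinement of `p`.
#' @param eta_min Lower clamp on the linear predictor; guards against
#'   divergence when a category is entirely zero (separation).
#' @param track Keep the per-iteration coefficient/deviance trace.
#' @return A list of control values.
#' @export
glm_control <- function(max_iter = 200, tol = 1e-12,
                        p_grid = seq(1.05, 1.95, by = 0.05), p_tol = 1e-4,
                        eta_min = -30, track = FALSE) {
  list(max_iter = max_iter, tol = tol, p_grid = p_grid, p_tol = p_tol,
       eta_min = eta_min, track = track)
}

#' Fit a Tweedie GLM to stacked diet data
#'
#' Fits the log-link Tweedie regression of per-sample-per-prey biomass on
#' prey-category effects and covariates. Coefficients are estimated by
#' Fisher scoring (IRLS) with variance function `mu^p`; the scale `phi` by
#' maximum likelihood given the coefficients, using the exact compound
#' Poisson-gamma series likelihood; and the power `p` either fixed or
#' profiled (coarse grid then golden-section refinement).
#'
#' Exact zeros (prey absent from a sample) and samples where one prey is
#' 100% of the biomass need no special handling: both lie in the support of
#' the Tweedie distribution on 1 < p < 2.
#'
#' @param data Long-format diet data: one row per (sample, prey category).
#' @param spec A [diet_spec()].
#' @param response,sample,group Column names in `data` holding the
#'   non-negative response, the sample identifier, and the prey category.
#' @param control A [glm_control()] list.
#'
#' @return An object of class `dietglm`: coefficients (`beta`), their
#'   covariance (`cov_beta`), `phi`, `p`, `loglik`, the profile table when
#'   `p` was profiled, convergence metadata, and the design/spec information
#'   needed for prediction. Supports [generics::tidy()],
#'   [generics::glance()], [predict_mu()] and [predict_composition()].
#' @examples
#' sim <- gen_glm_dataset(n_samples = 60, n_categories = 3,
#'                        beta = cbind(c(0, 0.5, -0.5), c(0.8, 0, -0.8)),
#'                        phi = 1, p = 1.6, seed = 1)
#' fit <- tweedie_glm(sim$data, diet_spec(covariates = "x", power = 1.6))
#' fit
#' @export
tweedie_glm <- function(data, spec = diet_spec(), response = "response",
                        sample = "sample_id", group = "group",
                        control = glm_control()) {
  data <- tibble::as_tibble(data)
  y <- as.numeric(data[[response]])
  if (any(y < 0) || anyNA(y)) {
    rlang::abort("Responses must be non-negative and complete.",
                 class = "dietglm_domain_error")
  }
  if (all(y == 0)) {
    rlang::abort("All responses are zero; the model mean is not estimable.",
                 class = "dietglm_domain_error")
  }
  des <- build_design(data, spec, response = response, sample = sample, group = group)
  if (length(des$groups) < 2) {
    rlang::abort("At least two prey categories are required.",
                 class = "dietglm_domain_error")
  }
  dup <- duplicated(paste(data[[sample]], data[[group]]))
  if (any(dup)) {
    rlang::abort("Each (sample, group) pair must appear exactly once.",
                 class = "dietglm_domain_error")
  }
  g <- as.character(data[[group]])
  zero_groups <- des$groups[vapply(des$groups, function(lev) all(y[g == lev] == 0), logical(1))]
  if (length(zero_groups) > 0) {
    rlang::warn(
      paste0("Categor", if (length(zero_groups) > 1) "ies " else "y ",
             paste(zero_groups, collapse = ", "),
             " ha", if (length(zero_groups) > 1) "ve" else "s",
             " no positive biomass; their intercepts are driven to the lower",
             " bound and their standard errors are unreliable."),
      class = "dietglm_separation_warning"
    )
  }

  fit_at_p <- function(p, track = FALSE) {
    ir <- irls_log_link(des$X, y, var_power = p, max_iter = control$max_iter,
                        tol = control$tol, eta_min = control$eta_min,
                        track = track)
    ph <- profile_phi_ml(y, ir$mu, p)
    list(irls = ir, phi = ph$phi, loglik = ph$loglik, p = p)
  }

  profile_tbl <- NULL
  if (identical(spec$power, "profile")) {
    grid_fits <- purrr::map(control$p_grid, fit_at_p)
    lls <- purrr::map_dbl(grid_fits, "loglik")
    profile_tbl <- tibble::tibble(p = control$p_grid, loglik = lls)
    i0 <- which.max(lls)
    lo <- control$p_grid[max(1, i0 - 1)]
    hi <- control$p_grid[min(length(control$p_grid), i0 + 1)]
    lo <- max(lo, .p_lower)
    hi <- min(hi, .p_upper)
    opt <- stats::optimize(function(p) -fit_at_p(p)$loglik,
                           interval = c(lo, hi), tol = control$p_tol)
    cand <- fit_at_p(opt$minimum, track = control$track)
    best <- if (cand$loglik >= lls[i0]) cand else fit_at_p(control$p_grid[i0], track = control$track)
  } else {
    best <- fit_at_p(spec$power, track = control$track)
  }

  W <- best$irls$weights
  XtWX <- crossprod(des$X, des$X * W)
  cov_beta <- best$phi * solve(XtWX)
  boundary <- des$coef_map$group %in% zero_groups
  structure(
    list(
      beta = best$irls$beta, cov_beta = cov_beta,
      phi = best$phi, p = best$p, loglik = best$loglik,
      n_obs = length(y), converged = best$irls$converged,
      iterations = best$irls$iterations,
      profile = profile_tbl, boundary = boundary,
      spec = spec, coef_map = des$coef_map, groups = des$groups,
      samples = des$samples,
      columns = list(response = response, sample = sample, group = group),
      covariate_means = covariate_means(data, spec),
      trace = best$irls$trace,
      fitted = tibble::tibble(
        sample_id = as.character(data[[sample]]), group = g,
        response = y, mu = best$irls$mu
      )
    ),
    class = "dietglm"
  )
}

covariate_means <- function(data, spec) {
  cvs <- unique(c(spec$covariates, spec$shared,
                  if (spec$alpha == "covariate") spec$alpha_covariates))
  if (length(cvs) == 0) return(tibble::tibble(.rows = 1))
  dplyr::summarise(data, dplyr::across(dplyr::all_of(cvs), mean))
}

#' @export
print.dietglm <- function(x, ...) {
  cat("Tweedie diet GLM\n")
  cat(sprintf("  %d observations, %d categories, %d coefficients\n",
              x$n_obs, length(x$groups), length(x$beta)))
  cat(sprintf("  phi = %.4g, p = %.4g%s, log-likelihood = %.4f\n",
              x$phi, x$p,
              if (identical(x$spec$power, "profile")) " (profiled)" else " (fixed)",
              x$loglik))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  cat("Coefficients:\n")
  print(utils::head(as.data.frame(generics::tidy(x)), 20), digits = 4)
  if (length(x$beta) > 20) cat("  ...\n")
  invisible(x)
}

# Design rows for new data, mirroring build_design() column order.
design_rows <- function(fit, newdata) {
  newdata <- tibble::as_tibble(newdata)
  gcol <- fit$columns$group
  if (!gcol %in% names(newdata)) {
    rlang::abort(paste0("`newdata` must contain the category column `", gcol, "`."),
                 class = "dietglm_spec_error")
  }
  g <- as.character(newdata[[gcol]])
  unseen <- setdiff(g, fit$groups)
  if (length(unseen) > 0) {
    rlang::abort(paste0("Unseen categor", if (length(unseen) > 1) "ies: " else "y: ",
                        paste(unseen, collapse = ", ")),
                 class = "dietglm_spec_error")
  }
  spec <- fit$spec
  need <- c(spec$covariates, spec$shared,
            if (spec$alpha == "covariate") spec$alpha_covariates)
  miss <- setdiff(need, names(newdata))
  if (length(miss) > 0) {
    rlang::abort(paste0("`newdata` lacks covariate(s): ", paste(miss, collapse = ", ")),
                 class = "dietglm_spec_error")
  }
  n <- nrow(newdata)
  X <- matrix(0, n, length(fit$beta), dimnames = list(NULL, names(fit$beta)))
  for (lev in fit$groups) X[, paste0("intercept:", lev)] <- as.numeric(g == lev)
  for (cv in spec$covariates) {
    for (lev in fit$groups) {
      X[, paste0(cv, ":", lev)] <- as.numeric(newdata[[cv]]) * (g == lev)
    }
  }
  for (cv in c(spec$shared, if (spec$alpha == "covariate") spec$alpha_covariates)) {
    X[, cv] <- as.numeric(newdata[[cv]])
  }
  if (spec$alpha == "sample") {
    scol <- fit$columns$sample
    if (scol %in% names(newdata)) {
      s <- as.character(newdata[[scol]])
      known <- s %in% fit$samples
      for (sm in intersect(unique(s[known]), fit$samples[-1])) {
        X[, paste0("alpha:", sm)] <- as.numeric(s == sm)
      }
      if (any(!known)) {
        rlang::warn("Unknown sample ids in `newdata`; using the reference sample's alpha (0).")
      }
    }
    # otherwise alpha of the reference sample (0) is used
  }
  X
}

#' Predicted mean biomass per category
#'
#' Evaluates `mu = exp(linear predictor)` for each row of `newdata`. Rows
#' must carry the category column and every covariate in the spec; with
#' per-sample intercepts the reference sample's alpha (zero) is used unless
#' a known sample id is supplied.
#'
#' @param fit A [tweedie_glm()] fit.
#' @param newdata Tibble of prediction rows.
#' @return `newdata` with a `.mu` column appended.
#' @export
predict_mu <- function(fit, newdata) {
  X <- design_rows(fit, newdata)
  dplyr::mutate(tibble::as_tibble(newdata), .mu = exp(drop(X %*% fit$beta)))
}
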