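test_that("wide-to-long stacking is column-major and reversible", {
  Y <- matrix(c(1, 2, 0, 3, 4, 0), nrow = 2,
              dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  covs <- data.frame(x = c(0.5, -0.5))
  long <- stack_diet_matrix(Y, covs)
  expect_equal(nrow(long), 6)
  # column-major: the first two records are category A
  expect_equal(long$group[1:2], c("A", "A"))
  expect_equal(long$response, as.vector(Y))
  expect_equal(long$x, rep(c(0.5, -0.5), 3))

  # round trip long -> wide -> long
  wide_back <- tidyr::pivot_wider(long[, c("sample_id", "group", "response")],
                                  names_from = "group", values_from = "response")
  Y_back <- as.matrix(wide_back[, c("A", "B", "C")])
  rownames(Y_back) <- wide_back$sample_id
  expect_equal(Y_back, Y, ignore_attr = FALSE)
  expect_identical(stack_diet_matrix(Y_back, covs), long)

  Y[1, 2] <- NA
  expect_error(stack_diet_matrix(Y), "explicit zeros",
               class = "dietglm_domain_error")
})

test_that("design construction follows the spec and flags collinearity", {
  sim <- gen_glm_dataset(10, 3, beta = recovery_beta(), seed = 1)
  spec <- diet_spec(covariates = "x")
  des <- build_design(sim$data, spec)
  # 3 category intercepts + 3 per-category slopes
  expect_equal(ncol(des$X), 6)
  expect_equal(sum(des$coef_map$term == "intercept"), 3)
  expect_equal(sum(des$coef_map$term == "x"), 3)

  # per-sample offsets add one indicator per non-reference sample
  des2 <- build_design(sim$data, diet_spec(alpha = "sample"))
  expect_equal(ncol(des2$X), 3 + 9)
  expect_equal(sum(des2$coef_map$term == "alpha"), 9)

  # a covariate constant across samples is collinear with the intercepts
  const <- dplyr::mutate(sim$data, z = 1)
  expect_error(build_design(const, diet_spec(shared = "z")), "z",
               class = "dietglm_rank_error")
})

test_that("null-model fitted means are the category means", {
  sim <- gen_glm_dataset(80, 3, beta = recovery_beta(), seed = 3)
  fit <- tweedie_glm(sim$data, diet_spec(power = 1.6))
  mu_hat <- exp(fit$beta[paste0("intercept:", fit$groups)])
  means <- tapply(sim$data$response, sim$data$group, mean)[fit$groups]
  expect_equal(unname(mu_hat), as.vector(means), tolerance = 1e-9)
})

test_that("quasi-likelihood score equations hold at the optimum", {
  sim <- gen_glm_dataset(120, 3, beta = recovery_beta(), seed = 4)
  spec <- diet_spec(covariates = "x", power = 1.6)
  fit <- tweedie_glm(sim$data, spec)
  des <- build_design(sim$data, spec)
  mu <- predict_mu(fit, sim$data)$.mu
  score <- crossprod(des$X, (sim$data$response - mu) / mu^(1.6 - 1))
  expect_lt(max(abs(score)), 1e-8)
})

test_that("fixed-p coefficients match an off-the-shelf Tweedie GLM fitter", {
  skip_if_not_installed("mgcv")
  sim <- gen_glm_dataset(120, 3, beta = recovery_beta(), seed = 5)
  spec <- diet_spec(covariates = "x", power = 1.6)
  fit <- tweedie_glm(sim$data, spec)
  des <- build_design(sim$data, spec)
  ref <- stats::glm(sim$data$response ~ 0 + des$X,
                    family = mgcv::Tweedie(p = 1.6, link = "log"),
                    control = list(epsilon = 1e-13, maxit = 200))
  expect_lt(max(abs(fit$beta - coef(ref))), 1e-6)
})

test_that("profiled power is recovered and attains the profile maximum", {
  sim <- gen_glm_dataset(667, 3, beta = recovery_beta(), phi = 1, p = 1.5,
                         seed = 6)
  fit <- tweedie_glm(sim$data, diet_spec(covariates = "x", power = "profile"))
  expect_gte(fit$p, 1.4)
  expect_lte(fit$p, 1.6)
  # the returned p is at least as good as every grid point
  expect_true(all(fit$loglik >= fit$profile$loglik - 1e-8))
})

test_that("exact log-likelihood never decreases across scoring iterations", {
  sim <- gen_glm_dataset(60, 3, beta = recovery_beta(), seed = 7)
  fit <- tweedie_glm(sim$data, diet_spec(covariates = "x", power = 1.6),
                     control = glm_control(track = TRUE))
  y <- sim$data$response
  des <- build_design(sim$data, diet_spec(covariates = "x", power = 1.6))
  lls <- vapply(fit$trace, function(it) {
    mu <- exp(pmax(drop(des$X %*% it$beta), -30))
    phi <- dietglm:::profile_phi_ml(y, mu, 1.6)$phi
    sum(dtweedie_cpg(y, mu, phi, 1.6, log = TRUE))
  }, numeric(1))
  expect_true(all(diff(lls) > -1e-6))
})

test_that("degenerate inputs are rejected or flagged", {
  sim <- gen_glm_dataset(30, 3, beta = recovery_beta(), seed = 8)
  zeroed <- dplyr::mutate(sim$data, response = 0)
  expect_error(tweedie_glm(zeroed, diet_spec(power = 1.5)),
               class = "dietglm_domain_error")

  # a category with no positive biomass triggers a separation warning and
  # NA standard errors for its coefficients
  sep <- dplyr::mutate(sim$data,
                       response = ifelse(group == "prey_3", 0, response))
  expect_warning(fit <- tweedie_glm(sep, diet_spec(power = 1.5)),
                 class = "dietglm_separation_warning")
  td <- tidy(fit)
  expect_true(all(is.na(td$std.error[td$group == "prey_3"])))
  expect_true(all(!is.na(td$std.error[td$group != "prey_3"])))

  # a sample that is 100% one prey is supported without special handling
  one_hot <- sim$data
  first <- one_hot$sample_id == "s1"
  one_hot$response[first] <- c(5, 0, 0)
  expect_s3_class(tweedie_glm(one_hot, diet_spec(power = 1.5)), "dietglm")
})

test_that("prediction honours the link and matches fitted values", {
  sim <- gen_glm_dataset(50, 3, beta = recovery_beta(), seed = 9)
  spec <- diet_spec(covariates = "x", power = 1.6)
  fit <- tweedie_glm(sim$data, spec)

  # in-sample predictions equal fitted values
  pred <- predict_mu(fit, sim$data)
  expect_equal(pred$.mu, fit$fitted$mu, tolerance = 1e-12)

  # all-zero coefficients give mu = 1 for every category
  fit0 <- fit
  fit0$beta[] <- 0
  nd <- tibble::tibble(group = fit$groups, x = 0.7)
  expect_equal(predict_mu(fit0, nd)$.mu, rep(1, 3))

  # adding c to every linear predictor scales mu by exp(c)
  fitc <- fit
  fitc$beta[paste0("intercept:", fit$groups)] <-
    fitc$beta[paste0("intercept:", fit$groups)] + 0.3
  expect_equal(predict_mu(fitc, nd)$.mu, predict_mu(fit, nd)$.mu * exp(0.3))

  expect_error(predict_mu(fit, tibble::tibble(group = "walrus", x = 0)),
               class = "dietglm_spec_error")
})

test_that("per-sample offsets and shared covariates enter the fit correctly", {
  sim <- gen_glm_dataset(40, 3, beta = recovery_beta(), seed = 10)
  # per-sample alpha: prediction with a known sample id differs from the
  # reference-alpha prediction by exactly exp(alpha_s)
  fit <- tweedie_glm(sim$data, diet_spec(alpha = "sample", power = 1.5))
  nd_ref <- tibble::tibble(group = fit$groups)
  nd_s <- tibble::tibble(group = fit$groups, sample_id = fit$samples[2])
  a2 <- unname(fit$beta[paste0("alpha:", fit$samples[2])])
  expect_equal(predict_mu(fit, nd_s)$.mu, predict_mu(fit, nd_ref)$.mu * exp(a2))

  # shared covariate shifts every category equally
  fit2 <- tweedie_glm(sim$data, diet_spec(shared = "x", power = 1.5))
  expect_equal(sum(fit2$coef_map$term == "x"), 1)
})
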