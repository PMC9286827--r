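sp2 <- function(center = c(0, 0), spread = diag(2), n = 500, w = 1.2, v = 1) {
  prey_species("sp", center = center, spread = spread, w = w, v = v,
               n_individuals = n)
}

test_that("marked-point simulation places the configured points and marks", {
  species <- list(
    prey_species("a", c(0, 0), n_individuals = 1000),
    prey_species("b", c(2, 2), n_individuals = 1000),
    prey_species("c", c(4, 0), n_individuals = 1000)
  )
  pts <- simulate_marked_points(species, seed = 1)
  expect_equal(nrow(pts), 3000)
  expect_equal(unname(table(pts$species)), rep(1000L, 3), ignore_attr = TRUE)
  expect_true(all(pts$mass > 0))
  expect_identical(pts, simulate_marked_points(species, seed = 1))

  # mean mark mass ~ w = 1.2 kg across many realizations
  set.seed(5)
  masses <- unlist(lapply(1:20, function(i) simulate_marked_points(species)$mass))
  expect_lt(abs(mean(masses) - 1.2), 3 * mc_se_mean(masses))

  expect_error(prey_species("x", c(0, 0), n_individuals = 0),
               class = "dietglm_domain_error")
  expect_error(prey_species("x", c(0, 0), spread = matrix(c(1, 2, 2, 1), 2)),
               class = "dietglm_domain_error")
})

test_that("site thinning retains mass with the right probability", {
  pts <- simulate_marked_points(sp2(n = 2000), seed = 2)

  none <- site_biomass(pts, foraging_site("s", c(0, 0), 1, thinning = 0), seed = 1)
  expect_equal(none$biomass, 0)

  all_site <- foraging_site("s", c(0, 0), radius = 1e3, thinning = 1)
  everything <- site_biomass(pts, all_site, seed = 1)
  expect_equal(everything$biomass, sum(pts$mass))

  # Bernoulli(0.5) thinning halves the expected retained mass in the disc
  disc <- foraging_site("s", c(0, 0), radius = 1, thinning = 0.5)
  contained <- sum(pts$mass[pts$x^2 + pts$y^2 <= 1])
  set.seed(9)
  kept <- replicate(1000, site_biomass(pts, disc)$biomass)
  expect_lt(abs(mean(kept) - 0.5 * contained), 3 * mc_se_mean(kept))
})

test_that("binomial thinning of contained counts stays Poisson-dispersed", {
  species <- sp2(spread = diag(2) * 4, n = 1000)
  site <- foraging_site("s", c(0.8, -0.5), radius = 0.45, thinning = 0.7)
  set.seed(13)
  counts <- replicate(600, {
    pts <- simulate_marked_points(list(species))
    inside <- (pts$x - 0.8)^2 + (pts$y + 0.5)^2 <= 0.45^2
    sum(inside & runif(nrow(pts)) < 0.7)
  })
  disp <- var(counts) / mean(counts)
  # variance/mean of a Poisson count is 1; allow Monte-Carlo slack
  expect_lt(abs(disp - 1), 3 * sqrt(2 / length(counts)) + 0.05)
})

test_that("expected thinned counts: centroid vs quadrature vs simulation", {
  expect_error(expected_lambda(sp2(), foraging_site("s", c(0, 0), 1), "nope"))

  # homogeneous-field limit: huge spread makes the two methods agree
  flat <- sp2(spread = diag(2) * 1e4)
  site <- foraging_site("s", c(1, 1), radius = 0.8)
  lc <- expected_lambda(flat, site, "centroid")
  lq <- expected_lambda(flat, site, "quadrature")
  expect_equal(lc, lq, tolerance = 1e-4)

  # site far in the intensity tail: lambda ~ 0
  far <- foraging_site("s", c(50, 50), radius = 1)
  expect_lt(expected_lambda(sp2(), far, "quadrature"), 1e-12)

  # shrinking the site radius closes the centroid/quadrature gap
  sp <- sp2(spread = diag(2) * 2)
  gaps <- vapply(c(1, 0.5, 0.25, 0.125), function(r) {
    st <- foraging_site("s", c(1.2, 0.4), radius = r)
    abs(expected_lambda(sp, st, "centroid") /
          expected_lambda(sp, st, "quadrature") - 1)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))

  # quadrature matches the empirical mean retained count
  sp <- sp2(spread = diag(2) * 3, n = 800)
  st <- foraging_site("s", c(1, 0.5), radius = 0.7, thinning = 0.6)
  lam <- expected_lambda(sp, st, "quadrature")
  set.seed(17)
  counts <- replicate(500, {
    pts <- simulate_marked_points(list(sp))
    inside <- (pts$x - 1)^2 + (pts$y - 0.5)^2 <= 0.7^2
    sum(inside & runif(nrow(pts)) < 0.6)
  })
  expect_lt(abs(mean(counts) - lam), 3 * mc_se_mean(counts))
})

test_that("pooled constant scale/power maximizes the likelihood it claims to", {
  # self-consistency: draws truly share one (phi, p)
  set.seed(21)
  mu <- rep(c(0.8, 2.5, 6), length.out = 2e4)
  y <- simulate_tweedie(length(mu), mu, phi = 1.3, p = 1.55)
  f <- fit_constant_scale_power(y, mu)
  expect_true(f$converged)
  # tolerances = ~3x the ML sampling scale at this n
  expect_lt(abs(f$p - 1.55), 0.01)
  expect_lt(abs(f$phi - 1.3) / 1.3, 0.06)

  # optimizer beats every grid point on heterogeneous cells
  set.seed(22)
  mu2 <- rep(c(0.5, 4), each = 1500)
  y2 <- c(simulate_tweedie(1500, 0.5, 0.6, 1.3),
          simulate_tweedie(1500, 4, 2.0, 1.7))
  f2 <- fit_constant_scale_power(y2, mu2)
  pool_ll <- function(phi, p) sum(dtweedie_cpg(y2, mu2, phi, p, log = TRUE))
  grid <- expand.grid(phi = c(0.5, 1, 1.5, 2, 3), p = seq(1.1, 1.9, 0.1))
  grid_best <- max(mapply(pool_ll, grid$phi, grid$p))
  expect_gte(f2$loglik, grid_best)

  # a single cell reduces to per-cell ML: loglik at the optimum is at least
  # the likelihood at the generating values
  set.seed(23)
  y3 <- simulate_tweedie(4000, 2, 1.1, 1.5)
  f3 <- fit_constant_scale_power(y3, rep(2, 4000))
  expect_gte(f3$loglik, pool_ll3 <- sum(dtweedie_cpg(y3, 2, 1.1, 1.5, log = TRUE)))
  expect_error(fit_constant_scale_power(1:3, 1:2), class = "dietglm_domain_error")
})

test_that("the replicated experiment matches its thinned-Poisson oracles", {
  cfg <- foraging_demo_config()
  ex <- run_foraging_experiment(cfg, n_reps = 150, seed = 29)

  # deterministic under a fixed seed
  ex2 <- run_foraging_experiment(cfg, n_reps = 150, seed = 29)
  expect_identical(ex$cells, ex2$cells)
  expect_identical(ex$draws, ex2$draws)

  # proportions sum to one within each site and the two Tweedie
  # approximations predict identical proportions (they share the means)
  sums <- tapply(ex$proportions$centroid_tweedie, ex$proportions$site, sum)
  expect_equal(as.vector(sums), rep(1, 3), tolerance = 1e-12)
  expect_identical(ex$proportions$centroid_tweedie, ex$proportions$constant_glm)

  # centroid-Tweedie proportion is mu / sum(mu) with mu = lambda * w
  by_site <- split(ex$cells, ex$cells$site)
  for (cell in by_site) {
    mu <- cell$lambda_centroid * 1.2
    expect_equal(
      ex$proportions$centroid_tweedie[ex$proportions$site == cell$site[1]],
      mu / sum(mu), tolerance = 1e-12)
  }

  # per-cell empirical zero fractions match exp(-lambda_quadrature)
  p0 <- exp(-ex$cells$lambda_quadrature)
  se <- sqrt(pmax(p0 * (1 - p0), 1e-12) / 150)
  expect_true(all(abs(ex$cells$zero_frac - p0) <= 3 * se + 1e-9))

  expect_error(run_foraging_experiment(cfg, n_reps = 1),
               class = "dietglm_domain_error")
})
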