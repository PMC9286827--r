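# Independent simulation oracle for the compound Poisson-gamma distribution:
# draws built directly from its definition (Poisson count of gamma masses),
# bypassing the package's parameter conversions and sampler.
r_cpg_oracle <- function(n, lam, k, theta) {
  counts <- rpois(n, lam)
  y <- numeric(n)
  pos <- counts > 0
  y[pos] <- rgamma(sum(pos), shape = counts[pos] * k, scale = theta)
  y
}

# Monte-Carlo standard error of a sample mean.
mc_se_mean <- function(x) sd(x) / sqrt(length(x))

# Monte-Carlo standard error of a sample variance (delta method on moments).
mc_se_var <- function(x) {
  n <- length(x)
  m <- mean(x)
  sqrt(max(mean((x - m)^4) - var(x)^2, 0) / n)
}

# Default 3-category, 1-covariate recovery setup used by several tests.
recovery_beta <- function() cbind(c(0, 0.5, -0.5), c(0.8, 0, -0.8))

# Run the installed command-line script in a subprocess, propagating the
# current library paths.
run_cli <- function(args) {
  script <- system.file("cli", "dietglm.R", package = "dietglm")
  stopifnot(nzchar(script))
  out <- suppressWarnings(system2(
    "Rscript", c(script, args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  status <- attr(out, "status") %||% 0L
  list(status = status, output = out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
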