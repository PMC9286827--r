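#' Multinomial proportion MLE from a count table
#'
#' Closed-form maximum-likelihood diet proportions from per-sample prey
#' counts: pooled across samples, `pi_c = sum_i n_ic / sum_ic n_ic`.
#'
#' @param counts Long-format tibble with columns `sample_id`, `group`, and
#'   `count` (non-negative integers; every sample must have a positive
#'   total).
#' @return A tibble with `group` and `proportion` (summing to one).
#' @examples
#' counts <- tibble::tibble(sample_id = 1, group = c("a", "b", "c"),
#'                          count = c(10, 30, 60))
#' fit_multinomial(counts)
#' @export
fit_multinomial <- function(counts) {
  counts <- check_count_table(counts)
  out <- counts |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop")
  tibble::tibble(group = out$group, proportion = out$n / sum(out$n))
}

check_count_table <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("sample_id", "group", "count")
  if (!all(need %in% names(counts)) || nrow(counts) == 0) {
    rlang::abort("`counts` must be a non-empty tibble with columns sample_id, group, count.",
                 class = "dietglm_domain_error")
  }
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    rlang::abort("`count` must contain non-negative integers.",
                 class = "dietglm_domain_error")
  }
  totals <- counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  if (any(totals$total == 0)) {
    rlang::abort("Every sample must have a positive total count.",
                 class = "dietglm_domain_error")
  }
  counts
}

#' Diet proportions via the multinomial-Poisson transformation
#'
#' Fits a log-link Poisson regression with one fixed intercept per sample
#' and one effect per prey category (the multinomial-Poisson
#' transformation), then converts the category effects into proportions
#' through the softmax. The per-sample intercepts absorb the sample totals,
#' so the resulting proportions coincide with the multinomial MLE of
#' [fit_multinomial()]; the fitted per-sample totals equal the observed
#' totals exactly (the intercepts' score equations).
#'
#' A category observed zero in every sample is reported with proportion 0
#' and flagged (`boundary = TRUE`): its log-scale effect sits on the
#' boundary and has no finite standard error.
#'
#' @inheritParams fit_multinomial
#' @return A tibble with `group`, `proportion`, and `boundary`.
#' @export
fit_poisson_equivalent <- function(counts) {
  counts <- check_count_table(counts)
  spec <- diet_spec(alpha = "sample", power = "profile")  # power unused for Poisson
  des <- build_design(
    dplyr::rename(counts, response = "count"), spec,
    response = "response"
  )
  ir <- irls_log_link(des$X, counts$count, var_power = 1, max_iter = 200,
                      tol = 1e-14)
  idx <- match(paste0("intercept:", des$groups), names(ir$beta))
  eta <- ir$beta[idx]
  eta <- eta - max(eta)
  pi <- exp(eta) / sum(exp(eta))
  boundary <- vapply(des$groups, function(g) {
    all(counts$count[counts$group == g] == 0)
  }, logical(1))
  pi[boundary] <- 0
  pi <- pi / sum(pi)
  tibble::tibble(group = des$groups, proportion = unname(pi),
                 boundary = unname(boundary))
}

#' Check the multinomial-Poisson equivalence on a count table
#'
#' Runs both routes -- the closed-form multinomial MLE and the Poisson
#' regression with per-sample intercepts -- and tabulates the per-category
#' difference, which should be numerically zero.
#'
#' @inheritParams fit_multinomial
#' @return A tibble with `group`, `multinomial`, `poisson`, and `diff`.
#' @export
mpt_check <- function(counts) {
  m <- fit_multinomial(counts)
  p <- fit_poisson_equivalent(counts)
  dplyr::left_join(
    dplyr::rename(m, multinomial = "proportion"),
    dplyr::select(dplyr::rename(p, poisson = "proportion"), "group", "poisson"),
    by = "group"
  ) |>
    dplyr::mutate(diff = .data$multinomial - .data$poisson)
}
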