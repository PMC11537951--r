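# Independent oracles, deliberately coded against different machinery than
# the package (stats::lm / stats::anova and direct textbook formulas).

# build a replicate view tibble from a list of numeric vectors
view_from_groups <- function(groups) {
  ids <- names(groups) %||% paste0("g", seq_along(groups))
  tibble::tibble(
    group_id = rep(ids, lengths(groups)),
    value = unlist(groups, use.names = FALSE)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# within-group (residual) mean square from a one-way fixed-effects fit
oracle_msw <- function(view) {
  fit <- stats::lm(value ~ factor(group_id), data = view)
  stats::anova(fit)["Residuals", "Mean Sq"]
}

oracle_msb <- function(view) {
  fit <- stats::lm(value ~ factor(group_id), data = view)
  stats::anova(fit)[1, "Mean Sq"]
}

# classical duplicate-pairs TEM, sqrt(sum d^2 / 2N)
oracle_pairs_tem <- function(view) {
  d <- tapply(view$value, view$group_id, function(v) v[2] - v[1])
  sqrt(sum(d^2) / (2 * length(d)))
}

# textbook single-rater one-way ICC for a balanced design, entirely from
# stats::anova mean squares
oracle_icc1_balanced <- function(view, k) {
  msb <- oracle_msb(view)
  msw <- oracle_msw(view)
  (msb - msw) / (msb + (k - 1) * msw)
}

# Searle's effective group size from the group-size table alone
oracle_k0 <- function(view) {
  k <- as.vector(table(view$group_id))
  m <- sum(k)
  (m - sum(k^2) / m) / (length(k) - 1)
}

# random replicate view: n_groups groups of sizes drawn from k_range
random_view <- function(n_groups, k_range = 2:4, mean = 50, sd_b = 5,
                        sd_w = 1) {
  groups <- lapply(seq_len(n_groups), function(i) {
    k <- k_range[sample.int(length(k_range), 1)]
    stats::rnorm(k, stats::rnorm(1, mean, sd_b), sd_w)
  })
  view_from_groups(groups)
}

# minimal valid measurement table builder for io tests
record_rows <- function(...) {
  rows <- list(...)
  tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
    data.frame(volunteer_id = r[[1]], rater_id = r[[2]],
               rater_group = r[[3]], parameter = r[[4]],
               round = as.integer(r[[5]]), value = as.numeric(r[[6]]),
               age_years = as.numeric(r[[7]]),
               stringsAsFactors = FALSE)
  })))
}
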