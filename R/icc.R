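#' One-way ANOVA components for unbalanced replicate groups
#'
#' Decomposes a replicate view into the between- and within-group mean
#' squares of the one-way random-effects model
#' \eqn{x_{ij} = \mu + a_i + e_{ij}}, together with Searle's effective group
#' size for unbalanced data. With \eqn{N} groups of sizes \eqn{k_i} and
#' \eqn{M = \sum_i k_i} observations:
#'
#' \deqn{MS_B = \frac{\sum_i k_i (\bar x_i - \bar x)^2}{N - 1}, \qquad
#'       MS_W = \frac{\sum_i \sum_j (x_{ij} - \bar x_i)^2}{M - N}, \qquad
#'       k_0 = \frac{M - \sum_i k_i^2 / M}{N - 1}.}
#'
#' \eqn{k_0} reduces to the common \eqn{k} for balanced designs. Because the
#' one-way model ignores rater identity, missing cells in a subjects-by-raters
#' layout reduce to nothing more than unequal group sizes, which this
#' decomposition handles directly. Note \eqn{MS_W} equals
#' [pooled_tem()]\eqn{^2} on the same view, exactly.
#'
#' @param view A replicate view or data frame with `group_id` and `value`;
#'   at least 2 groups, every group with at least 2 values.
#' @return A one-row tibble: `msb`, `msw`, `k0`, `n_groups`, `n_obs`.
#' @examples
#' v <- tibble::tibble(group_id = c("a", "a", "b", "b", "b"),
#'                     value = c(1, 2, 4, 4, 5))
#' anova_components(v) # k0 = (5 - 13/5) / 1 = 2.4
#' @export
anova_components <- function(view) {
  stopifnot(is.data.frame(view), all(c("group_id", "value") %in% names(view)))
  gs <- group_stats(view)
  if (nrow(gs) < 2) {
    abort("At least 2 replicate groups are required for the one-way decomposition.")
  }
  if (any(gs$k < 2)) {
    abort("Every replicate group must have at least 2 values.")
  }
  m <- sum(gs$k)
  n_groups <- nrow(gs)
  grand <- sum(gs$k * gs$mean) / m
  msb <- sum(gs$k * (gs$mean - grand)^2) / (n_groups - 1)
  msw <- sum(gs$ss) / (m - n_groups)
  k0 <- (m - sum(gs$k^2) / m) / (n_groups - 1)
  tibble::tibble(msb = msb, msw = msw, k0 = k0,
                 n_groups = n_groups, n_obs = m)
}

#' One-way random-effects intraclass correlation (single rater)
#'
#' The single-measurement, absolute-agreement ICC of the one-way
#' random-effects model,
#' \deqn{ICC = \frac{MS_B - MS_W}{MS_B + (k_0 - 1) MS_W},}
#' estimating \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)}: the share of
#' total variance due to real between-subject differences rather than
#' measurement error. Applied to an inter-rater view it treats each rater's
#' first measurement as one interchangeable observation of the volunteer;
#' applied to an intra-rater view each (volunteer, rater) pair is a group
#' with its two rounds. Values can be negative (bounded below by
#' \eqn{-1/(k_0 - 1)}) and are reported as computed.
#'
#' @inheritParams anova_components
#' @return A single number, or `NA` with a warning when all values are
#'   identical (no variance to apportion) or the view is empty/single-group.
#' @examples
#' v <- tibble::tibble(group_id = rep(c("a", "b", "c"), each = 2),
#'                     value = c(1, 2, 4, 4, 7, 8))
#' icc_oneway(v) # about 0.964
#' @export
icc_oneway <- function(view) {
  stopifnot(is.data.frame(view))
  if (nrow(view) == 0 || dplyr::n_distinct(view$group_id) < 2) {
    warn("ICC needs at least 2 replicate groups; returning NA.")
    return(NA_real_)
  }
  ac <- anova_components(view)
  if (ac$msb == 0 && ac$msw == 0) {
    warn("All values identical: ICC is undefined (NA).")
    return(NA_real_)
  }
  (ac$msb - ac$msw) / (ac$msb + (ac$k0 - 1) * ac$msw)
}
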