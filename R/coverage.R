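#' Abundance-based sample coverage
#'
#' The Chao–Jost coverage estimator from singleton (`f1`) and doubleton
#' (`f2`) counts:
#' `C = 1 - (f1 / n) * ((n - 1) f1 / ((n - 1) f1 + 2 f2))`.
#' Coverage is the estimated share of community abundance belonging to
#' species already present in the sample; above 0.90 an inventory is
#' conventionally called adequate.
#'
#' @param x Per-species pooled abundances (zeros are dropped).
#' @return A single value in `[0, 1]`.
#' @examples
#' sample_coverage(c(4, 2, 1, 1)) # 0.78125
#' @export
sample_coverage <- function(x) {
  x <- check_abundances(x)
  n <- sum(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 == 0) return(1)
  if (n == 1) return(0)
  1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
}

check_abundances <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0) stop("no positive abundances", call. = FALSE)
  if (any(x != round(x))) stop("abundances must be integer counts", call. = FALSE)
  x
}

#' Rarefaction and extrapolation curve for species richness
#'
#' Interpolates expected richness for subsamples of `m <= n` individuals by
#' the exact hypergeometric formula
#' `E[S(m)] = sum_i (1 - choose(n - x_i, m) / choose(n, m))`
#' and extrapolates beyond `n` with the Chao1 estimate of undetected
#' richness `f0 = ((n-1)/n) f1^2 / (2 f2)` (or `((n-1)/n) f1 (f1-1)/2` when
#' `f2 = 0`):
#' `S(n + m*) = S_obs + f0 (1 - (1 - f1 / (n f0 + f1))^{m*})`.
#' The curve is continuous at `m = n`, where it equals observed richness.
#'
#' @param x Per-species pooled abundances.
#' @param m_max Largest sample size on the curve; default `2 * sum(x)`, the
#'   conventional extrapolation endpoint.
#' @param knots Approximate number of curve points (always includes 1 and
#'   `n`).
#' @return A tibble with columns `m`, `richness`, `method`
#'   (`"rarefaction"`, `"observed"` or `"extrapolation"`).
#' @export
richness_curve <- function(x, m_max = NULL, knots = 40) {
  x <- check_abundances(x)
  n <- sum(x)
  if (is.null(m_max)) m_max <- 2 * n
  if (m_max < 1) stop("m_max must be at least 1", call. = FALSE)
  grid <- sort(unique(c(1, n, round(seq(1, m_max, length.out = knots)))))
  grid <- grid[grid >= 1 & grid <= m_max]
  tibble::tibble(
    m = grid,
    richness = vapply(grid, function(mm) expected_richness(x, mm), numeric(1)),
    method = dplyr::case_when(
      grid < n ~ "rarefaction",
      grid == n ~ "observed",
      TRUE ~ "extrapolation"
    )
  )
}

expected_richness <- function(x, m) {
  n <- sum(x)
  s_obs <- length(x)
  if (m <= n) {
    # exp(lchoose) keeps large n stable; choose(n - x_i, m) = 0 when x_i > n - m
    p_absent <- exp(lchoose(n - x, m) - lchoose(n, m))
    p_absent[n - x < m] <- 0
    return(sum(1 - p_absent))
  }
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  f0 <- if (f2 > 0) {
    (n - 1) / n * f1^2 / (2 * f2)
  } else {
    (n - 1) / n * f1 * (f1 - 1) / 2
  }
  if (f0 == 0 || f1 == 0) return(s_obs)
  s_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^(m - n))
}

#' Inventory-completeness summary per analysis group
#'
#' Pools abundances across all sites within each analysis group (waterbirds
#' excluded first, as always) and reports sample size, observed richness,
#' singletons, doubletons, coverage and the > 0.90 adequacy flag.
#'
#' @param m A [community_matrix()].
#' @param groups A group table (see [read_group_table()]).
#' @param which_groups Character vector of groups to summarise.
#' @return A tibble with one row per group.
#' @export
coverage_summary <- function(m, groups,
                             which_groups = analysis_groups) {
  purrr::map_dfr(which_groups, function(g) {
    sub <- subset_by_group(m, groups, g)
    x <- species_totals(sub)
    x <- x[x > 0]
    tibble::tibble(
      group = g,
      n = sum(x),
      s_obs = length(x),
      f1 = sum(x == 1),
      f2 = sum(x == 2),
      coverage = sample_coverage(x),
      adequate = sample_coverage(x) > 0.90
    )
  })
}
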