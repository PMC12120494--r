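#' Coleman's random placement curve
#'
#' Under passive sampling each of the `n_i` individuals of species `i`
#' falls into site `j` independently with probability equal to the site's
#' relative area `a_j = A_j / sum(A)`. Expected richness and its variance at
#' a site then have closed forms:
#' `E_j = S - sum_i (1 - a_j)^{n_i}` and
#' `Var_j = sum_i (1 - a_j)^{n_i} (1 - (1 - a_j)^{n_i})`.
#'
#' @param abundances Named per-species pooled abundances (zeros dropped with
#'   a warning).
#' @param areas A site-attribute table (`site_id`, `area`) or named numeric
#'   vector of areas.
#' @return A tibble with columns `site_id`, `area`, `rel_area`, `expected`,
#'   `sd`.
#' @export
coleman_curve <- function(abundances, areas) {
  if (any(abundances == 0)) {
    warning("dropping species with zero pooled abundance", call. = FALSE)
    abundances <- abundances[abundances > 0]
  }
  if (length(abundances) == 0) stop("no species with positive abundance", call. = FALSE)
  a <- attribute_vector(if (is.data.frame(areas)) areas else areas)
  if (any(a <= 0)) stop("areas must be strictly positive", call. = FALSE)
  tot <- sum(a)
  if (tot <= 0) stop("total area must be positive", call. = FALSE)
  rel <- a / tot
  s <- length(abundances)
  stats_ <- purrr::map(rel, function(aj) {
    q <- (1 - aj)^abundances
    c(e = s - sum(q), v = sum(q * (1 - q)))
  })
  tibble::tibble(
    site_id = names(a),
    area = unname(a),
    rel_area = unname(rel),
    expected = unname(vapply(stats_, `[[`, numeric(1), "e")),
    sd = unname(sqrt(vapply(stats_, `[[`, numeric(1), "v")))
  )
}

#' Passive-sampling test via random placement
#'
#' Compares observed per-site richness with the random placement band
#' `E_j +/- 1 SD`; sites exactly on the boundary count as within. When more
#' than one third of the sites fall outside the band the passive-sampling
#' hypothesis is rejected, i.e. nestedness (or its absence) cannot be
#' explained by individuals accumulating in proportion to area alone.
#' Pooled abundances are taken from the matrix as given, so each analysis
#' group gets its own curve after [subset_by_group()].
#'
#' @param m A [community_matrix()].
#' @param areas Site-attribute table or named area vector covering every
#'   site of `m`.
#' @return A `random_placement` object; `tidy()` gives the per-site table
#'   (`site_id`, `area`, `rel_area`, `expected`, `sd`, `observed`,
#'   `within_1sd`), `glance()` the summary (`fraction_outside`,
#'   `passive_sampling_rejected`, `n_sites`, `n_species`).
#' @export
passive_sampling_test <- function(m, areas) {
  x <- as_community(m)
  a <- attribute_vector(areas)
  miss <- setdiff(colnames(x), names(a))
  if (length(miss) > 0) {
    stop(sprintf("no area for site(s): %s", paste(miss, collapse = ", ")),
      call. = FALSE
    )
  }
  a <- a[colnames(x)]
  pooled <- species_totals(x)
  curve <- suppressWarnings(coleman_curve(pooled, a))
  obs <- site_richness(x)
  curve$observed <- as.integer(obs[curve$site_id])
  curve$within_1sd <- curve$observed >= curve$expected - curve$sd &
    curve$observed <= curve$expected + curve$sd
  frac <- mean(!curve$within_1sd)
  structure(
    list(
      sites = curve,
      fraction_outside = frac,
      passive_sampling_rejected = frac > 1 / 3,
      n_sites = nrow(curve),
      n_species = sum(pooled > 0)
    ),
    class = "random_placement"
  )
}

#' @export
print.random_placement <- function(x, ...) {
  cat(sprintf(
    "random placement: %d/%d sites outside 1 SD (%.1f%%) -> passive sampling %s\n",
    sum(!x$sites$within_1sd), x$n_sites, 100 * x$fraction_outside,
    if (x$passive_sampling_rejected) "REJECTED" else "not rejected"
  ))
  invisible(x)
}
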