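#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for avinest result objects
#'
#' Every fitted/result object in the package can be flattened to a tibble:
#' `tidy()` returns one row per component (or per site for the random
#' placement model), `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name avinest-tidiers
NULL

#' @rdname avinest-tidiers
#' @method tidy nestedness_result
#' @export
tidy.nestedness_result <- function(x, ...) {
  tibble::tibble(
    metric = x$metric,
    component = c("overall", "row", "col"),
    value = c(x$overall, x$row_component, x$col_component),
    n_pairs = c(x$n_row_pairs + x$n_col_pairs, x$n_row_pairs, x$n_col_pairs),
    ordering = x$ordering
  )
}

#' @rdname avinest-tidiers
#' @method glance nestedness_result
#' @export
glance.nestedness_result <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, overall = x$overall,
    row_component = x$row_component, col_component = x$col_component,
    n_row_pairs = x$n_row_pairs, n_col_pairs = x$n_col_pairs,
    ordering = x$ordering
  )
}

#' @rdname avinest-tidiers
#' @method tidy null_test
#' @export
tidy.null_test <- function(x, ...) x$results

#' @rdname avinest-tidiers
#' @method glance null_test
#' @export
glance.null_test <- function(x, ...) {
  dplyr::filter(x$results, .data$component == "overall")
}

#' @rdname avinest-tidiers
#' @method tidy random_placement
#' @export
tidy.random_placement <- function(x, ...) x$sites

#' @rdname avinest-tidiers
#' @method glance random_placement
#' @export
glance.random_placement <- function(x, ...) {
  tibble::tibble(
    fraction_outside = x$fraction_outside,
    passive_sampling_rejected = x$passive_sampling_rejected,
    n_sites = x$n_sites,
    n_species = x$n_species
  )
}

#' @rdname avinest-tidiers
#' @method tidy tree_nodf_result
#' @export
tidy.tree_nodf_result <- function(x, ...) {
  tibble::tibble(
    component = c("treeNODF", "S.Fraction", "topoNODF"),
    value = c(x$tree_nodf, x$s_fraction, x$topo_nodf),
    n_pairs = x$n_pairs
  )
}

#' @rdname avinest-tidiers
#' @method glance tree_nodf_result
#' @export
glance.tree_nodf_result <- function(x, ...) {
  tibble::tibble(
    tree_nodf = x$tree_nodf, s_fraction = x$s_fraction,
    topo_nodf = x$topo_nodf, n_pairs = x$n_pairs
  )
}

#' @rdname avinest-tidiers
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) x$results

#' @rdname avinest-tidiers
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  dplyr::filter(x$results, .data$component == "treeNODF")
}
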