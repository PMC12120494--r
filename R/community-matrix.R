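#' Build a labelled species-by-site community matrix
#'
#' A community matrix holds non-negative integer abundances for every
#' (species, site) cell. Internally species are always kept in rows; use
#' `orientation` to declare how the input is laid out. Species never observed
#' anywhere carry no information for nestedness and are dropped with a
#' warning; all-zero sites are kept because a richness of zero is a real
#' observation.
#'
#' @param x A numeric matrix with row and column names, or a data frame whose
#'   first column holds labels and remaining columns hold abundances.
#' @param orientation Either `"species_rows"` (default) or `"species_cols"`.
#' @return An integer matrix of class `community_matrix`, species in rows.
#' @examples
#' m <- community_matrix(matrix(c(1, 0, 2, 3, 1, 0), nrow = 3,
#'   dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
#' site_richness(m)
#' @export
community_matrix <- function(x, orientation = c("species_rows", "species_cols")) {
  orientation <- match.arg(orientation)
  if (is.data.frame(x)) {
    labels <- as.character(x[[1]])
    vals <- as.matrix(x[, -1, drop = FALSE])
    rownames(vals) <- labels
    x <- vals
  }
  if (!is.matrix(x)) stop("`x` must be a matrix or data frame", call. = FALSE)
  if (orientation == "species_cols") x <- t(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("community matrix needs species and site labels", call. = FALSE)
  }
  check_labels(rownames(x), "species")
  check_labels(colnames(x), "site")
  storage.mode(x) <- "double"
  bad <- which(!is.finite(x) | x < 0 | x != round(x), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "cell (%s, %s) is not a non-negative integer abundance",
      rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]
    ), call. = FALSE)
  }
  storage.mode(x) <- "integer"
  empty <- rowSums(x) == 0
  if (any(empty)) {
    warning(sprintf(
      "dropping %d species never recorded at any site: %s",
      sum(empty), paste(rownames(x)[empty], collapse = ", ")
    ), call. = FALSE)
    x <- x[!empty, , drop = FALSE]
  }
  structure(x, class = c("community_matrix", class(x)))
}

check_labels <- function(lab, what) {
  if (anyNA(lab) || any(lab == "")) {
    stop(sprintf("missing %s label", what), call. = FALSE)
  }
  dup <- unique(lab[duplicated(lab)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s label: %s", what, paste(dup, collapse = ", ")),
      call. = FALSE
    )
  }
  invisible(lab)
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf(
    "community matrix: %d species x %d sites, %d individuals, fill %d\n",
    nrow(x), ncol(x), sum(x), sum(x > 0)
  ))
  print(unclass(x), ...)
  invisible(x)
}

#' Read a community matrix from delimited text
#'
#' Expects the first row to hold site ids and the first column species ids
#' (flip with `orientation`). Comma and tab delimiters are auto-detected from
#' the file unless `delim` is given.
#'
#' @param path Path to a delimited text file.
#' @param orientation `"species_rows"` (default) or `"species_cols"`.
#' @param delim Field delimiter; `NULL` auto-detects comma vs tab.
#' @return A [community_matrix()].
#' @export
read_community_matrix <- function(path,
                                  orientation = c("species_rows", "species_cols"),
                                  delim = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(),
    show_col_types = FALSE, progress = FALSE
  )
  nonnum <- names(tab)[-1][!vapply(tab[-1], is.numeric, logical(1))]
  if (length(nonnum) > 0) {
    stop(sprintf(
      "non-numeric abundance column(s): %s", paste(nonnum, collapse = ", ")
    ), call. = FALSE)
  }
  message(sprintf(
    "read %d x %d community table from %s", nrow(tab), ncol(tab) - 1L, path
  ))
  community_matrix(as.data.frame(tab), orientation = orientation)
}

#' Write a community matrix as delimited text
#'
#' Writes species in rows with a leading `species_id` column, the layout
#' [read_community_matrix()] reads back.
#'
#' @param m A [community_matrix()].
#' @param path Output path.
#' @param delim Field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_community_matrix <- function(m, path, delim = ",") {
  m <- as_community(m)
  tab <- tibble::as_tibble(unclass(m), rownames = "species_id")
  readr::write_delim(tab, path, delim = delim)
  invisible(path)
}

# Accept either a community_matrix or a bare labelled matrix (used on null
# matrices, where all-zero rows must be kept, not dropped).
as_community <- function(m) {
  if (inherits(m, "community_matrix")) return(m)
  if (is.matrix(m) && !is.null(rownames(m)) && !is.null(colnames(m))) return(m)
  if (is.data.frame(m)) return(community_matrix(m))
  stop("expected a community matrix", call. = FALSE)
}

#' Per-site species richness and per-species abundance totals
#'
#' @param m A [community_matrix()].
#' @return A named integer vector.
#' @export
site_richness <- function(m) {
  m <- as_community(m)
  colSums(m > 0)
}

#' @rdname site_richness
#' @export
species_totals <- function(m) {
  m <- as_community(m)
  rowSums(m)
}

#' Read the site-attribute table (park areas)
#'
#' @param path Delimited text with columns `site_id` and `area` (hectares).
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return A tibble with columns `site_id`, `area`.
#' @export
read_site_attributes <- function(path, delim = NULL) {
  tab <- read_table_file(path, delim, c("site_id", "area"))
  validate_site_attributes(tab)
}

#' @rdname read_site_attributes
#' @param attrs A data frame with columns `site_id`, `area`.
#' @export
validate_site_attributes <- function(attrs) {
  attrs <- tibble::as_tibble(attrs)
  stopifnot(all(c("site_id", "area") %in% names(attrs)))
  attrs$site_id <- as.character(attrs$site_id)
  check_labels(attrs$site_id, "site")
  if (any(!is.finite(attrs$area) | attrs$area <= 0)) {
    stop("site areas must be strictly positive", call. = FALSE)
  }
  attrs
}

#' Read the species group table
#'
#' Flags used to carve analysis groups out of the community: passerine,
#' resident, diet guild and waterbird status. Waterbirds are always excluded
#' before any analysis.
#'
#' @param path Delimited text with columns `species_id`, `is_passerine`,
#'   `is_resident`, `diet_guild`, `is_waterbird`.
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return A tibble.
#' @export
read_group_table <- function(path, delim = NULL) {
  tab <- read_table_file(
    path, delim,
    c("species_id", "is_passerine", "is_resident", "diet_guild", "is_waterbird")
  )
  validate_group_table(tab)
}

diet_guilds <- c(
  "insectivorous", "omnivorous", "carnivorous",
  "nectarivorous", "granivorous", "other"
)

#' @rdname read_group_table
#' @param groups A data frame with the group-table columns.
#' @export
validate_group_table <- function(groups) {
  groups <- tibble::as_tibble(groups)
  need <- c("species_id", "is_passerine", "is_resident", "diet_guild", "is_waterbird")
  miss <- setdiff(need, names(groups))
  if (length(miss) > 0) {
    stop(sprintf("group table lacks column(s): %s", paste(miss, collapse = ", ")),
      call. = FALSE
    )
  }
  groups$species_id <- as.character(groups$species_id)
  check_labels(groups$species_id, "species")
  for (fl in c("is_passerine", "is_resident", "is_waterbird")) {
    groups[[fl]] <- as.logical(groups[[fl]])
    if (anyNA(groups[[fl]])) stop(sprintf("%s has missing flags", fl), call. = FALSE)
  }
  bad <- setdiff(unique(groups$diet_guild), diet_guilds)
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown diet guild(s): %s (must be one of %s)",
      paste(bad, collapse = ", "), paste(diet_guilds, collapse = ", ")
    ), call. = FALSE)
  }
  groups
}

#' Read the species trait table
#'
#' @param path Delimited text with a `species_id` column and one numeric
#'   column per continuous trait (e.g. body size, wing length).
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return A tibble.
#' @export
read_trait_table <- function(path, delim = NULL) {
  tab <- read_table_file(path, delim, "species_id")
  tab$species_id <- as.character(tab$species_id)
  check_labels(tab$species_id, "species")
  if (ncol(tab) < 2) stop("trait table needs at least one trait", call. = FALSE)
  nonnum <- names(tab)[-1][!vapply(tab[-1], is.numeric, logical(1))]
  if (length(nonnum) > 0) {
    stop(sprintf("non-numeric trait column(s): %s", paste(nonnum, collapse = ", ")),
      call. = FALSE
    )
  }
  tab
}

read_table_file <- function(path, delim, need) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(),
    show_col_types = FALSE, progress = FALSE
  )
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop(sprintf(
      "%s lacks column(s): %s", path, paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  message(sprintf("read %d rows from %s", nrow(tab), path))
  tibble::as_tibble(tab)
}

# Groups for which the study design has enough species to analyse; rarer
# partitions (carnivores, nectarivores, granivores, migrants, non-passerines)
# are refused.
analysis_groups <- c("all", "passerine", "resident", "insectivorous", "omnivorous")

#' Restrict a community matrix to one analysis group
#'
#' Waterbirds are removed first in every case. Only the five groups with
#' workable sample sizes are accepted (`all`, `passerine`, `resident`,
#' `insectivorous`, `omnivorous`); other partitions are refused. Sites left
#' with no species are kept — zero richness is meaningful — and species order
#' is preserved.
#'
#' @param m A [community_matrix()].
#' @param groups A group table (see [read_group_table()]).
#' @param group One of `"all"`, `"passerine"`, `"resident"`,
#'   `"insectivorous"`, `"omnivorous"`.
#' @return A [community_matrix()] restricted to the group.
#' @export
subset_by_group <- function(m, groups, group = "all") {
  m <- as_community(m)
  groups <- validate_group_table(groups)
  if (!group %in% analysis_groups) {
    stop(sprintf(
      paste0(
        "group '%s' is not analysable (insufficient sample size by design); ",
        "choose one of %s"
      ),
      group, paste(analysis_groups, collapse = ", ")
    ), call. = FALSE)
  }
  unclassified <- setdiff(rownames(m), groups$species_id)
  if (length(unclassified) > 0) {
    stop(sprintf(
      "species missing from group table: %s", paste(unclassified, collapse = ", ")
    ), call. = FALSE)
  }
  g <- groups[match(rownames(m), groups$species_id), ]
  keep <- !g$is_waterbird
  keep <- keep & switch(group,
    all = TRUE,
    passerine = g$is_passerine,
    resident = g$is_resident,
    insectivorous = g$diet_guild == "insectivorous",
    omnivorous = g$diet_guild == "omnivorous"
  )
  if (sum(keep) < 2) {
    stop(sprintf("group '%s' has fewer than 2 species after exclusions", group),
      call. = FALSE
    )
  }
  out <- m[keep, , drop = FALSE]
  structure(out, class = c("community_matrix", class(unclass(out))))
}

#' Reorder the rows and columns of a community matrix
#'
#' Ordering specs: `"marginal_totals_desc"` (decreasing row/column sums),
#' `"external_attribute_desc"` (decreasing value of a supplied attribute such
#' as park area), or `"given"` (leave as is). Ties keep the input order
#' (stable), so results are reproducible across runs.
#'
#' @param m A [community_matrix()].
#' @param rows,cols Ordering spec for each margin.
#' @param row_attr,col_attr Named numeric vector (or a `site_id`/`area`-style
#'   two-column data frame) giving the external attribute, required for
#'   `"external_attribute_desc"`.
#' @return The permuted [community_matrix()].
#' @export
order_matrix <- function(m, rows = "marginal_totals_desc",
                         cols = "marginal_totals_desc",
                         row_attr = NULL, col_attr = NULL) {
  m <- as_community(m)
  ri <- margin_order(rowSums(m), rownames(m), rows, row_attr, "row")
  ci <- margin_order(colSums(m), colnames(m), cols, col_attr, "column")
  out <- m[ri, ci, drop = FALSE]
  structure(out, class = c("community_matrix", class(unclass(out))))
}

margin_order <- function(totals, labels, spec, attr, what) {
  specs <- c("marginal_totals_desc", "external_attribute_desc", "given")
  if (!spec %in% specs) {
    stop(sprintf("unknown ordering spec '%s'", spec), call. = FALSE)
  }
  if (spec == "given") return(seq_along(labels))
  if (spec == "external_attribute_desc") {
    attr <- attribute_vector(attr)
    miss <- setdiff(labels, names(attr))
    if (length(miss) > 0) {
      stop(sprintf(
        "no attribute value for %s(s): %s", what, paste(miss, collapse = ", ")
      ), call. = FALSE)
    }
    totals <- attr[labels]
  }
  order(-totals) # stable: ties keep input order
}

attribute_vector <- function(attr) {
  if (is.data.frame(attr)) {
    if (ncol(attr) < 2) stop("attribute table needs id and value columns", call. = FALSE)
    out <- attr[[2]]
    names(out) <- as.character(attr[[1]])
    return(out)
  }
  if (is.numeric(attr) && !is.null(names(attr))) return(attr)
  stop("attribute must be a named numeric vector or two-column data frame",
    call. = FALSE
  )
}
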