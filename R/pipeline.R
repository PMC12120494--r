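#' Assemble a validated analysis configuration
#'
#' Inputs may be given as in-memory objects (community matrix, tibbles) or
#' as paths to delimited files; paths are read eagerly so a bad config fails
#' here, not mid-pipeline. Defaults reproduce the study design: five bird
#' groups, four null models, 1000 null matrices, 99 row permutations.
#'
#' @param community A [community_matrix()] or path.
#' @param areas Site-attribute table or path.
#' @param groups Group table or path.
#' @param traits Trait table or path.
#' @param which_groups Groups to analyse.
#' @param models Null models to test.
#' @param metrics Nestedness metrics to test.
#' @param n_sim Null matrices per test.
#' @param n_perm Row permutations for the functional test.
#' @param seed Single top-level seed; every stage derives its own stream
#'   from it deterministically.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(community, areas, groups, traits,
                            which_groups = analysis_groups,
                            models = c("pp", "rc", "aa", "ss"),
                            metrics = c("NODF", "WNODF"),
                            n_sim = 1000, n_perm = 99, seed = 1L) {
  if (is.character(community)) community <- read_community_matrix(community)
  if (is.character(areas)) areas <- read_site_attributes(areas)
  if (is.character(groups)) groups <- read_group_table(groups)
  if (is.character(traits)) traits <- read_trait_table(traits)
  community <- as_community(community)
  areas <- validate_site_attributes(areas)
  groups <- validate_group_table(groups)
  stopifnot(
    all(which_groups %in% analysis_groups),
    all(models %in% c("pp", "rc", "aa", "ss")),
    all(metrics %in% c("NODF", "WNODF")),
    n_sim >= 2, n_perm >= 1
  )
  miss <- setdiff(colnames(community), areas$site_id)
  if (length(miss) > 0) {
    stop(sprintf("no area for site(s): %s", paste(miss, collapse = ", ")),
      call. = FALSE
    )
  }
  structure(
    list(
      community = community, areas = areas, groups = groups, traits = traits,
      which_groups = which_groups, models = models, metrics = metrics,
      n_sim = as.integer(n_sim), n_perm = as.integer(n_perm),
      seed = as.integer(seed)
    ),
    class = "analysis_config"
  )
}

#' Run the full nestedness workflow
#'
#' Executes, in order: inventory completeness (coverage per group),
#' taxonomic nestedness of every group x metric x null-model combination,
#' the random placement passive-sampling test per group, and functional
#' nestedness (Gower + UPGMA dendrogram, treeNODF ordered by decreasing
#' area, permRows test). Each null-model test receives a non-overlapping
#' block of derived seeds, so one top-level seed reproduces the whole
#' report bit-for-bit.
#'
#' @param config An [analysis_config()].
#' @return An `analysis_report`: list of tibbles `coverage`, `nestedness`
#'   (one row per group/metric/component/model), `random_placement_sites`,
#'   `random_placement` (per-group summary), `functional` (treeNODF
#'   components with permutation statistics), plus `tree` (the dendrogram)
#'   and `provenance`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cm <- config$community
  message("stage coverage: inventory completeness per group")
  cov <- coverage_summary(cm, config$groups, config$which_groups)

  message("stage nestedness: null-model tests")
  grid <- tidyr::expand_grid(
    group = config$which_groups,
    metric = config$metrics,
    model = config$models
  )
  test_idx <- seq_len(nrow(grid))
  seeds <- config$seed + (test_idx - 1L) * (config$n_sim + 1L)
  nest <- purrr::map_dfr(test_idx, function(i) {
    sub <- subset_by_group(cm, config$groups, grid$group[i])
    res <- tidy(null_model_test(
      sub,
      metric = grid$metric[i], model = grid$model[i],
      n_sim = config$n_sim, seed = seeds[i]
    ))
    dplyr::bind_cols(tibble::tibble(group = grid$group[i]), res)
  })

  message("stage random placement: passive-sampling test per group")
  rp <- purrr::map(config$which_groups, function(g) {
    passive_sampling_test(
      subset_by_group(cm, config$groups, g), config$areas
    )
  })
  rp_sites <- purrr::map2_dfr(config$which_groups, rp, function(g, r) {
    dplyr::bind_cols(tibble::tibble(group = g), tidy(r))
  })
  rp_sum <- purrr::map2_dfr(config$which_groups, rp, function(g, r) {
    dplyr::bind_cols(tibble::tibble(group = g), glance(r))
  })

  message("stage functional: Gower + UPGMA + treeNODF + permRows")
  analysed <- subset_by_group(cm, config$groups, "all")
  tr_tab <- config$traits
  miss <- setdiff(rownames(analysed), as.character(tr_tab$species_id))
  if (length(miss) > 0) {
    stop(sprintf(
      "stage functional: species without traits: %s",
      paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  tree <- upgma(gower_distance(tr_tab))
  perm_seed <- config$seed + length(test_idx) * (config$n_sim + 1L)
  perm <- perm_rows_test(analysed, tree, config$areas,
    n_perm = config$n_perm, seed = perm_seed
  )

  structure(
    list(
      coverage = cov,
      nestedness = nest,
      random_placement_sites = rp_sites,
      random_placement = rp_sum,
      functional = tidy(perm),
      tree = tree,
      provenance = list(
        seed = config$seed, n_sim = config$n_sim, n_perm = config$n_perm,
        groups = config$which_groups, models = config$models,
        metrics = config$metrics,
        n_species = nrow(cm), n_sites = ncol(cm),
        package_version = as.character(utils::packageVersion("avinest"))
      )
    ),
    class = "analysis_report"
  )
}

#' Write an analysis report as delimited tables
#'
#' One TSV per report table plus the dendrogram as Newick and a key–value
#' provenance file. Re-running with the same config and seed reproduces the
#' files byte for byte.
#'
#' @param report An [run_analysis()] report.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c(
    "coverage", "nestedness", "random_placement_sites",
    "random_placement", "functional"
  )) {
    readr::write_tsv(report[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  ape::write.tree(report$tree, file.path(dir, "functional_dendrogram.nwk"))
  prov <- report$provenance
  readr::write_tsv(
    tibble::tibble(
      key = names(prov),
      value = vapply(prov, function(v) paste(v, collapse = ","), character(1))
    ),
    file.path(dir, "provenance.tsv")
  )
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf(
    "analysis report: %d species x %d sites, seed %d\n",
    x$provenance$n_species, x$provenance$n_sites, x$provenance$seed
  ))
  cat(sprintf(
    "  coverage: %d groups, all adequate: %s\n",
    nrow(x$coverage), all(x$coverage$adequate)
  ))
  cat(sprintf("  nestedness: %d null-test rows\n", nrow(x$nestedness)))
  cat(sprintf(
    "  passive sampling rejected for %d/%d groups\n",
    sum(x$random_placement$passive_sampling_rejected),
    nrow(x$random_placement)
  ))
  cat(sprintf(
    "  treeNODF = %.2f (p = %.3g)\n",
    x$functional$observed[x$functional$component == "treeNODF"],
    x$functional$p[x$functional$component == "treeNODF"]
  ))
  invisible(x)
}
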