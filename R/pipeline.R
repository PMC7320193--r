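#' Run the locus-heterogeneity analysis end to end
#'
#' Sequences every stage on one input bundle: read and validate the
#' catalogs, filter disease-gene pairs, assemble the group family
#' (series-based or disease-based), select and prune the complex catalog,
#' find the group-complex intersections and their summary, run the
#' randomization controls, augment with murine orthologs (series mode),
#' classify univocal versus redundant relations, and optionally write the
#' full report bundle.
#'
#' @param paths Named list of input paths: `morbid`, `genes`, `ps`, `obo`,
#'   `annotations`, `orthologs`, `matches`, `disease_hp`, optionally `gof`
#'   — exactly what [generate_universe()] returns in `$paths`.
#' @param mode `"ps_based"` (phenotypic-series groups; the default) or
#'   `"disease_based"` (disease-identifier groups; skips series grouping,
#'   ortholog augmentation and the pairwise control).
#' @param null_reps Replicates per randomization control (>= 1); 0 or less
#'   is a configuration error. The full-study setting is 100000; the
#'   default here (1000) is a desk-scale choice with the same estimator.
#' @param run_nulls Set `FALSE` to skip the randomization controls.
#' @param seed Integer; each control gets its own derived seed, so the
#'   whole report is a deterministic function of (inputs, seed).
#' @param jc_floor Jaccard floor for the exported relation graph.
#' @param out_dir If non-`NULL`, stage outputs (TSV) and `report.json` are
#'   written there; on a stage failure a `FAILED` marker file names the
#'   stage, and partial outputs are retained.
#' @return Invisibly, a list with `pairs`, `filter_report`, `groups`,
#'   `catalog`, `records`, `summary`, `nulls` (list of `lh_null_result`),
#'   `augmented`, `gof`, `lethality`, `relations`, `graph`, `report`.
#' @export
run_lh_pipeline <- function(paths,
                            mode = c("ps_based", "disease_based"),
                            null_reps = 1000L,
                            run_nulls = TRUE,
                            seed = 1L,
                            jc_floor = 0.1,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (run_nulls && null_reps < 1) stop("config: null_reps must be >= 1")
  stage <- "setup"
  on.exit({
    if (!is.null(out_dir) && dir.exists(out_dir) && stage != "done") {
      writeLines(stage, file.path(out_dir, "FAILED"))
    }
  })
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  morbid <- run_stage("catalog_io", read_morbid_map(paths$morbid))
  aux <- run_stage("catalog_io", read_aux_tables(paths))
  ontology <- run_stage("catalog_io", read_obo(paths$obo))

  fl <- run_stage("disease_catalog", filter_disease_gene_pairs(morbid, aux$genes))
  groups <- run_stage("disease_catalog", {
    if (mode == "ps_based") build_ps_groups(fl$pairs, aux$ps)
    else build_disease_groups(fl$pairs)
  })

  catalog <- run_stage("complex_catalog",
                       select_and_prune_complexes(ontology, aux$annotations))
  records <- run_stage("lh_intersection", find_intersections(groups, catalog))
  summ <- run_stage("lh_intersection",
                    summarize_intersections(records, groups, catalog))

  nulls <- list()
  if (run_nulls) {
    nulls <- run_stage("randomization", {
      lh_pool <- sort(unique(unlist(groups$proteins[groups$eligible],
                                    use.names = FALSE)))
      nonlh_pool <- setdiff(sort(unique(fl$pairs$entrez_id)), lh_pool)
      out <- list(
        pseudo_ps = run_null_control("pseudo_ps", groups, catalog,
                                     reps = null_reps, seed = seed + 1L),
        pseudo_pc = run_null_control("pseudo_pc", groups, catalog,
                                     reps = null_reps, seed = seed + 2L)
      )
      if (length(nonlh_pool) >= max(groups$n_proteins[groups$eligible], 0)) {
        out$non_lh <- run_null_control("non_lh", groups, catalog,
                                       reps = null_reps, seed = seed + 3L,
                                       nonlh_pool = nonlh_pool)
      }
      if (mode == "ps_based") {
        out$pairwise <- pairwise_control(fl$pairs, aux$ps, catalog,
                                         reps = null_reps, seed = seed + 4L)
      }
      out
    })
  }

  augmented <- NULL
  if (mode == "ps_based") {
    augmented <- run_stage("ortholog_augmentation",
                           augment_intersections(groups, catalog, aux$orthologs,
                                                 aux$matches, aux$disease_hp))
  }
  gof_ann <- NULL
  if (!is.null(aux$gof)) {
    gof_ann <- run_stage("ortholog_augmentation",
                         annotate_gof(groups, records, aux$gof, catalog))
  }
  lethality <- run_stage("ortholog_augmentation",
                         annotate_lethality(catalog, aux$orthologs))

  relations <- run_stage("nonunivocal", classify_relations(records, groups, catalog))
  graph <- run_stage("nonunivocal",
                     export_relation_graph(records, relations, jc_floor))

  report <- list(
    mode = mode, seed = seed, null_reps = if (run_nulls) null_reps else 0L,
    jc_floor = jc_floor,
    filter = stats::setNames(as.list(fl$report$n), fl$report$reason),
    n_groups = nrow(groups),
    n_groups_eligible = sum(groups$eligible),
    n_complexes = nrow(catalog$complexes),
    n_groups_hit = summ$n_groups_hit,
    pct_groups_hit = summ$pct_groups_hit,
    n_pcs_hit = summ$n_pcs_hit,
    pct_pcs_hit = summ$pct_pcs_hit,
    mean_jc = summ$mean_jc, sd_jc = summ$sd_jc, median_jc = summ$median_jc,
    nulls = lapply(nulls, function(x) {
      x[c("kind", "reps", "seed", "observed", "null_mean", "null_sd", "z")]
    }),
    n_univocal = sum(relations$univocal$univocal),
    n_nonunivocal = sum(!relations$univocal$univocal)
  )
  if (!is.null(augmented)) {
    base_groups <- unique(records$group_id)
    aug_base <- augmented[augmented$group_id %in% base_groups, ]
    report$n_groups_hit_augmented <- length(unique(augmented$group_id))
    report$mean_jc_augmented <- if (nrow(aug_base) > 0) mean(aug_base$jc_augmented) else 0
    report$median_jc_augmented <- if (nrow(aug_base) > 0) stats::median(aug_base$jc_augmented) else 0
  }

  if (!is.null(out_dir)) {
    stage <- "export"
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(fl$report, file.path(out_dir, "filter_report.tsv"),
                     progress = FALSE)
    write_protein_groups(groups, file.path(
      out_dir, if (mode == "ps_based") "ps_groups.tsv" else "disease_groups.tsv"))
    write_complex_catalog(catalog, file.path(out_dir, "complexes.tsv"),
                          file.path(out_dir, "complex_removals.tsv"))
    write_intersections(records, file.path(out_dir, "intersections.tsv"))
    for (nm in names(nulls)) {
      write_null_result(nulls[[nm]], file.path(out_dir, sprintf("null_%s.json", nm)))
    }
    if (!is.null(augmented)) {
      readr::write_tsv(tibble::tibble(
        group_id = augmented$group_id, term_id = augmented$term_id,
        n_shared = augmented$n_shared,
        presumptive = vapply(augmented$presumptive, paste, character(1),
                             collapse = ";"),
        jc = round(augmented$jc, 3),
        jc_augmented = round(augmented$jc_augmented, 3),
        is_new = augmented$is_new
      ), file.path(out_dir, "augmented.tsv"), progress = FALSE)
    }
    if (!is.null(gof_ann)) {
      readr::write_tsv(tibble::tibble(
        group_id = gof_ann$annotations$group_id,
        term_id = gof_ann$annotations$term_id,
        gof_outside_pc = vapply(gof_ann$annotations$gof_outside_pc, paste,
                                character(1), collapse = ";")
      ), file.path(out_dir, "gof_annotations.tsv"), progress = FALSE)
    }
    readr::write_tsv(tibble::tibble(
      term_id = lethality$term_id,
      essential_proteins = vapply(lethality$essential_proteins, paste,
                                  character(1), collapse = ";"),
      stages = vapply(lethality$stages, paste, character(1), collapse = ";")
    ), file.path(out_dir, "lethality_annotations.tsv"), progress = FALSE)
    readr::write_tsv(relations$one_to_many,
                     file.path(out_dir, "relations_one_to_many.tsv"),
                     progress = FALSE)
    readr::write_tsv(relations$many_to_one,
                     file.path(out_dir, "relations_many_to_one.tsv"),
                     progress = FALSE)
    readr::write_tsv(graph, file.path(out_dir, "relation_graph.tsv"),
                     progress = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- "done"

  invisible(list(pairs = fl$pairs, filter_report = fl$report, groups = groups,
                 catalog = catalog, records = records, summary = summ,
                 nulls = nulls, augmented = augmented, gof = gof_ann,
                 lethality = lethality, relations = relations, graph = graph,
                 report = report))
}
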