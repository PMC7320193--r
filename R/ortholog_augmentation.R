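# HP phenotype terms reachable from each human gene through its mouse
# ortholog's MP terms and the MP->HP best-match table
protein_hp_terms <- function(orthologs, matches) {
  hp_of_mp <- split(matches$hp_term, matches$mp_term)
  hp <- lapply(orthologs$mp_terms, function(mp) {
    unique(unlist(hp_of_mp[mp], use.names = FALSE))
  })
  agg <- lapply(split(hp, orthologs$human_entrez_id),
                function(x) unique(unlist(x, use.names = FALSE)))
  agg[lengths(agg) > 0]
}

#' Find presumptive disease proteins for one group-complex intersection
#'
#' A complex member that is not (yet) a disease protein of the phenotypic
#' series is promoted to a presumptive disease protein when its mouse
#' ortholog carries at least one Mammalian Phenotype term whose best-match
#' Human Phenotype term is annotated to at least one disease of the series.
#' Resemblance is exact term identity after the MP-to-HP translation; no
#' ontology-ancestor expansion is applied.
#'
#' @param group_proteins Disease proteins of the series.
#' @param pc_proteins Members of the complex.
#' @param ps_diseases Disease identifiers belonging to the series.
#' @param orthologs Tibble from [read_ortholog_phenotypes()].
#' @param matches Tibble from [read_phenotype_matches()].
#' @param disease_hp Tibble from [read_disease_phenotypes()].
#' @return Sorted vector of presumptive protein ids (possibly empty),
#'   always disjoint from `group_proteins`.
#' @export
find_presumptive_proteins <- function(group_proteins, pc_proteins, ps_diseases,
                                      orthologs, matches, disease_hp) {
  hp_by_protein <- protein_hp_terms(orthologs, matches)
  ps_hp <- unique(unlist(
    disease_hp$hp_terms[disease_hp$phenotype_mim %in% ps_diseases],
    use.names = FALSE
  ))
  candidates <- setdiff(pc_proteins, group_proteins)
  hits <- vapply(as.character(candidates), function(p) {
    hp <- hp_by_protein[[p]]
    !is.null(hp) && length(intersect(hp, ps_hp)) > 0
  }, logical(1))
  sort(candidates[hits])
}

#' Recalculate a Jaccard coefficient after adding presumptive proteins
#'
#' Presumptive disease proteins are added to the group-complex
#' intersection only; the union term keeps the ORIGINAL group size. With
#' intersection `i`, `m` presumptive proteins, group size `g` and complex
#' size `p`: `jc' = (i + m) / (g + p - (i + m))`. This is the reading of
#' the augmentation rule that turns the 4-in-12 worked example (JC 0.33)
#' into 0.60 with two presumptive proteins; recomputing a standard union
#' over an enlarged group would give 0.50 instead (see the methods
#' vignette).
#'
#' @param n_shared Size of the original intersection (`i`).
#' @param n_presumptive Number of presumptive proteins added (`m`);
#'   presumptive proteins are complex members, so `i + m` cannot exceed
#'   the complex size.
#' @param group_size,pc_size Original group and complex sizes.
#' @return The augmented coefficient, always `>=` the base one, equal
#'   exactly when `m = 0`.
#' @export
augmented_jaccard <- function(n_shared, n_presumptive, group_size, pc_size) {
  if (any(n_shared + n_presumptive > pc_size)) {
    stop("intersection plus presumptive proteins exceeds the complex size")
  }
  if (any(n_shared > group_size)) stop("intersection exceeds the group size")
  (n_shared + n_presumptive) / (group_size + pc_size - (n_shared + n_presumptive))
}

#' Augment a series-complex intersection analysis with murine orthologs
#'
#' For every eligible series-complex pair, finds the presumptive disease
#' proteins ([find_presumptive_proteins()]) and recomputes the Jaccard
#' coefficient ([augmented_jaccard()]). Pairs whose original intersection
#' was below two proteins but reach two when presumptive proteins are
#' included enter the output as NEW records (`is_new = TRUE`) — this is how
#' augmentation raises the count of series intersecting a complex, not
#' just the coefficients of existing records.
#'
#' @param groups Series-based protein groups (from [build_ps_groups()];
#'   must carry the `diseases` list column).
#' @param catalog `lh_complex_catalog`.
#' @param orthologs,matches,disease_hp Ortholog-phenotype inputs.
#' @param min_total Minimum `n_shared + n_presumptive` for a record
#'   (default 2).
#' @return Tibble `group_id`, `term_id`, `shared`, `n_shared`,
#'   `presumptive` (list), `n_presumptive`, `jc` (base coefficient of the
#'   pair), `jc_augmented`, `group_size`, `pc_size`, `is_new`.
#' @export
augment_intersections <- function(groups, catalog, orthologs, matches, disease_hp,
                                  min_total = 2L) {
  stopifnot(inherits(catalog, "lh_complex_catalog"))
  if (!"diseases" %in% names(groups)) {
    stop("augmentation needs series-based groups carrying their member diseases")
  }
  g <- groups[groups$eligible, ]
  pcs <- catalog$complexes

  hp_by_protein <- protein_hp_terms(orthologs, matches)
  hp_of_disease <- stats::setNames(disease_hp$hp_terms, disease_hp$phenotype_mim)

  out <- list()
  for (gi in seq_len(nrow(g))) {
    gp <- g$proteins[[gi]]
    ps_hp <- unique(unlist(hp_of_disease[as.character(g$diseases[[gi]])],
                           use.names = FALSE))
    for (ci in seq_len(nrow(pcs))) {
      cp <- pcs$proteins[[ci]]
      shared <- intersect(gp, cp)
      candidates <- setdiff(cp, gp)
      pres <- candidates[vapply(as.character(candidates), function(p) {
        hp <- hp_by_protein[[p]]
        !is.null(hp) && length(intersect(hp, ps_hp)) > 0
      }, logical(1))]
      i <- length(shared)
      m <- length(pres)
      if (i + m < min_total || i == 0) next
      gs <- g$n_proteins[gi]
      ps_sz <- pcs$n_proteins[ci]
      out[[length(out) + 1L]] <- tibble::tibble(
        group_id = g$group_id[gi], term_id = pcs$term_id[ci],
        shared = list(sort(shared)), n_shared = i,
        presumptive = list(sort(pres)), n_presumptive = m,
        jc = i / (gs + ps_sz - i),
        jc_augmented = augmented_jaccard(i, m, gs, ps_sz),
        group_size = gs, pc_size = ps_sz,
        is_new = i < min_total
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(group_id = character(0), term_id = character(0),
                          shared = list(), n_shared = integer(0),
                          presumptive = list(), n_presumptive = integer(0),
                          jc = double(0), jc_augmented = double(0),
                          group_size = integer(0), pc_size = integer(0),
                          is_new = logical(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$group_id, res$term_id), ]
}

#' Annotate gain-of-function disease proteins falling outside the complex
#'
#' Gain-of-function mutations can cause a disease of the series without
#' the mutated protein belonging to the intersecting complex. For every
#' series-complex record this lists the flagged series proteins absent
#' from the complex; series carrying flagged proteins but intersecting no
#' complex at all are reported separately.
#'
#' @param groups Protein groups (series- or disease-based).
#' @param records Intersection records ([find_intersections()]).
#' @param gof_flags Vector of protein ids with curated gain-of-function
#'   annotation (an input table, not inferred).
#' @param catalog `lh_complex_catalog` (for complex membership).
#' @return List with `annotations` (tibble `group_id`, `term_id`,
#'   `gof_outside_pc` list, `n_gof_outside`) and `no_intersection` (tibble
#'   `group_id`, `gof_proteins` for eligible groups without any record).
#' @export
annotate_gof <- function(groups, records, gof_flags, catalog) {
  pcs <- catalog$complexes
  ann <- tibble::tibble(
    group_id = records$group_id,
    term_id = records$term_id,
    gof_outside_pc = lapply(seq_len(nrow(records)), function(k) {
      gp <- groups$proteins[[match(records$group_id[k], groups$group_id)]]
      cp <- pcs$proteins[[match(records$term_id[k], pcs$term_id)]]
      sort(setdiff(intersect(gp, gof_flags), cp))
    })
  )
  ann$n_gof_outside <- lengths(ann$gof_outside_pc)

  g <- groups[groups$eligible, ]
  miss <- g[!g$group_id %in% records$group_id, ]
  no_int <- tibble::tibble(
    group_id = miss$group_id,
    gof_proteins = lapply(miss$proteins, function(p) sort(intersect(p, gof_flags)))
  )
  no_int <- no_int[lengths(no_int$gof_proteins) > 0, ]
  list(annotations = ann, no_intersection = no_int)
}

#' Annotate complexes containing essential proteins
#'
#' A complex member is essential when its mouse ortholog causes pre-birth
#' lethality (embryonic, fetal or prenatal stage). Loss-of-function
#' mutations of such proteins may never surface as post-natal disease,
#' which is one reason series-complex intersections stay partial.
#'
#' @param catalog `lh_complex_catalog`.
#' @param orthologs Tibble from [read_ortholog_phenotypes()].
#' @return Tibble `term_id`, `essential_proteins` (list), `stages` (list of
#'   stage per protein, same order), `n_essential`; one row per complex
#'   with at least one essential member.
#' @export
annotate_lethality <- function(catalog, orthologs) {
  lethal <- orthologs[orthologs$lethality_stage != "none", ]
  stage_of <- stats::setNames(lethal$lethality_stage, lethal$human_entrez_id)
  pcs <- catalog$complexes
  rows <- lapply(seq_len(nrow(pcs)), function(k) {
    ess <- sort(intersect(pcs$proteins[[k]], lethal$human_entrez_id))
    if (length(ess) == 0) return(NULL)
    tibble::tibble(term_id = pcs$term_id[k],
                   essential_proteins = list(ess),
                   stages = list(unname(stage_of[as.character(ess)])),
                   n_essential = length(ess))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(tibble::tibble(term_id = character(0), essential_proteins = list(),
                          stages = list(), n_essential = integer(0)))
  }
  do.call(rbind, rows)
}
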