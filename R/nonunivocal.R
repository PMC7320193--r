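# all ancestors of each node by BFS over child -> parent edges
ancestor_sets <- function(edges) {
  parents_of <- split(edges$parent_id, edges$term_id)
  nodes <- unique(c(edges$term_id, edges$parent_id))
  anc <- stats::setNames(vector("list", length(nodes)), nodes)
  for (n in nodes) {
    seen <- character(0)
    frontier <- parents_of[[n]]
    while (length(frontier) > 0) {
      frontier <- setdiff(unique(frontier), seen)
      seen <- c(seen, frontier)
      frontier <- unlist(parents_of[frontier], use.names = FALSE)
    }
    anc[[n]] <- seen
  }
  anc
}

#' Classify complex pairs intersecting the same group (one-to-many)
#'
#' A series intersecting several complexes is often an artifact of
#' annotation redundancy rather than true mechanistic multiplicity. For
#' every group with two or more intersecting complexes, each complex pair
#' is discarded under the FIRST matching rule, or kept:
#'
#' 1. `parent_child` — one complex is an ancestor of the other (transitive
#'    closure of `is_a`/`part_of` within all selected complex terms,
#'    including terms pruned from the analysis catalog);
#' 2. `common_parent` — the two complexes share a direct parent (the three
#'    generic umbrella terms do not count as a shared parent);
#' 3. `majority_shared` — the complexes share more than half the protein
#'    content of the smaller one (strict `>`), suggesting variants of the
#'    same biochemical entity.
#'
#' @param records Intersection records ([find_intersections()]).
#' @param catalog `lh_complex_catalog` (its `hierarchy` spans kept and
#'   pruned selected terms).
#' @return Tibble `group_id`, `term_i`, `term_j` (`term_i < term_j`),
#'   `status` (kept/discarded), `reason` (`NA` when kept).
#' @export
filter_one_to_many <- function(records, catalog) {
  stopifnot(inherits(catalog, "lh_complex_catalog"))
  anc <- ancestor_sets(catalog$hierarchy)
  parents_of <- split(catalog$hierarchy$parent_id, catalog$hierarchy$term_id)
  prot <- stats::setNames(catalog$complexes$proteins, catalog$complexes$term_id)

  by_group <- split(records$term_id, records$group_id)
  by_group <- by_group[lengths(by_group) >= 2]
  out <- list()
  for (gid in names(by_group)) {
    terms <- sort(unique(by_group[[gid]]))
    cmb <- utils::combn(terms, 2)
    for (k in seq_len(ncol(cmb))) {
      ti <- cmb[1, k]; tj <- cmb[2, k]
      reason <- NA_character_
      if (tj %in% anc[[ti]] || ti %in% anc[[tj]]) {
        reason <- "parent_child"
      } else {
        shared_parents <- setdiff(intersect(parents_of[[ti]], parents_of[[tj]]),
                                  catalog$generic_ids)
        if (length(shared_parents) > 0) {
          reason <- "common_parent"
        } else {
          pi <- prot[[ti]]; pj <- prot[[tj]]
          if (length(intersect(pi, pj)) > 0.5 * min(length(pi), length(pj))) {
            reason <- "majority_shared"
          }
        }
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        group_id = gid, term_i = ti, term_j = tj,
        status = if (is.na(reason)) "kept" else "discarded",
        reason = reason
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(group_id = character(0), term_i = character(0),
                          term_j = character(0), status = character(0),
                          reason = character(0)))
  }
  do.call(rbind, out)
}

#' Classify group pairs intersecting the same complex (many-to-one)
#'
#' Several series intersecting one complex often reflect allele
#' heterogeneity: the same protein, mutated differently, causes diseases
#' in more than one series. For every complex with two or more
#' intersecting groups, a group pair is discarded (reason
#' `allele_heterogeneity`) when the two series share at least one
#' annotating disease protein, and kept otherwise.
#'
#' @param records Intersection records.
#' @param groups Protein groups the records were computed from.
#' @return Tibble `term_id`, `group_i`, `group_j`, `status`, `reason`.
#' @export
filter_many_to_one <- function(records, groups) {
  prot <- stats::setNames(groups$proteins, groups$group_id)
  by_pc <- split(records$group_id, records$term_id)
  by_pc <- by_pc[lengths(by_pc) >= 2]
  out <- list()
  for (tid in names(by_pc)) {
    gs <- sort(unique(by_pc[[tid]]))
    cmb <- utils::combn(gs, 2)
    for (k in seq_len(ncol(cmb))) {
      gi <- cmb[1, k]; gj <- cmb[2, k]
      shared <- length(intersect(prot[[gi]], prot[[gj]])) > 0
      out[[length(out) + 1L]] <- tibble::tibble(
        term_id = tid, group_i = gi, group_j = gj,
        status = if (shared) "discarded" else "kept",
        reason = if (shared) "allele_heterogeneity" else NA_character_
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(term_id = character(0), group_i = character(0),
                          group_j = character(0), status = character(0),
                          reason = character(0)))
  }
  do.call(rbind, out)
}

# union-find over character labels
component_count <- function(nodes, edge_a, edge_b) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (k in seq_along(edge_a)) {
    ra <- find(match(edge_a[[k]], nodes))
    rb <- find(match(edge_b[[k]], nodes))
    if (ra != rb) parent[[rb]] <- ra
  }
  length(unique(vapply(seq_along(nodes), find, numeric(1))))
}

#' Full univocality classification of series-complex relations
#'
#' Runs both redundancy filters and decides, per group, whether its
#' relation to the complex catalog is univocal. Complexes whose pairwise
#' relation was discarded as redundant are treated as one effective
#' complex (connected components of the discarded-pair graph); a group is
#' univocal when it is left with exactly one effective intersecting
#' complex.
#'
#' @param records Intersection records.
#' @param groups Protein groups.
#' @param catalog `lh_complex_catalog`.
#' @return An object of class `lh_relations`: list with `one_to_many`,
#'   `many_to_one` (the two pair classifications) and `univocal` (tibble
#'   `group_id`, `n_pcs`, `n_effective_pcs`, `univocal`).
#' @export
classify_relations <- function(records, groups, catalog) {
  otm <- filter_one_to_many(records, catalog)
  mto <- filter_many_to_one(records, groups)

  by_group <- split(records$term_id, records$group_id)
  uni <- lapply(names(by_group), function(gid) {
    terms <- sort(unique(by_group[[gid]]))
    if (length(terms) == 1) {
      n_eff <- 1L
    } else {
      disc <- otm[otm$group_id == gid & otm$status == "discarded", ]
      n_eff <- component_count(terms, disc$term_i, disc$term_j)
    }
    tibble::tibble(group_id = gid, n_pcs = length(terms),
                   n_effective_pcs = as.integer(n_eff),
                   univocal = n_eff == 1L)
  })
  uni <- if (length(uni) > 0) do.call(rbind, uni) else
    tibble::tibble(group_id = character(0), n_pcs = integer(0),
                   n_effective_pcs = integer(0), univocal = logical(0))

  structure(list(one_to_many = otm, many_to_one = mto, univocal = uni),
            class = "lh_relations")
}

#' @export
print.lh_relations <- function(x, ...) {
  cat("<lh_relations> ", sum(x$univocal$univocal), "/", nrow(x$univocal),
      " groups univocal; ", sum(x$one_to_many$status == "discarded"),
      " redundant complex pairs, ", sum(x$many_to_one$status == "discarded"),
      " allele-heterogeneity series pairs\n", sep = "")
  invisible(x)
}

#' Export the series-complex relation graph as an edge list
#'
#' Bipartite edge list suitable for any graph tool. An edge's complex is
#' flagged `redundant` when, within its group, it participates only in
#' discarded pairs; the reason shown is the first one recorded for it.
#' Edges are filtered at `jc >= jc_floor` (display convention of the
#' relation figures: 0.1).
#'
#' @param records Intersection records.
#' @param relations `lh_relations` from [classify_relations()].
#' @param jc_floor Minimum Jaccard coefficient for an edge (default 0.1);
#'   0 keeps every edge.
#' @return Tibble `group_id`, `term_id`, `jc`, `n_shared`, `status`
#'   (kept/redundant), `reason`.
#' @export
export_relation_graph <- function(records, relations, jc_floor = 0.1) {
  keep <- records$jc >= jc_floor
  rec <- records[keep, ]
  otm <- relations$one_to_many
  status <- character(nrow(rec))
  reason <- rep(NA_character_, nrow(rec))
  for (k in seq_len(nrow(rec))) {
    rows <- otm[otm$group_id == rec$group_id[k] &
                  (otm$term_i == rec$term_id[k] | otm$term_j == rec$term_id[k]), ]
    if (nrow(rows) > 0 && all(rows$status == "discarded")) {
      status[k] <- "redundant"
      reason[k] <- rows$reason[[1]]
    } else {
      status[k] <- "kept"
    }
  }
  tibble::tibble(group_id = rec$group_id, term_id = rec$term_id,
                 jc = rec$jc, n_shared = rec$n_shared,
                 status = status, reason = reason)
}
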