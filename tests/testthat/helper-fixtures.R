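# in-code fixtures shared across the suite; no files on disk except via tempfile()

make_groups <- function(sets, role = "ps", diseases = NULL) {
  g <- tibble::tibble(
    group_id = names(sets),
    role = role,
    proteins = lapply(unname(sets), function(p) sort(unique(p))),
    n_proteins = unname(vapply(sets, function(p) length(unique(p)), integer(1)))
  )
  g$eligible <- g$n_proteins >= 2L
  if (!is.null(diseases)) {
    g$diseases <- unname(diseases)
    g$n_diseases <- lengths(diseases)
  }
  g
}

make_catalog <- function(sets, edges = NULL, generic_ids = GENERIC_COMPLEX_IDS) {
  cx <- tibble::tibble(
    term_id = names(sets),
    name = paste(names(sets), "complex"),
    class = "non_parent",
    proteins = lapply(unname(sets), function(p) sort(unique(p))),
    n_proteins = unname(vapply(sets, function(p) length(unique(p)), integer(1)))
  )
  if (is.null(edges)) {
    edges <- tibble::tibble(term_id = character(0), parent_id = character(0),
                            relation = character(0))
  }
  structure(list(complexes = cx, selected = cx, hierarchy = edges,
                 removal_log = tibble::tibble(term_id = character(0),
                                              reason = character(0)),
                 generic_ids = generic_ids),
            class = "lh_complex_catalog")
}

# independent oracle: direct double loop over all (group, complex) pairs
brute_force_intersections <- function(groups, catalog, min_shared = 2L) {
  g <- groups[groups$eligible, ]
  pcs <- catalog$complexes
  out <- list()
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(nrow(pcs))) {
      shared_set <- sort(intersect(g$proteins[[i]], pcs$proteins[[j]]))
      if (length(shared_set) < min_shared) next
      out[[length(out) + 1L]] <- tibble::tibble(
        group_id = g$group_id[i], term_id = pcs$term_id[j],
        shared = list(shared_set), n_shared = length(shared_set),
        jc = length(shared_set) /
          length(union(g$proteins[[i]], pcs$proteins[[j]])),
        group_size = g$n_proteins[i], pc_size = pcs$n_proteins[j]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(group_id = character(0), term_id = character(0),
                          shared = list(), n_shared = integer(0), jc = double(0),
                          group_size = integer(0), pc_size = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$group_id, res$term_id), ]
}

# random toy universe over <= `n_proteins` proteins
random_toy_world <- function(n_proteins = 50, n_groups = 6, n_pcs = 8) {
  pool <- seq_len(n_proteins)
  groups <- make_groups(stats::setNames(
    lapply(seq_len(n_groups), function(i) sample(pool, sample(2:8, 1))),
    sprintf("G%02d", seq_len(n_groups))
  ))
  catalog <- make_catalog(stats::setNames(
    lapply(seq_len(n_pcs), function(i) sample(pool, sample(2:12, 1))),
    sprintf("GO:%07d", seq_len(n_pcs))
  ))
  list(groups = groups, catalog = catalog)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

morbid_file <- function(lines) write_lines_tmp(lines, ".tsv")

gene_catalog_tbl <- function(gene_mim, entrez_id = gene_mim - 500000L,
                             status = "active", protein_coding = TRUE) {
  tibble::tibble(gene_mim = gene_mim, entrez_id = entrez_id,
                 status = status, protein_coding = protein_coding)
}
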