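#' Filter morbid-map rows to validated disease-gene pairs
#'
#' Applies, in a fixed order, the row-level discard rules that define a
#' "disease" for the locus-heterogeneity analysis, then maps gene MIMs to
#' Entrez protein identifiers through the gene catalog. A row is counted
#' under the FIRST rule it violates, so discard-reason counts are
#' reproducible:
#'
#' 1. `unconfirmed` / `non_disease` / `susceptibility` — phenotype label
#'    carrying a leading `?`, enclosing `[ ]` or `{ }`;
#' 2. `mapping_key` — key 1, 2 or 4 (only key 3, molecular basis known,
#'    survives);
#' 3. `no_phenotype_mim` — phenotype without its own MIM identifier;
#' 4. `gene_unmapped` — gene MIM absent from the catalog, with status
#'    moved/removed, or lacking an Entrez id;
#' 5. `non_coding` — the gene does not code for a protein.
#'
#' @param rows Tibble from [read_morbid_map()].
#' @param genes Tibble from [read_gene_catalog()].
#' @return A list with
#'   \describe{
#'     \item{pairs}{tibble of unique `(phenotype_mim, entrez_id)` pairs,
#'       with the originating `gene_mim` retained for reporting}
#'     \item{report}{tibble `reason`, `n` — counts of discarded rows per
#'       reason (fixed reason order, zero counts included) plus a final
#'       `retained` row}
#'   }
#' @export
filter_disease_gene_pairs <- function(rows, genes) {
  reasons <- c("unconfirmed", "non_disease", "susceptibility", "mapping_key",
               "no_phenotype_mim", "gene_unmapped", "non_coding")

  gene_idx <- match(rows$gene_mim, genes$gene_mim)
  entrez <- genes$entrez_id[gene_idx]
  status <- genes$status[gene_idx]
  coding <- genes$protein_coding[gene_idx]

  reason <- rep(NA_character_, nrow(rows))
  unset <- function() is.na(reason)

  reason[unset() & rows$marker == "question"] <- "unconfirmed"
  reason[unset() & rows$marker == "brackets"] <- "non_disease"
  reason[unset() & rows$marker == "braces"] <- "susceptibility"
  reason[unset() & rows$mapping_key != 3L] <- "mapping_key"
  reason[unset() & is.na(rows$phenotype_mim)] <- "no_phenotype_mim"
  reason[unset() & (is.na(gene_idx) | status %in% c("moved", "removed") | is.na(entrez))] <-
    "gene_unmapped"
  reason[unset() & !coding] <- "non_coding"

  keep <- is.na(reason)
  pairs <- tibble::tibble(
    phenotype_mim = rows$phenotype_mim[keep],
    entrez_id = entrez[keep],
    gene_mim = rows$gene_mim[keep]
  )
  pairs <- pairs[!duplicated(pairs[c("phenotype_mim", "entrez_id")]), ]

  counts <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE), integer(1))
  report <- tibble::tibble(reason = c(reasons, "retained"),
                           n = c(unname(counts), sum(keep)))
  list(pairs = pairs, report = report)
}

new_protein_groups <- function(group_id, role, proteins, extra = NULL) {
  tbl <- tibble::tibble(
    group_id = group_id,
    role = role,
    proteins = proteins,
    n_proteins = lengths(proteins)
  )
  if (!is.null(extra)) tbl <- tibble::as_tibble(cbind(tbl, extra))
  tbl
}

#' Assemble disease-based locus-heterogeneity groups
#'
#' One protein group per distinct disease identifier. Diseases annotated by
#' two or more distinct proteins are the disease-based instances of locus
#' heterogeneity; single-protein diseases are retained in the output but
#' flagged ineligible, so the non-LH tally stays available.
#'
#' @param pairs Tibble of validated pairs (`pairs` element of
#'   [filter_disease_gene_pairs()]).
#' @return Tibble `group_id` (disease MIM as character), `role = "disease"`,
#'   `proteins` (list of integer Entrez ids), `n_proteins`, `eligible`
#'   (`n_proteins >= 2`).
#' @export
build_disease_groups <- function(pairs) {
  prot <- lapply(split(pairs$entrez_id, pairs$phenotype_mim), function(p) sort(unique(p)))
  grp <- new_protein_groups(names(prot), "disease", unname(prot))
  grp$eligible <- grp$n_proteins >= 2L
  grp[order(grp$group_id), ]
}

#' Assemble phenotypic-series-based locus-heterogeneity groups
#'
#' One protein group per phenotypic series (PS) having at least two member
#' diseases with a surviving disease-gene pair; the group's protein set is
#' the union over its member diseases. Series referencing no surviving
#' disease are dropped with a warning. A series whose diseases collapse to
#' a single protein is kept (it still has two molecularly characterized
#' diseases) but flagged via `single_protein`, and is ineligible for the
#' intersection analysis, which needs two shareable proteins.
#'
#' @param pairs Tibble of validated pairs.
#' @param ps Tibble from [read_ps_membership()].
#' @return Tibble `group_id` (PS id), `role = "ps"`, `proteins`,
#'   `n_proteins`, `diseases` (list of member disease MIMs with a surviving
#'   pair), `n_diseases`, `single_protein`, `eligible`.
#' @export
build_ps_groups <- function(pairs, ps) {
  known <- ps[ps$phenotype_mim %in% pairs$phenotype_mim, ]
  dropped <- setdiff(unique(ps$ps_id), unique(known$ps_id))
  if (length(dropped) > 0) {
    warning("PS with no surviving disease dropped: ", paste(dropped, collapse = ", "))
  }

  dis_by_ps <- lapply(split(known$phenotype_mim, known$ps_id),
                      function(d) sort(unique(d)))
  dis_by_ps <- dis_by_ps[vapply(dis_by_ps, length, integer(1)) >= 2L]

  prot_of_disease <- split(pairs$entrez_id, pairs$phenotype_mim)
  prot <- lapply(dis_by_ps, function(dd) {
    sort(unique(unlist(prot_of_disease[as.character(dd)], use.names = FALSE)))
  })

  grp <- new_protein_groups(names(dis_by_ps), "ps", unname(prot))
  grp$diseases <- unname(dis_by_ps)
  grp$n_diseases <- lengths(dis_by_ps)
  grp$single_protein <- grp$n_proteins < 2L
  grp$eligible <- grp$n_proteins >= 2L
  grp[order(grp$group_id), ]
}

#' Write protein groups to TSV
#'
#' @param groups Tibble from [build_disease_groups()] or [build_ps_groups()].
#' @param path Output path; protein ids are semicolon-joined.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(groups, path) {
  readr::write_tsv(tibble::tibble(
    group_id = groups$group_id,
    n_proteins = groups$n_proteins,
    proteins = vapply(groups$proteins, paste, character(1), collapse = ";")
  ), path, progress = FALSE)
  invisible(path)
}
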