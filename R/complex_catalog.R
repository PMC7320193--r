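#' Generic complex terms excluded from the analysis catalog
#'
#' Protein complex (GO:0043234), transcription factor complex (GO:0005667)
#' and macromolecular complex (GO:0032991): umbrella terms too generic to
#' act as a concrete molecular machine.
#' @export
GENERIC_COMPLEX_IDS <- c("GO:0043234", "GO:0005667", "GO:0032991")

#' Select and prune protein-complex terms from an ontology
#'
#' A protein complex (PC) is any non-obsolete cellular-component term whose
#' name contains the string "complex" (case-insensitive, anywhere in the
#' name). The selection is then pruned to the analysis catalog:
#'
#' 1. attach directly annotated proteins per term (no propagation up the
#'    hierarchy — see the methods vignette for why);
#' 2. classify every selected term as non-parent / parent / parent-of-parent
#'    using `is_a` and `part_of` edges restricted to the selected set
#'    (parent-of-parent = has a selected child that itself has a selected
#'    child; no deeper transitivity);
#' 3. remove parents of parents, unless at least one selected child is
#'    devoid of proteins (removing the parent would then lose its
#'    annotation content with nothing below to carry it);
#' 4. remove the generic terms [GENERIC_COMPLEX_IDS];
#' 5. remove complexes with fewer than two proteins.
#'
#' Each removed term is logged once, under the first rule that removed it.
#'
#' @param ontology `lh_ontology` from [read_obo()].
#' @param annotations Tibble from [read_annotations()]. Annotations to terms
#'   absent from the ontology are dropped with a warning.
#' @param generic_ids Term ids removed as generic; default
#'   [GENERIC_COMPLEX_IDS].
#' @return An object of class `lh_complex_catalog`: a list with
#'   \describe{
#'     \item{complexes}{tibble of kept PCs: `term_id`, `name`, `class`,
#'       `proteins` (list of Entrez ids), `n_proteins`}
#'     \item{selected}{tibble of all selected terms before pruning, with
#'       the same columns}
#'     \item{hierarchy}{parent edges among all selected terms (kept and
#'       removed): `term_id` (child), `parent_id`, `relation`}
#'     \item{removal_log}{tibble `term_id`, `reason` in
#'       parent_of_parent/generic/singleton}
#'   }
#' @export
select_and_prune_complexes <- function(ontology, annotations,
                                       generic_ids = GENERIC_COMPLEX_IDS) {
  stopifnot(inherits(ontology, "lh_ontology"))
  terms <- ontology$terms

  unknown <- !annotations$term_id %in% terms$term_id
  if (any(unknown)) {
    warning("dropping ", sum(unknown), " annotation(s) to term(s) absent from the ontology")
    annotations <- annotations[!unknown, ]
  }

  is_cc <- is.na(terms$namespace) | terms$namespace == "cellular_component"
  sel <- terms[!terms$obsolete & is_cc & grepl("complex", terms$name, ignore.case = TRUE), ]

  edges <- ontology$edges
  edges <- edges[edges$term_id %in% sel$term_id & edges$parent_id %in% sel$term_id &
                   edges$relation %in% c("is_a", "part_of"), ]

  prot_by_term <- lapply(split(annotations$entrez_id, annotations$term_id),
                         function(p) sort(unique(p)))
  proteins <- lapply(sel$term_id, function(id) {
    p <- prot_by_term[[id]]
    if (is.null(p)) integer(0) else p
  })

  # classification on the selected set: parent has >=1 selected child;
  # parent-of-parent has a selected child that is itself a parent
  has_child <- sel$term_id %in% edges$parent_id
  names(has_child) <- sel$term_id
  parents_of_parents <- unique(edges$parent_id[has_child[edges$term_id]])
  cls <- ifelse(sel$term_id %in% parents_of_parents, "parent_of_parent",
                ifelse(has_child[sel$term_id], "parent", "non_parent"))

  selected <- tibble::tibble(
    term_id = sel$term_id, name = sel$name, class = cls,
    proteins = proteins, n_proteins = lengths(proteins)
  )
  selected <- selected[order(selected$term_id), ]

  removed <- character(0)
  reason <- character(0)
  note_removed <- function(ids, why) {
    new <- setdiff(ids, removed)
    removed <<- c(removed, new)
    reason <<- c(reason, rep(why, length(new)))
  }

  n_prot <- stats::setNames(selected$n_proteins, selected$term_id)
  children_of <- split(edges$term_id, edges$parent_id)
  pop_ids <- selected$term_id[selected$class == "parent_of_parent"]
  pop_drop <- pop_ids[vapply(pop_ids, function(id) {
    all(n_prot[children_of[[id]]] > 0)
  }, logical(1))]
  note_removed(pop_drop, "parent_of_parent")
  note_removed(intersect(generic_ids, selected$term_id), "generic")
  left <- setdiff(selected$term_id, removed)
  note_removed(left[n_prot[left] < 2], "singleton")

  kept <- selected[!selected$term_id %in% removed, ]
  structure(list(
    complexes = kept,
    selected = selected,
    hierarchy = edges[c("term_id", "parent_id", "relation")],
    removal_log = tibble::tibble(term_id = removed, reason = reason),
    generic_ids = generic_ids
  ), class = "lh_complex_catalog")
}

#' @export
print.lh_complex_catalog <- function(x, ...) {
  cat("<lh_complex_catalog> ", nrow(x$complexes), " complexes kept of ",
      nrow(x$selected), " selected (",
      paste(sprintf("%s: %d", names(table(x$removal_log$reason)),
                    as.integer(table(x$removal_log$reason))), collapse = ", "),
      " removed)\n", sep = "")
  invisible(x)
}

#' Write the pruned complex catalog and its removal log to TSV
#'
#' @param catalog `lh_complex_catalog`.
#' @param path,removals_path Output paths (`removals_path` optional).
#' @return `path`, invisibly.
#' @export
write_complex_catalog <- function(catalog, path, removals_path = NULL) {
  readr::write_tsv(tibble::tibble(
    term_id = catalog$complexes$term_id,
    name = catalog$complexes$name,
    n_proteins = catalog$complexes$n_proteins,
    proteins = vapply(catalog$complexes$proteins, paste, character(1), collapse = ";")
  ), path, progress = FALSE)
  if (!is.null(removals_path)) {
    readr::write_tsv(catalog$removal_log, removals_path, progress = FALSE)
  }
  invisible(path)
}
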