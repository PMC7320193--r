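#' Read an OMIM-style morbid map
#'
#' Parses the 4-column tab-separated morbid-map dialect: phenotype label
#' (optionally carrying a leading `?`, enclosing `[ ]` or `{ }`, an embedded
#' 6-digit phenotype MIM and a parenthesized mapping key), comma-separated
#' gene symbols, gene MIM and cytogenetic location. Marker characters are
#' detected but NOT stripped; all filtering happens downstream in
#' [filter_disease_gene_pairs()].
#'
#' @param path Path to a UTF-8 TSV file. Lines starting with `#` are comments.
#' @return A tibble with one row per data line: `line` (source line number),
#'   `phenotype_label` (verbatim, markers included), `phenotype_mim` (integer
#'   or `NA`), `mapping_key` (integer 1-4), `marker` (one of `"none"`,
#'   `"question"`, `"brackets"`, `"braces"`), `gene_symbols` (list of
#'   character vectors), `gene_mim` (integer), `cyto_location` (character).
#'   The number of non-comment source lines is attached as attribute
#'   `n_data_lines`, so callers can verify no line was silently dropped.
#' @details Malformed lines (missing or non-integer mapping key, unbalanced
#'   marker brackets, fewer than three columns, non-numeric gene MIM) raise
#'   an error naming the offending line.
#' @export
read_morbid_map <- function(path) {
  stopifnot(file.exists(path))
  raw <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  line_no <- seq_along(raw)[keep]

  n <- length(lines)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("morbid map line %d: expected at least 3 tab-separated columns", line_no[k]))
    }
    pheno <- trimws(fields[[1]])

    key_m <- regmatches(pheno, regexec("\\(([^()]*)\\)\\s*$", pheno))[[1]]
    if (length(key_m) == 0) {
      stop(sprintf("morbid map line %d: missing mapping key", line_no[k]))
    }
    key_chr <- key_m[[2]]
    if (!grepl("^[0-9]+$", key_chr)) {
      stop(sprintf("morbid map line %d: non-integer mapping key '(%s)'", line_no[k], key_chr))
    }
    key <- as.integer(key_chr)
    if (!key %in% 1:4) {
      stop(sprintf("morbid map line %d: mapping key %d outside 1-4", line_no[k], key))
    }
    rest <- trimws(sub("\\(([^()]*)\\)\\s*$", "", pheno))

    mim_m <- regmatches(rest, regexec(",\\s*([0-9]{6})\\s*$", rest))[[1]]
    if (length(mim_m) > 0) {
      phenotype_mim <- as.integer(mim_m[[2]])
      label <- trimws(sub(",\\s*[0-9]{6}\\s*$", "", rest))
    } else {
      phenotype_mim <- NA_integer_
      label <- rest
    }

    marker <- "none"
    first <- substr(label, 1L, 1L)
    if (first == "?") {
      marker <- "question"
    } else if (first == "[") {
      if (!endsWith(label, "]")) {
        stop(sprintf("morbid map line %d: unbalanced '[' in phenotype label", line_no[k]))
      }
      marker <- "brackets"
    } else if (first == "{") {
      if (!endsWith(label, "}")) {
        stop(sprintf("morbid map line %d: unbalanced '{' in phenotype label", line_no[k]))
      }
      marker <- "braces"
    }

    gene_mim_chr <- trimws(fields[[3]])
    if (!grepl("^[0-9]{6}$", gene_mim_chr)) {
      stop(sprintf("morbid map line %d: gene MIM '%s' is not a 6-digit identifier",
                   line_no[k], gene_mim_chr))
    }

    out[[k]] <- list(
      line = line_no[k],
      phenotype_label = label,
      phenotype_mim = phenotype_mim,
      mapping_key = key,
      marker = marker,
      gene_symbols = list(trimws(strsplit(fields[[2]], ",", fixed = TRUE)[[1]])),
      gene_mim = as.integer(gene_mim_chr),
      cyto_location = if (length(fields) >= 4) trimws(fields[[4]]) else NA_character_
    )
  }

  res <- tibble::tibble(
    line = vapply(out, `[[`, integer(1), "line"),
    phenotype_label = vapply(out, `[[`, character(1), "phenotype_label"),
    phenotype_mim = vapply(out, `[[`, integer(1), "phenotype_mim"),
    mapping_key = vapply(out, `[[`, integer(1), "mapping_key"),
    marker = vapply(out, `[[`, character(1), "marker"),
    gene_symbols = lapply(out, function(x) x$gene_symbols[[1]]),
    gene_mim = vapply(out, `[[`, integer(1), "gene_mim"),
    cyto_location = vapply(out, `[[`, character(1), "cyto_location")
  )
  attr(res, "n_data_lines") <- n
  res
}

#' Write morbid-map rows back to the TSV dialect
#'
#' Inverse of [read_morbid_map()]; used by the synthetic-universe generator
#' and the round-trip tests.
#'
#' @param rows Tibble as returned by [read_morbid_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_morbid_map <- function(rows, path) {
  pheno <- ifelse(
    is.na(rows$phenotype_mim),
    sprintf("%s (%d)", rows$phenotype_label, rows$mapping_key),
    sprintf("%s, %06d (%d)", rows$phenotype_label, rows$phenotype_mim, rows$mapping_key)
  )
  lines <- paste(
    pheno,
    vapply(rows$gene_symbols, paste, character(1), collapse = ", "),
    sprintf("%06d", rows$gene_mim),
    ifelse(is.na(rows$cyto_location), "", rows$cyto_location),
    sep = "\t"
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an OBO-format ontology
#'
#' Parses `[Term]` stanzas of an OBO file, capturing both `is_a` and
#' `relationship: part_of` parent edges, obsolete flags and (when present)
#' the namespace. Dangling parent references are kept but flagged
#' unresolved, with a warning.
#'
#' @param path Path to an OBO file.
#' @return An object of class `lh_ontology`: a list with
#'   \describe{
#'     \item{terms}{tibble `term_id`, `name`, `namespace`, `obsolete`}
#'     \item{edges}{tibble `term_id` (child), `parent_id`, `relation`
#'       (`"is_a"` or `"part_of"`), `resolved` (parent defined in the file)}
#'   }
#' @export
read_obo <- function(path) {
  stopifnot(file.exists(path))
  raw <- readLines(path, encoding = "UTF-8")

  terms <- list()
  edges <- list()
  cur <- NULL
  in_term <- FALSE

  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id)) return(NULL)
    cur
  }

  for (ln in raw) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      if (in_term && !is.null(cur$id)) terms[[length(terms) + 1L]] <- cur
      cur <- list(id = NULL, name = NA_character_, namespace = NA_character_,
                  obsolete = FALSE, parents = list())
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {          # any other stanza type ends the term
      if (in_term && !is.null(cur$id)) terms[[length(terms) + 1L]] <- cur
      in_term <- FALSE
      cur <- NULL
      next
    }
    if (!in_term || !nzchar(ln)) next

    if (grepl("^id:", ln)) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (grepl("^name:", ln)) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (grepl("^namespace:", ln)) {
      cur$namespace <- trimws(sub("^namespace:", "", ln))
    } else if (grepl("^is_obsolete:\\s*true", ln)) {
      cur$obsolete <- TRUE
    } else if (grepl("^is_a:", ln)) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents[[length(cur$parents) + 1L]] <- c("is_a", tgt)
    } else if (grepl("^relationship:\\s*part_of\\s", ln)) {
      tgt <- trimws(sub("!.*$", "", sub("^relationship:\\s*part_of", "", ln)))
      cur$parents[[length(cur$parents) + 1L]] <- c("part_of", tgt)
    }
  }
  if (in_term && !is.null(cur$id)) terms[[length(terms) + 1L]] <- cur

  term_tbl <- tibble::tibble(
    term_id = vapply(terms, `[[`, character(1), "id"),
    name = vapply(terms, `[[`, character(1), "name"),
    namespace = vapply(terms, `[[`, character(1), "namespace"),
    obsolete = vapply(terms, `[[`, logical(1), "obsolete")
  )
  if (anyDuplicated(term_tbl$term_id)) {
    stop("OBO file defines duplicate term ids: ",
         paste(unique(term_tbl$term_id[duplicated(term_tbl$term_id)]), collapse = ", "))
  }

  ch <- unlist(lapply(terms, function(t) rep(t$id, length(t$parents))))
  if (is.null(ch)) ch <- character(0)
  rel <- unlist(lapply(terms, function(t) vapply(t$parents, `[[`, character(1), 1L)))
  par <- unlist(lapply(terms, function(t) vapply(t$parents, `[[`, character(1), 2L)))
  if (is.null(rel)) { rel <- character(0); par <- character(0) }

  if (any(ch == par)) {
    stop("OBO file contains self-loop parent edges: ",
         paste(unique(ch[ch == par]), collapse = ", "))
  }
  edge_tbl <- tibble::tibble(
    term_id = ch, parent_id = par, relation = rel,
    resolved = par %in% term_tbl$term_id
  )
  if (any(!edge_tbl$resolved)) {
    warning("ontology has ", sum(!edge_tbl$resolved),
            " parent reference(s) not defined in the file; edges kept, flagged unresolved")
  }
  structure(list(terms = term_tbl, edges = edge_tbl), class = "lh_ontology")
}

#' @export
print.lh_ontology <- function(x, ...) {
  cat("<lh_ontology> ", nrow(x$terms), " terms, ", nrow(x$edges), " parent edges (",
      sum(x$terms$obsolete), " obsolete terms)\n", sep = "")
  invisible(x)
}

# -- generic TSV machinery -----------------------------------------------

read_checked_tsv <- function(path, expected, label) {
  stopifnot(file.exists(path))
  tbl <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  extra <- setdiff(names(tbl), expected)
  if (length(extra) > 0) {
    stop(sprintf("%s (%s): unknown column '%s'", label, path, extra[[1]]))
  }
  missing <- setdiff(expected, names(tbl))
  if (length(missing) > 0) {
    stop(sprintf("%s (%s): missing column '%s'", label, path, missing[[1]]))
  }
  tbl[expected]
}

split_semicolon <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
  })
}

#' Read the gene catalog (mim2gene-style table)
#'
#' Columns: `gene_mim`, `entrez_id` (may be empty), `status`
#' (active/moved/removed), `protein_coding` (TRUE/FALSE). Rows with
#' `moved`/`removed` status or no Entrez id are retained here and excluded
#' downstream by [filter_disease_gene_pairs()].
#'
#' @param path Path to a TSV with the documented header.
#' @return Tibble with typed columns.
#' @export
read_gene_catalog <- function(path) {
  tbl <- read_checked_tsv(path, c("gene_mim", "entrez_id", "status", "protein_coding"),
                          "gene catalog")
  out <- tibble::tibble(
    gene_mim = as.integer(tbl$gene_mim),
    entrez_id = suppressWarnings(as.integer(tbl$entrez_id)),
    status = tbl$status,
    protein_coding = toupper(tbl$protein_coding) %in% c("TRUE", "1", "YES")
  )
  bad <- !out$status %in% c("active", "moved", "removed")
  if (any(bad)) stop("gene catalog: unknown status value(s): ",
                     paste(unique(out$status[bad]), collapse = ", "))
  if (any(!is.na(out$entrez_id) & out$status != "active")) {
    warning("gene catalog: Entrez id present on non-active record(s)")
  }
  out
}

#' Read the phenotypic-series membership table
#'
#' Columns: `ps_id` (e.g. `"PS191100"`), `phenotype_mim`. A disease may
#' belong to more than one series.
#'
#' @param path Path to a TSV with the documented header.
#' @return Tibble `ps_id`, `phenotype_mim`.
#' @export
read_ps_membership <- function(path) {
  tbl <- read_checked_tsv(path, c("ps_id", "phenotype_mim"), "PS membership")
  tibble::tibble(ps_id = tbl$ps_id, phenotype_mim = as.integer(tbl$phenotype_mim))
}

#' Read gene-to-ontology-term annotations
#'
#' Columns: `entrez_id`, `term_id`. These are direct annotations; no
#' propagation along the hierarchy is performed anywhere in the package.
#'
#' @param path Path to a TSV with the documented header.
#' @return Tibble `entrez_id`, `term_id`.
#' @export
read_annotations <- function(path) {
  tbl <- read_checked_tsv(path, c("entrez_id", "term_id"), "annotations")
  if (any(is.na(tbl$entrez_id) | !nzchar(tbl$entrez_id)) ||
      any(is.na(tbl$term_id) | !nzchar(tbl$term_id))) {
    stop("annotations: empty identifier")
  }
  unique(tibble::tibble(entrez_id = as.integer(tbl$entrez_id), term_id = tbl$term_id))
}

#' Read the mouse ortholog / phenotype report
#'
#' Columns: `human_entrez_id`, `mouse_gene_id`, `mp_terms`
#' (semicolon-joined Mammalian Phenotype ids, possibly empty) and
#' `lethality_stage` (one of embryonic/fetal/prenatal/none).
#'
#' @param path Path to a TSV with the documented header.
#' @return Tibble with `mp_terms` as a list column.
#' @export
read_ortholog_phenotypes <- function(path) {
  tbl <- read_checked_tsv(path, c("human_entrez_id", "mouse_gene_id", "mp_terms",
                                  "lethality_stage"), "ortholog phenotypes")
  stage <- ifelse(is.na(tbl$lethality_stage) | !nzchar(tbl$lethality_stage),
                  "none", tbl$lethality_stage)
  bad <- !stage %in% c("embryonic", "fetal", "prenatal", "none")
  if (any(bad)) stop("ortholog phenotypes: unknown lethality stage: ",
                     paste(unique(stage[bad]), collapse = ", "))
  out <- tibble::tibble(
    human_entrez_id = as.integer(tbl$human_entrez_id),
    mouse_gene_id = tbl$mouse_gene_id,
    mp_terms = split_semicolon(tbl$mp_terms),
    lethality_stage = stage
  )
  empty_mp <- lengths(out$mp_terms) == 0
  if (any(empty_mp & out$lethality_stage == "none")) {
    warning("ortholog phenotypes: record(s) with neither MP terms nor a lethality stage")
  }
  out
}

#' Read the MP-to-HP best-match table
#'
#' Columns: `mp_term`, `hp_term`. Duplicate pairs are deduplicated.
#'
#' @param path Path to a TSV with the documented header.
#' @return Tibble of unique `mp_term`, `hp_term` pairs.
#' @export
read_phenotype_matches <- function(path) {
  tbl <- read_checked_tsv(path, c("mp_term", "hp_term"), "phenotype matches")
  unique(tibble::tibble(mp_term = tbl$mp_term, hp_term = tbl$hp_term))
}

#' Read the disease-to-HP-phenotype table
#'
#' Columns: `phenotype_mim`, `hp_terms` (semicolon-joined, non-empty).
#'
#' @param path Path to a TSV with the documented header.
#' @return Tibble with `hp_terms` as a list column.
#' @export
read_disease_phenotypes <- function(path) {
  tbl <- read_checked_tsv(path, c("phenotype_mim", "hp_terms"), "disease phenotypes")
  out <- tibble::tibble(
    phenotype_mim = as.integer(tbl$phenotype_mim),
    hp_terms = split_semicolon(tbl$hp_terms)
  )
  if (any(lengths(out$hp_terms) == 0)) stop("disease phenotypes: empty hp_terms field")
  out
}

#' Read gain-of-function mutation flags
#'
#' Single column `entrez_id`: disease proteins whose causal mutations are
#' annotated as gain-of-function. This is curated input, not inferred.
#'
#' @param path Path to a TSV with the documented header.
#' @return Integer vector of Entrez ids.
#' @export
read_gof_flags <- function(path) {
  tbl <- read_checked_tsv(path, "entrez_id", "GoF flags")
  unique(as.integer(tbl$entrez_id))
}

#' Read every auxiliary table of an input bundle
#'
#' @param paths Named list/vector with elements `genes`, `ps`, `annotations`,
#'   `orthologs`, `matches`, `disease_hp` and optionally `gof`.
#' @return Named list of tibbles (see the individual readers).
#' @export
read_aux_tables <- function(paths) {
  need <- c("genes", "ps", "annotations", "orthologs", "matches", "disease_hp")
  stopifnot(all(need %in% names(paths)))
  out <- list(
    genes = read_gene_catalog(paths[["genes"]]),
    ps = read_ps_membership(paths[["ps"]]),
    annotations = read_annotations(paths[["annotations"]]),
    orthologs = read_ortholog_phenotypes(paths[["orthologs"]]),
    matches = read_phenotype_matches(paths[["matches"]]),
    disease_hp = read_disease_phenotypes(paths[["disease_hp"]])
  )
  if ("gof" %in% names(paths)) out$gof <- read_gof_flags(paths[["gof"]])
  out
}
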