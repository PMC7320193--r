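#' Jaccard coefficient of two protein sets
#'
#' `|A intersect B| / |A union B|`, ranging from 0 (disjoint) to 1
#' (identical). This is the overlap statistic of the whole analysis: a
#' 4-protein series fully contained in a 12-protein complex scores
#' `4 / 12 = 0.33`.
#'
#' @param a,b Vectors of protein identifiers; at least one non-empty.
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    stop("jaccard undefined for two empty sets")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Find group-complex intersections with at least two shared proteins
#'
#' Materializes the (group, protein, complex) 3-tuples implied by group
#' membership and complex membership and self-joins them: a record is
#' emitted for every (group, complex) pair in which two different proteins
#' are members of the complex and cause diseases of the group. Equivalent
#' to a direct double loop over all pairs of eligible groups and complexes,
#' keeping those sharing `min_shared` proteins or more.
#'
#' @param groups Tibble from [build_disease_groups()] or [build_ps_groups()];
#'   only `eligible` rows enter the analysis.
#' @param catalog `lh_complex_catalog` from [select_and_prune_complexes()].
#' @param min_shared Minimum shared-protein count for a record (default 2).
#' @return Tibble `group_id`, `term_id`, `shared` (list of protein ids),
#'   `n_shared`, `jc`, `group_size`, `pc_size`, ordered by group then
#'   complex id.
#' @export
find_intersections <- function(groups, catalog, min_shared = 2L) {
  stopifnot(inherits(catalog, "lh_complex_catalog"))
  g <- groups[groups$eligible, ]
  pcs <- catalog$complexes

  g_long <- tibble::tibble(
    group_id = rep(g$group_id, g$n_proteins),
    entrez_id = unlist(g$proteins, use.names = FALSE)
  )
  c_long <- tibble::tibble(
    term_id = rep(pcs$term_id, pcs$n_proteins),
    entrez_id = unlist(pcs$proteins, use.names = FALSE)
  )
  tuples <- merge(g_long, c_long, by = "entrez_id")
  if (nrow(tuples) == 0) {
    return(tibble::tibble(group_id = character(0), term_id = character(0),
                          shared = list(), n_shared = integer(0), jc = double(0),
                          group_size = integer(0), pc_size = integer(0)))
  }

  key <- paste(tuples$group_id, tuples$term_id, sep = "\r")
  shared <- lapply(split(tuples$entrez_id, key), function(p) sort(unique(p)))
  shared <- shared[lengths(shared) >= min_shared]
  if (length(shared) == 0) {
    return(tibble::tibble(group_id = character(0), term_id = character(0),
                          shared = list(), n_shared = integer(0), jc = double(0),
                          group_size = integer(0), pc_size = integer(0)))
  }
  parts <- strsplit(names(shared), "\r", fixed = TRUE)
  group_id <- vapply(parts, `[[`, character(1), 1L)
  term_id <- vapply(parts, `[[`, character(1), 2L)

  group_size <- g$n_proteins[match(group_id, g$group_id)]
  pc_size <- pcs$n_proteins[match(term_id, pcs$term_id)]
  n_shared <- lengths(shared)

  rec <- tibble::tibble(
    group_id = group_id, term_id = term_id,
    shared = unname(shared), n_shared = unname(n_shared),
    jc = unname(n_shared / (group_size + pc_size - n_shared)),
    group_size = unname(group_size), pc_size = unname(pc_size)
  )
  rec[order(rec$group_id, rec$term_id), ]
}

#' Histogram of Jaccard coefficients in width-0.1 bins
#'
#' Bins span `(0, 1]`, right-closed, with `jc = 1` falling in the top bin.
#'
#' @param jc Numeric vector of coefficients in `(0, 1]`.
#' @return Tibble `bin` (label like `"(0.2,0.3]"`), `count`.
#' @keywords internal
jc_histogram <- function(jc) {
  breaks <- seq(0, 1, by = 0.1)
  cut_idx <- cut(jc, breaks = breaks, include.lowest = FALSE, right = TRUE)
  tibble::tibble(bin = levels(cut_idx), count = as.integer(table(cut_idx)))
}

#' Summary statistics of an intersection table
#'
#' Reports how many groups hit at least one complex (and the percentage
#' over all eligible groups), how many complexes are hit (percentage over
#' the catalog), the mean/SD/median Jaccard coefficient over all records,
#' the per-group maximum JC (`jc_max`; the statistic the overlap histograms
#' are built from when one group intersects several complexes), and the
#' `jc_max` histogram. Ties for `jc_max` are broken toward the smallest
#' complex id so reports are deterministic; tied records all remain in the
#' record table.
#'
#' @param records Tibble from [find_intersections()].
#' @param groups,catalog The inputs the records were computed from.
#' @return An object of class `lh_summary`: list with `n_groups`, `n_pcs`,
#'   `n_groups_hit`, `pct_groups_hit`, `n_pcs_hit`, `pct_pcs_hit`,
#'   `mean_jc`, `sd_jc`, `median_jc`, `jc_max` (tibble of best record per
#'   group) and `jc_histogram`.
#' @export
summarize_intersections <- function(records, groups, catalog) {
  n_groups <- sum(groups$eligible)
  n_pcs <- nrow(catalog$complexes)

  if (nrow(records) == 0) {
    empty <- jc_histogram(numeric(0))
    return(structure(list(
      n_groups = n_groups, n_pcs = n_pcs,
      n_groups_hit = 0L, pct_groups_hit = 0,
      n_pcs_hit = 0L, pct_pcs_hit = 0,
      mean_jc = 0, sd_jc = 0, median_jc = 0,
      jc_max = records, jc_histogram = empty
    ), class = "lh_summary"))
  }

  ord <- order(records$group_id, -records$jc, records$term_id)
  best <- records[ord, ][!duplicated(records$group_id[ord]), ]

  structure(list(
    n_groups = n_groups, n_pcs = n_pcs,
    n_groups_hit = length(unique(records$group_id)),
    pct_groups_hit = 100 * length(unique(records$group_id)) / n_groups,
    n_pcs_hit = length(unique(records$term_id)),
    pct_pcs_hit = 100 * length(unique(records$term_id)) / n_pcs,
    mean_jc = mean(records$jc),
    sd_jc = if (nrow(records) > 1) stats::sd(records$jc) else 0,
    median_jc = stats::median(records$jc),
    jc_max = best,
    jc_histogram = jc_histogram(best$jc)
  ), class = "lh_summary")
}

#' @export
print.lh_summary <- function(x, ...) {
  cat(sprintf("<lh_summary> %d/%d groups hit a complex (%.1f%%); %d/%d complexes hit (%.1f%%)\n",
              x$n_groups_hit, x$n_groups, x$pct_groups_hit,
              x$n_pcs_hit, x$n_pcs, x$pct_pcs_hit))
  cat(sprintf("  JC %.2f +/- %.2f (median %.2f) over %d records\n",
              x$mean_jc, x$sd_jc, x$median_jc,
              if (is.data.frame(x$jc_max)) nrow(x$jc_max) else 0L))
  invisible(x)
}

#' Write an intersection table to TSV
#'
#' @param records Tibble from [find_intersections()].
#' @param path Output path; shared protein ids are semicolon-joined and
#'   JCs rounded to 3 decimals for display (records keep full precision).
#' @return `path`, invisibly.
#' @export
write_intersections <- function(records, path) {
  readr::write_tsv(tibble::tibble(
    group_id = records$group_id,
    term_id = records$term_id,
    n_shared = records$n_shared,
    shared = vapply(records$shared, paste, character(1), collapse = ";"),
    jc = round(records$jc, 3),
    group_size = records$group_size,
    pc_size = records$pc_size
  ), path, progress = FALSE)
  invisible(path)
}
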