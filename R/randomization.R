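#' Draw pseudo-groups of matched sizes from a protein pool
#'
#' Each pseudo-group is an independent uniform random subset of the pool
#' with the requested size (sampling without replacement within a group,
#' independently across groups; a protein may land in several
#' pseudo-groups). This is the minimal randomization preserving the real
#' group-size multiset: real series sizes sum to more than the number of
#' distinct disease proteins, so a partition of the pool is impossible.
#'
#' @param pool Vector of protein identifiers.
#' @param sizes Integer vector of group sizes; each must not exceed
#'   `length(pool)`.
#' @return A protein-group tibble compatible with [find_intersections()]
#'   (`group_id` = `pseudo_1`, ..., `role = "pseudo"`).
#' @export
make_pseudo_groups <- function(pool, sizes) {
  pool <- unique(pool)
  if (any(sizes > length(pool))) {
    stop("pseudo-group size exceeds pool size (", length(pool), ")")
  }
  if (any(sizes < 1)) stop("pseudo-group sizes must be >= 1")
  proteins <- lapply(sizes, function(s) sort(sample(pool, s, replace = FALSE)))
  grp <- new_protein_groups(paste0("pseudo_", seq_along(sizes)), "pseudo", proteins)
  grp$eligible <- grp$n_proteins >= 2L
  grp
}

#' Z-score of an observed count against simulated null counts
#'
#' `(observed - mean(null)) / sd(null)` with the sample (n-1) standard
#' deviation. A degenerate null (zero SD) yields `NA` with a warning, the
#' undefined-Z flag.
#'
#' @param observed Observed count.
#' @param null_counts Numeric vector of per-replicate null counts
#'   (length >= 2).
#' @return A single number, or `NA` if the null SD is zero.
#' @export
z_score <- function(observed, null_counts) {
  if (length(null_counts) < 2) stop("z_score needs at least 2 null replicates")
  s <- stats::sd(null_counts)
  if (s == 0) {
    warning("null counts are constant; Z undefined")
    return(NA_real_)
  }
  (observed - mean(null_counts)) / s
}

# number of sets in `side` sharing >= min_shared proteins with >= 1 set in `fixed`
count_sharing <- function(side, fixed, min_shared = 2L) {
  sum(vapply(side, function(s) {
    any(vapply(fixed, function(f) length(intersect(s, f)) >= min_shared, logical(1)))
  }, logical(1)))
}

# sparse protein-by-set indicator over a fixed protein universe
set_incidence <- function(sets, universe) {
  idx <- lapply(sets, function(s) match(s, universe))
  Matrix::sparseMatrix(
    i = unlist(idx, use.names = FALSE),
    j = rep(seq_along(sets), lengths(idx)),
    x = 1, dims = c(length(universe), length(sets))
  )
}

#' Run one randomization control for the group-complex intersection
#'
#' Implements the permutation controls that calibrate the observed number
#' of intersecting entities against chance:
#' \describe{
#'   \item{`pseudo_ps`}{redistribute the disease proteins among
#'     pseudo-groups of the real group sizes; count pseudo-groups sharing
#'     at least two proteins with some real complex.}
#'   \item{`pseudo_pc`}{redistribute the complex proteins among
#'     pseudo-complexes of the real complex sizes; count pseudo-complexes
#'     sharing at least two proteins with some real group.}
#'   \item{`non_lh`}{as `pseudo_ps`, but drawing from the pool of disease
#'     proteins NOT associated with locus heterogeneity (supply
#'     `nonlh_pool`).}
#' }
#' The observed count is always computed on the real, non-randomized data.
#'
#' @param kind One of `"pseudo_ps"`, `"pseudo_pc"`, `"non_lh"`.
#' @param groups Eligible protein groups (disease- or series-based).
#' @param catalog `lh_complex_catalog`.
#' @param reps Number of replicates (default 100000, the full-study
#'   setting; tests and desk runs use far fewer).
#' @param seed Integer seed for this control's random stream.
#' @param pool Protein pool for the randomized side; defaults to the union
#'   of proteins on that side.
#' @param nonlh_pool Pool of non-LH disease proteins, required for
#'   `kind = "non_lh"`.
#' @return An object of class `lh_null_result`: list with `kind`, `reps`,
#'   `seed`, `observed`, `null_counts`, `null_mean`, `null_sd`, `z`,
#'   `z_defined`.
#' @export
run_null_control <- function(kind = c("pseudo_ps", "pseudo_pc", "non_lh"),
                             groups, catalog, reps = 100000L, seed = 1L,
                             pool = NULL, nonlh_pool = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(catalog, "lh_complex_catalog"))
  if (reps < 1) stop("reps must be >= 1")
  g <- groups[groups$eligible, ]
  group_sets <- g$proteins
  pc_sets <- catalog$complexes$proteins

  if (kind == "pseudo_pc") {
    random_sizes <- lengths(pc_sets)
    fixed_sets <- group_sets
    if (is.null(pool)) pool <- sort(unique(unlist(pc_sets, use.names = FALSE)))
    observed <- count_sharing(pc_sets, fixed_sets)
  } else {
    random_sizes <- lengths(group_sets)
    fixed_sets <- pc_sets
    if (kind == "non_lh") {
      if (is.null(nonlh_pool)) stop("kind = 'non_lh' requires nonlh_pool")
      pool <- sort(unique(nonlh_pool))
    } else if (is.null(pool)) {
      pool <- sort(unique(unlist(group_sets, use.names = FALSE)))
    }
    observed <- count_sharing(group_sets, fixed_sets)
  }
  if (any(random_sizes > length(pool))) {
    stop("a randomized-side size exceeds the protein pool")
  }

  universe <- sort(unique(c(pool, unlist(fixed_sets, use.names = FALSE))))
  fixed_M <- set_incidence(fixed_sets, universe)
  pool_idx <- match(pool, universe)
  n_side <- length(random_sizes)
  j_rep <- rep(seq_len(n_side), random_sizes)

  set.seed(seed)
  null_counts <- integer(reps)
  for (r in seq_len(reps)) {
    i_idx <- unlist(lapply(random_sizes, function(s) {
      pool_idx[sample.int(length(pool_idx), s)]
    }), use.names = FALSE)
    G <- Matrix::sparseMatrix(i = j_rep, j = i_idx, x = 1,
                              dims = c(n_side, length(universe)))
    H <- G %*% fixed_M
    null_counts[r] <- length(unique(H@i[H@x >= 2]))
  }

  s <- stats::sd(null_counts)
  z <- if (s > 0) (observed - mean(null_counts)) / s else NA_real_
  structure(list(
    kind = kind, reps = reps, seed = seed,
    observed = observed, null_counts = null_counts,
    null_mean = mean(null_counts), null_sd = s,
    z = z, z_defined = s > 0
  ), class = "lh_null_result")
}

#' @export
print.lh_null_result <- function(x, ...) {
  cat(sprintf("<lh_null_result:%s> observed %d vs null %.2f +/- %.2f over %d reps (Z = %s)\n",
              x$kind, x$observed, x$null_mean, x$null_sd, x$reps,
              if (x$z_defined) sprintf("%.1f", x$z) else "undefined"))
  if (!is.null(x$ratio)) cat(sprintf("  observed/null ratio = %.1f\n", x$ratio))
  invisible(x)
}

# same-series-different-disease indicator machinery: a protein pair
# satisfies the condition iff they share a series through two DIFFERENT
# diseases. That fails for a shared series only when both proteins
# annotate exactly one disease there and it is the same one.
same_ps_diff_disease_matrix <- function(pairs, ps, pool) {
  memb <- merge(pairs[c("phenotype_mim", "entrez_id")], ps, by = "phenotype_mim")
  memb <- memb[memb$entrez_id %in% pool, ]
  memb <- unique(memb)
  if (nrow(memb) == 0) {
    n <- length(pool)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = double(0),
                                dims = c(n, n)))
  }
  pidx <- match(memb$entrez_id, pool)

  ps_ids <- sort(unique(memb$ps_id))
  S <- Matrix::sparseMatrix(i = pidx, j = match(memb$ps_id, ps_ids), x = 1,
                            dims = c(length(pool), length(ps_ids)))
  S@x[] <- 1  # collapse duplicate (protein, series) entries
  T_common <- Matrix::tcrossprod(S)

  # proteins with exactly one disease in a series, keyed by (series, disease)
  cnt <- stats::aggregate(list(n = memb$phenotype_mim),
                          by = list(pidx = pidx, ps_id = memb$ps_id),
                          FUN = function(d) length(unique(d)))
  single <- cnt[cnt$n == 1, ]
  single_rows <- merge(data.frame(pidx = pidx, ps_id = memb$ps_id,
                                  phenotype_mim = memb$phenotype_mim),
                       single[c("pidx", "ps_id")], by = c("pidx", "ps_id"))
  if (nrow(single_rows) > 0) {
    keys <- sort(unique(paste(single_rows$ps_id, single_rows$phenotype_mim)))
    S1 <- Matrix::sparseMatrix(
      i = single_rows$pidx,
      j = match(paste(single_rows$ps_id, single_rows$phenotype_mim), keys),
      x = 1, dims = c(length(pool), length(keys))
    )
    S1@x[] <- 1
    U_fail <- Matrix::tcrossprod(S1)
  } else {
    U_fail <- T_common * 0
  }
  D <- T_common - U_fail
  D
}

#' Pairwise control: same-complex versus random disease-protein pairs
#'
#' The observed statistic is the number of unordered disease-protein pairs
#' that (a) co-occur in at least one complex of the catalog and (b) cause
#' two different diseases belonging to the same phenotypic series. The
#' null draws, per replicate, the same number of uniform random
#' distinct-protein pairs from the disease-protein pool and counts those
#' satisfying (b). The result carries the observed count, null moments,
#' Z-score and the enrichment ratio `observed / null_mean` — the "how many
#' times more likely is same-series causation within a complex" figure.
#'
#' @param pairs Validated disease-gene pairs (tibble with `phenotype_mim`,
#'   `entrez_id`).
#' @param ps Series membership tibble (`ps_id`, `phenotype_mim`).
#' @param catalog `lh_complex_catalog`.
#' @param reps Number of null replicates.
#' @param seed Integer seed.
#' @return `lh_null_result` with an extra `ratio` element.
#' @export
pairwise_control <- function(pairs, ps, catalog, reps = 100000L, seed = 1L) {
  stopifnot(inherits(catalog, "lh_complex_catalog"))
  pool <- sort(unique(pairs$entrez_id))
  if (length(pool) < 2) stop("pairwise control needs at least 2 disease proteins")

  D <- same_ps_diff_disease_matrix(pairs, ps, pool)

  pc_sets <- lapply(catalog$complexes$proteins, function(p) intersect(p, pool))
  pc_sets <- pc_sets[lengths(pc_sets) >= 2]
  M <- set_incidence(pc_sets, pool)
  CP <- Matrix::tcrossprod(M)
  CP_t <- methods::as(methods::as(CP, "generalMatrix"), "TsparseMatrix")
  sel <- CP_t@i < CP_t@j & CP_t@x > 0
  pi_idx <- CP_t@i[sel] + 1L
  pj_idx <- CP_t@j[sel] + 1L
  n_pairs <- length(pi_idx)

  observed <- if (n_pairs > 0) sum(D[cbind(pi_idx, pj_idx)] > 0) else 0L

  set.seed(seed)
  null_counts <- integer(reps)
  n <- length(pool)
  for (r in seq_len(reps)) {
    if (n_pairs == 0) break
    a <- sample.int(n, n_pairs, replace = TRUE)
    b <- sample.int(n - 1L, n_pairs, replace = TRUE)
    b <- ifelse(b >= a, b + 1L, b)  # distinct proteins within a pair
    null_counts[r] <- sum(D[cbind(a, b)] > 0)
  }

  s <- stats::sd(null_counts)
  nm <- mean(null_counts)
  structure(list(
    kind = "pairwise", reps = reps, seed = seed,
    observed = as.integer(observed), null_counts = null_counts,
    null_mean = nm, null_sd = s,
    z = if (s > 0) (observed - nm) / s else NA_real_,
    z_defined = s > 0,
    ratio = if (nm > 0) observed / nm else NA_real_,
    n_same_pc_pairs = n_pairs
  ), class = "lh_null_result")
}

#' Write a null-model result to JSON
#'
#' @param result `lh_null_result`.
#' @param path Output path; per-replicate counts are omitted, moments kept.
#' @return `path`, invisibly.
#' @export
write_null_result <- function(result, path) {
  out <- result[setdiff(names(result), "null_counts")]
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
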