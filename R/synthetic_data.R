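#' Default planted overlap specifications
#'
#' Four series-complex overlap geometries exercised throughout the test
#' suite, chosen to replicate the canonical worked examples of the
#' analysis: a 4-protein series fully inside a 12-protein complex with two
#' promotable members (JC 0.33 rising to 0.60); a 12-protein series
#' sharing the same 5 proteins with a 14- and an 88-protein complex
#' (JC 0.238 vs 0.053 — the complex-size effect); a 3-protein series fully
#' inside an 88-protein complex (JC 0.034); and a 3-protein series
#' identical to its complex (JC 1, full intersection).
#'
#' @return List of specs; each has `group_size` and `overlaps`, a list of
#'   `c(pc_size, i, m)` triples (complex size, shared proteins, presumptive
#'   proteins). Overlaps of one spec share their first `i` proteins.
#' @export
default_planted_overlaps <- function() {
  list(
    list(group_size = 4L, overlaps = list(c(12L, 4L, 2L))),
    list(group_size = 12L, overlaps = list(c(14L, 5L, 0L), c(88L, 5L, 0L))),
    list(group_size = 3L, overlaps = list(c(88L, 3L, 0L))),
    list(group_size = 3L, overlaps = list(c(3L, 3L, 0L)))
  )
}

#' Configuration of a synthetic input universe
#'
#' Bundles every knob of [generate_universe()]. Size samplers are discrete
#' log-normals clipped to a range, mimicking the long-tailed size
#' distributions of real phenotypic series (about 6.6 +/- 8.1 proteins)
#' and Gene Ontology complexes (2 to 116 members).
#'
#' @param seed Integer seed; the whole bundle is a deterministic function
#'   of the configuration.
#' @param n_genes Size of the background coding-gene pool.
#' @param n_background_ps,n_background_pc Numbers of background
#'   (non-planted) series and complexes.
#' @param ps_size,pc_size Lists `meanlog`, `sdlog`, `min`, `max` for the
#'   two size samplers.
#' @param planted_overlaps List of planted overlap specs
#'   ([default_planted_overlaps()]); `NULL` or `list()` plants none.
#' @param plant_redundancy Plant the redundancy cases (parent-child
#'   complex pair, common-parent trio, majority-shared pair, disjoint
#'   kept trio, allele-heterogeneity and disjoint series pairs on one
#'   complex).
#' @param plant_decoys Plant one morbid-map row per discard rule and the
#'   pruning decoys (parent-of-parent chains, generic terms, singleton,
#'   obsolete term).
#' @param plant_gof_ps Plant a series whose proteins are all
#'   gain-of-function flagged and belong to no complex.
#' @param n_multi_gene_diseases Diseases annotated by 2-4 genes each
#'   (disease-based locus heterogeneity instances).
#' @param n_background_diseases Single-gene diseases belonging to no
#'   series; their proteins form the non-LH pool of the `non_lh` control.
#' @param background_in_pc_frac Fraction of background series drawn as a
#'   subset of a random background complex; 0 (default) makes background
#'   series independent of the complexes (the no-association null world),
#'   values near 1 plant a strong global association.
#' @param frac_gof Fraction of background disease proteins flagged
#'   gain-of-function.
#' @param frac_lethal Fraction of complex-member genes whose mouse
#'   ortholog carries a pre-birth lethality stage.
#' @param frac_noncoding Fraction of EXTRA catalog genes (not used by any
#'   generated structure) flagged non-protein-coding.
#' @return An object of class `lh_world_config`.
#' @export
world_config <- function(seed = 1L,
                         n_genes = 1200L,
                         n_background_ps = 40L,
                         n_background_pc = 60L,
                         ps_size = list(meanlog = log(4.5), sdlog = 0.85,
                                        min = 2L, max = 40L),
                         pc_size = list(meanlog = log(8), sdlog = 0.9,
                                        min = 2L, max = 116L),
                         planted_overlaps = default_planted_overlaps(),
                         plant_redundancy = TRUE,
                         plant_decoys = TRUE,
                         plant_gof_ps = TRUE,
                         n_multi_gene_diseases = 6L,
                         n_background_diseases = 150L,
                         background_in_pc_frac = 0,
                         frac_gof = 0.05,
                         frac_lethal = 0.08,
                         frac_noncoding = 0.05) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_background_ps = as.integer(n_background_ps),
              n_background_pc = as.integer(n_background_pc),
              ps_size = ps_size, pc_size = pc_size,
              planted_overlaps = planted_overlaps,
              plant_redundancy = isTRUE(plant_redundancy),
              plant_decoys = isTRUE(plant_decoys),
              plant_gof_ps = isTRUE(plant_gof_ps),
              n_multi_gene_diseases = as.integer(n_multi_gene_diseases),
              n_background_diseases = as.integer(n_background_diseases),
              background_in_pc_frac = background_in_pc_frac,
              frac_gof = frac_gof, frac_lethal = frac_lethal,
              frac_noncoding = frac_noncoding)
  class(cfg) <- "lh_world_config"
  validate_world_config(cfg)
  cfg
}

validate_world_config <- function(cfg) {
  for (nm in c("background_in_pc_frac", "frac_gof", "frac_lethal", "frac_noncoding")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(nm, " must be in [0, 1]")
  }
  for (spec in cfg$planted_overlaps) {
    gs <- spec$group_size
    if (gs < 2) stop("planted group_size must be >= 2")
    for (ov in spec$overlaps) {
      pc <- ov[[1]]; i <- ov[[2]]; m <- ov[[3]]
      if (i > gs) stop("planted intersection exceeds group size")
      if (i + m > pc) stop("planted intersection plus presumptive proteins exceeds complex size")
      if (i < 0 || m < 0 || pc < 2) stop("invalid planted overlap sizes")
      if (pc > cfg$pc_size$max) stop("planted complex size exceeds pc_size$max")
    }
  }
  invisible(cfg)
}

sample_clipped_sizes <- function(n, spec) {
  s <- round(stats::rlnorm(n, meanlog = spec$meanlog, sdlog = spec$sdlog))
  as.integer(pmin(pmax(s, spec$min), spec$max))
}

#' Generate a synthetic input universe with planted ground truth
#'
#' Writes a complete, internally consistent bundle of input files in the
#' dialects consumed by the catalog readers — morbid map, gene catalog,
#' series membership, OBO ontology (with "complex"-named terms, parent
#' chains, the three generic umbrella terms, a singleton and an obsolete
#' term), gene-complex annotations, ortholog phenotypes, MP-to-HP best
#' matches, disease phenotypes and gain-of-function flags — together with
#' a truth manifest stating exactly what the pipeline must recover:
#' planted overlap coefficients, presumptive sets and augmented
#' coefficients, complex removal reasons, morbid-row discard reasons, and
#' kept/discarded relation pairs.
#'
#' Identifiers are synthetic but format-valid (6-digit MIMs,
#' `PS` + 6 digits, `GO:`/`HP:`/`MP:` + 7 digits), so no parser can
#' special-case test data. Same configuration, same seed: byte-identical
#' bundle.
#'
#' @param cfg `lh_world_config` from [world_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with `dir`, `paths` (named file paths,
#'   suitable for [read_aux_tables()]) and `truth` (class `lh_truth`).
#'   `truth.json` is also written alongside the bundle.
#' @export
generate_universe <- function(cfg = world_config(), dir) {
  validate_world_config(cfg)
  stopifnot(is.character(dir), length(dir) == 1)
  set.seed(cfg$seed)

  # -- gene registry -------------------------------------------------------
  reg <- new.env(parent = emptyenv())
  reg$n <- 0L
  reg$rows <- list()
  new_genes <- function(n, status = "active", coding = TRUE) {
    if (n == 0L) return(integer(0))
    ids <- reg$n + seq_len(n)
    reg$n <- reg$n + as.integer(n)
    no_entrez <- status %in% c("unmapped", "moved", "removed")
    reg$rows[[length(reg$rows) + 1L]] <- tibble::tibble(
      gene_mim = 600000L + ids,
      entrez_id = ifelse(rep(no_entrez, n), NA_integer_, 1000L + ids),
      status = if (status == "unmapped") "active" else status,
      protein_coding = coding,
      symbol = sprintf("GN%04d", ids)
    )
    1000L + ids
  }
  entrez_to_mim <- function(entrez) 600000L + (entrez - 1000L)
  entrez_to_symbol <- function(entrez) sprintf("GN%04d", entrez - 1000L)

  pool <- new_genes(cfg$n_genes)

  morbid <- list()
  add_disease <- function(mim, genes, label = sprintf("Synthetic disorder %d", mim),
                          key = 3L) {
    for (g in genes) {
      morbid[[length(morbid) + 1L]] <<- list(label = label, mim = mim, key = key,
                                             gene = if (is.na(g)) NA else g)
    }
  }
  ps_rows <- list()
  add_ps <- function(ps_id, mims) {
    ps_rows[[length(ps_rows) + 1L]] <<- tibble::tibble(ps_id = ps_id,
                                                       phenotype_mim = mims)
  }

  terms <- list()
  add_term <- function(id, name, parents = character(0), relation = "is_a",
                       obsolete = FALSE, namespace = "cellular_component") {
    terms[[length(terms) + 1L]] <<- list(id = id, name = name, parents = parents,
                                         relation = relation, obsolete = obsolete,
                                         namespace = namespace)
  }
  annot <- list()
  add_annotations <- function(term_id, genes) {
    if (length(genes) == 0) return(invisible())
    annot[[length(annot) + 1L]] <<- tibble::tibble(entrez_id = genes,
                                                   term_id = term_id)
  }

  ortho <- list()
  add_ortholog <- function(genes, mp = character(0), stage = "none") {
    if (length(genes) == 0) return(invisible())
    ortho[[length(ortho) + 1L]] <<- tibble::tibble(
      human_entrez_id = genes,
      mouse_gene_id = paste0(tolower(entrez_to_symbol(genes)), "-m"),
      mp_terms = ifelse(length(mp) > 0, paste(mp, collapse = ";"), ""),
      lethality_stage = stage
    )
  }
  matches <- list()
  add_match <- function(mp, hp) {
    matches[[length(matches) + 1L]] <<- tibble::tibble(mp_term = mp, hp_term = hp)
  }
  dis_hp <- list()
  add_disease_hp <- function(mims, hp) {
    dis_hp[[length(dis_hp) + 1L]] <<- tibble::tibble(phenotype_mim = mims,
                                                     hp_terms = hp)
  }

  gof <- integer(0)

  truth_planted <- list()
  truth_removals <- list()
  truth_discards <- list()
  truth_otm <- list()
  truth_mto <- list()

  # -- generic umbrella terms and pruning decoys ---------------------------
  add_term("GO:0032991", "macromolecular complex")
  add_term("GO:0043234", "protein complex", "GO:0032991")
  add_term("GO:0005667", "transcription factor complex", "GO:0032991")
  add_annotations("GO:0005667", new_genes(3L))
  truth_removals[["GO:0032991"]] <- "generic"
  truth_removals[["GO:0043234"]] <- "generic"
  truth_removals[["GO:0005667"]] <- "generic"

  if (cfg$plant_decoys) {
    # chain A1 <- B1 <- C1, every level protein-bearing: A1 is a removable
    # parent of parent
    add_term("GO:0900001", "alpha assembly complex", "GO:0032991")
    add_term("GO:0900002", "beta assembly complex", "GO:0900001")
    add_term("GO:0900003", "gamma assembly complex", "GO:0900002", relation = "part_of")
    add_annotations("GO:0900001", new_genes(2L))
    add_annotations("GO:0900002", new_genes(3L))
    add_annotations("GO:0900003", new_genes(3L))
    truth_removals[["GO:0900001"]] <- "parent_of_parent"

    # chain A2 <- B2 <- C2 with B2 devoid of proteins: A2 stays (removing it
    # would lose its annotations), B2 falls to the singleton rule
    add_term("GO:0900004", "delta assembly complex", "GO:0032991")
    add_term("GO:0900005", "epsilon assembly complex", "GO:0900004")
    add_term("GO:0900006", "zeta assembly complex", "GO:0900005")
    add_annotations("GO:0900004", new_genes(3L))
    add_annotations("GO:0900006", new_genes(2L))
    truth_removals[["GO:0900005"]] <- "singleton"

    add_term("GO:0900007", "solo subunit complex", "GO:0043234")
    add_annotations("GO:0900007", new_genes(1L))
    truth_removals[["GO:0900007"]] <- "singleton"

    add_term("GO:0900008", "obsolete omega complex", obsolete = TRUE)
    add_term("GO:0900009", "nuclear envelope", "GO:0032991")
    add_annotations("GO:0900009", new_genes(2L))
  }

  # -- planted overlaps ----------------------------------------------------
  mk_ps_hp <- function(idx, mims) {
    hp <- sprintf("HP:%07d", 1000000L + idx)
    mp <- sprintf("MP:%07d", 1000000L + idx)
    add_match(mp, hp)
    add_disease_hp(mims, hp)
    list(hp = hp, mp = mp)
  }
  neg_counter <- 0L
  add_nonmatching_orthologs <- function(genes) {
    # negative controls: orthologs whose phenotype maps to an HP term no
    # disease carries
    if (length(genes) == 0) return(invisible())
    neg_counter <<- neg_counter + 1L
    mp <- sprintf("MP:%07d", 2000000L + neg_counter)
    add_match(mp, sprintf("HP:%07d", 2000000L + neg_counter))
    add_ortholog(genes, mp)
  }

  specs <- cfg$planted_overlaps
  pc_counter <- 0L
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    gs <- spec$group_size
    ps_id <- sprintf("PS%06d", 310000L + k)
    dis_mims <- 310000L + 100L * k + seq_len(gs)
    genes <- sort(new_genes(gs))
    for (j in seq_len(gs)) add_disease(dis_mims[j], genes[j])
    add_ps(ps_id, dis_mims)
    ph <- mk_ps_hp(k, dis_mims)

    for (ov in spec$overlaps) {
      pc_sz <- ov[[1]]; i <- ov[[2]]; m <- ov[[3]]
      pc_counter <- pc_counter + 1L
      term_id <- sprintf("GO:%07d", 800000L + pc_counter)
      shared <- genes[seq_len(i)]          # overlaps of one spec share these
      presumptive <- sort(new_genes(m))
      fillers <- sort(new_genes(pc_sz - i - m))
      add_term(term_id, sprintf("planted machine %d complex", pc_counter),
               "GO:0043234")
      add_annotations(term_id, sort(c(shared, presumptive, fillers)))
      if (m > 0) add_ortholog(presumptive, ph$mp)
      if (length(fillers) > 0) {
        add_nonmatching_orthologs(fillers[seq_len(ceiling(length(fillers) / 2))])
      }
      truth_planted[[length(truth_planted) + 1L]] <- tibble::tibble(
        ps_id = ps_id, term_id = term_id,
        group_size = gs, pc_size = pc_sz,
        shared = list(shared), n_shared = i,
        presumptive = list(presumptive), n_presumptive = m,
        jc = i / (gs + pc_sz - i),
        jc_augmented = (i + m) / (gs + pc_sz - (i + m))
      )
    }
    if (length(spec$overlaps) >= 2) {
      ids <- sprintf("GO:%07d",
                     800000L + pc_counter - rev(seq_along(spec$overlaps)) + 1L)
      cmb <- utils::combn(sort(ids), 2)
      for (cc in seq_len(ncol(cmb))) {
        # distinct planted machines sharing only the series proteins: kept
        truth_otm[[length(truth_otm) + 1L]] <- tibble::tibble(
          group_id = ps_id, term_i = cmb[1, cc], term_j = cmb[2, cc],
          status = "kept", reason = NA_character_)
      }
    }
  }

  # -- redundancy plants ---------------------------------------------------
  if (cfg$plant_redundancy) {
    red_idx <- length(specs)

    # parent-child pair (meiotic-ring / ring style)
    core <- sort(new_genes(2L))
    r1 <- "GO:0910001"; r2 <- "GO:0910002"
    add_term(r2, "ring maintenance complex", "GO:0032991")
    add_term(r1, "meiotic ring maintenance complex", r2)
    add_annotations(r1, sort(c(core, new_genes(2L))))
    add_annotations(r2, sort(c(core, new_genes(4L))))
    mims <- 320000L + 1:2
    add_disease(mims[1], core[1]); add_disease(mims[2], core[2])
    add_ps("PS320001", mims)
    mk_ps_hp(red_idx + 1L, mims)
    truth_otm[[length(truth_otm) + 1L]] <- tibble::tibble(
      group_id = "PS320001", term_i = r1, term_j = r2,
      status = "discarded", reason = "parent_child")

    # common-parent trio under a protein-free parent (pruned as singleton,
    # but still a hierarchy witness)
    r0 <- "GO:0910010"
    add_term(r0, "granule assembly complex", "GO:0032991")
    truth_removals[[r0]] <- "singleton"
    trio <- c("GO:0910011", "GO:0910012", "GO:0910013")
    trio_genes <- list()
    for (t in seq_along(trio)) {
      add_term(trio[t], sprintf("granule subunit %d complex", t), r0)
      g2 <- sort(new_genes(2L))
      trio_genes[[t]] <- g2
      add_annotations(trio[t], sort(c(g2, new_genes(2L))))
    }
    mims <- 320100L + seq_len(6L)
    gg <- unlist(trio_genes)
    for (j in seq_len(6L)) add_disease(mims[j], gg[j])
    add_ps("PS320002", mims)
    mk_ps_hp(red_idx + 2L, mims)
    cmb <- utils::combn(trio, 2)
    for (cc in seq_len(ncol(cmb))) {
      truth_otm[[length(truth_otm) + 1L]] <- tibble::tibble(
        group_id = "PS320002", term_i = cmb[1, cc], term_j = cmb[2, cc],
        status = "discarded", reason = "common_parent")
    }

    # majority-shared pair: small complex fully enclosed in a big one
    small <- sort(new_genes(4L))
    big <- sort(c(small, new_genes(6L)))
    r6 <- "GO:0910020"; r7 <- "GO:0910021"
    add_term(r6, "anion channel complex", "GO:0043234")
    add_term(r7, "inhibitory receptor complex", "GO:0043234")
    add_annotations(r6, big)
    add_annotations(r7, small)
    mims <- 320200L + 1:2
    add_disease(mims[1], small[1]); add_disease(mims[2], small[2])
    add_ps("PS320003", mims)
    mk_ps_hp(red_idx + 3L, mims)
    truth_otm[[length(truth_otm) + 1L]] <- tibble::tibble(
      group_id = "PS320003", term_i = r6, term_j = r7,
      status = "discarded", reason = "majority_shared")

    # disjoint unrelated trio (DNA-repair style): every pair kept
    f_terms <- c("GO:0910030", "GO:0910031", "GO:0910032")
    f_genes <- list()
    for (t in seq_along(f_terms)) {
      add_term(f_terms[t], sprintf("repair module %d complex", t), "GO:0043234")
      g2 <- sort(new_genes(2L))
      f_genes[[t]] <- g2
      add_annotations(f_terms[t], sort(c(g2, new_genes(2L))))
    }
    mims <- 320300L + seq_len(6L)
    gg <- unlist(f_genes)
    for (j in seq_len(6L)) add_disease(mims[j], gg[j])
    add_ps("PS320004", mims)
    mk_ps_hp(red_idx + 4L, mims)
    cmb <- utils::combn(f_terms, 2)
    for (cc in seq_len(ncol(cmb))) {
      truth_otm[[length(truth_otm) + 1L]] <- tibble::tibble(
        group_id = "PS320004", term_i = cmb[1, cc], term_j = cmb[2, cc],
        status = "kept", reason = NA_character_)
    }

    # many-to-one: two series sharing one protein on the same complex
    # (allele heterogeneity) and two disjoint series on another (kept)
    g_star <- new_genes(1L); ga <- new_genes(1L); gb <- new_genes(1L)
    t_term <- "GO:0910040"
    add_term(t_term, "growth receptor complex", "GO:0043234")
    add_annotations(t_term, sort(c(g_star, ga, gb, new_genes(3L))))
    mims_a <- 320400L + 1:2; mims_b <- 320400L + 3:4
    add_disease(mims_a[1], g_star); add_disease(mims_a[2], ga)
    add_disease(mims_b[1], g_star); add_disease(mims_b[2], gb)
    add_ps("PS320005", mims_a); add_ps("PS320006", mims_b)
    mk_ps_hp(red_idx + 5L, mims_a); mk_ps_hp(red_idx + 6L, mims_b)
    truth_mto[[length(truth_mto) + 1L]] <- tibble::tibble(
      term_id = t_term, group_i = "PS320005", group_j = "PS320006",
      status = "discarded", reason = "allele_heterogeneity")

    k_term <- "GO:0910041"
    add_term(k_term, "cation channel complex", "GO:0043234")
    gc1 <- sort(new_genes(2L)); gc2 <- sort(new_genes(2L))
    add_annotations(k_term, sort(c(gc1, gc2, new_genes(4L))))
    mims_c <- 320500L + 1:2; mims_d <- 320500L + 3:4
    add_disease(mims_c[1], gc1[1]); add_disease(mims_c[2], gc1[2])
    add_disease(mims_d[1], gc2[1]); add_disease(mims_d[2], gc2[2])
    add_ps("PS320007", mims_c); add_ps("PS320008", mims_d)
    mk_ps_hp(red_idx + 7L, mims_c); mk_ps_hp(red_idx + 8L, mims_d)
    truth_mto[[length(truth_mto) + 1L]] <- tibble::tibble(
      term_id = k_term, group_i = "PS320007", group_j = "PS320008",
      status = "kept", reason = NA_character_)
  }

  # -- gain-of-function series outside any complex -------------------------
  if (cfg$plant_gof_ps) {
    g3 <- sort(new_genes(3L))
    mims <- 460000L + seq_len(3L)
    for (j in seq_len(3L)) add_disease(mims[j], g3[j])
    add_ps("PS460001", mims)
    mk_ps_hp(100L, mims)
    gof <- c(gof, g3)
  }

  # -- background complexes and series ------------------------------------
  bg_pc_sizes <- sample_clipped_sizes(cfg$n_background_pc, cfg$pc_size)
  bg_pc_sizes <- pmin(bg_pc_sizes, length(pool))
  bg_pc_ids <- sprintf("GO:%07d", 700000L + seq_len(cfg$n_background_pc))
  bg_pc_members <- vector("list", cfg$n_background_pc)
  for (b in seq_len(cfg$n_background_pc)) {
    bg_pc_members[[b]] <- sort(sample(pool, bg_pc_sizes[b]))
    add_term(bg_pc_ids[b], sprintf("background machine %d complex", b),
             "GO:0043234")
    add_annotations(bg_pc_ids[b], bg_pc_members[[b]])
  }

  bg_ps_sizes <- sample_clipped_sizes(cfg$n_background_ps, cfg$ps_size)
  for (b in seq_len(cfg$n_background_ps)) {
    sz <- bg_ps_sizes[b]
    from_pc <- cfg$background_in_pc_frac > 0 &&
      stats::runif(1) < cfg$background_in_pc_frac &&
      cfg$n_background_pc > 0
    if (from_pc) {
      host <- bg_pc_members[[sample.int(cfg$n_background_pc, 1)]]
      sz <- min(sz, length(host))
      genes <- sort(sample(host, sz))
    } else {
      genes <- sort(sample(pool, sz))
    }
    mims <- 400000L + 100L * b + seq_len(sz)
    for (j in seq_len(sz)) add_disease(mims[j], genes[j])
    add_ps(sprintf("PS%06d", 400000L + b), mims)
    add_disease_hp(mims, sprintf("HP:%07d", 5000000L + b))
  }

  # -- background single-gene diseases outside any series ------------------
  # disease proteins not associated with locus heterogeneity; they populate
  # the non-LH pool of the non_lh randomization control
  if (cfg$n_background_diseases > 0) {
    bg_dis_genes <- sample(pool, min(cfg$n_background_diseases, length(pool)))
    for (d in seq_along(bg_dis_genes)) {
      add_disease(470000L + d, bg_dis_genes[d])
    }
  }

  # -- disease-based locus heterogeneity (multi-gene diseases) -------------
  if (cfg$n_multi_gene_diseases > 0) {
    for (d in seq_len(cfg$n_multi_gene_diseases)) {
      ng <- sample(2:4, 1)
      add_disease(450000L + d, sort(sample(pool, ng)))
    }
  }

  # -- gain-of-function flags on background disease proteins ---------------
  used_disease_genes <- unique(vapply(morbid, function(m) m$gene, integer(1)))
  bg_gof <- used_disease_genes[stats::runif(length(used_disease_genes)) < cfg$frac_gof]
  gof <- sort(unique(c(gof, bg_gof)))

  # -- lethal orthologs on complex members ---------------------------------
  pc_genes <- sort(unique(unlist(c(bg_pc_members,
                                   lapply(annot, function(a) a$entrez_id)),
                                 use.names = FALSE)))
  already <- unique(unlist(lapply(ortho, function(o) o$human_entrez_id),
                           use.names = FALSE))
  lethal_pool <- setdiff(pc_genes, already)
  lethal <- lethal_pool[stats::runif(length(lethal_pool)) < cfg$frac_lethal]
  stages <- c("embryonic", "fetal", "prenatal")
  for (g in lethal) add_ortholog(g, character(0), stage = sample(stages, 1))

  # -- morbid-map decoys (one per discard rule) ----------------------------
  if (cfg$plant_decoys) {
    decoy_gene <- function(...) new_genes(1L, ...)
    note_discard <- function(label, reason) {
      truth_discards[[length(truth_discards) + 1L]] <<-
        tibble::tibble(phenotype_label = label, reason = reason)
    }
    d <- 500000L
    add_disease(d + 1L, decoy_gene(), label = "?Uncertain syndrome")
    note_discard("?Uncertain syndrome", "unconfirmed")
    add_disease(d + 2L, decoy_gene(), label = "[Laboratory trait]")
    note_discard("[Laboratory trait]", "non_disease")
    add_disease(d + 3L, decoy_gene(), label = "{Infection susceptibility}")
    note_discard("{Infection susceptibility}", "susceptibility")
    add_disease(d + 4L, decoy_gene(), label = "Linked-only disorder", key = 1L)
    note_discard("Linked-only disorder", "mapping_key")
    add_disease(d + 5L, decoy_gene(), label = "Unknown-mutation disorder", key = 2L)
    note_discard("Unknown-mutation disorder", "mapping_key")
    add_disease(d + 6L, decoy_gene(), label = "Polygenic disorder", key = 4L)
    note_discard("Polygenic disorder", "mapping_key")
    add_disease(NA_integer_, decoy_gene(), label = "Orphan disorder")
    note_discard("Orphan disorder", "no_phenotype_mim")
    add_disease(d + 7L, decoy_gene(status = "moved"), label = "Moved-gene disorder")
    note_discard("Moved-gene disorder", "gene_unmapped")
    add_disease(d + 8L, decoy_gene(status = "removed"), label = "Removed-gene disorder")
    note_discard("Removed-gene disorder", "gene_unmapped")
    add_disease(d + 9L, decoy_gene(status = "unmapped"), label = "Unmapped-gene disorder")
    note_discard("Unmapped-gene disorder", "gene_unmapped")
    add_disease(d + 10L, decoy_gene(coding = FALSE), label = "Noncoding-RNA disorder")
    note_discard("Noncoding-RNA disorder", "non_coding")
  }

  # -- extra unused catalog genes (catalog realism) ------------------------
  n_extra <- max(20L, round(0.05 * cfg$n_genes))
  extra <- new_genes(n_extra)
  noncoding_extra <- stats::runif(n_extra) < cfg$frac_noncoding
  # flip the coding flag on a fraction of the extras, post hoc
  gene_tbl <- do.call(rbind, reg$rows)
  gene_tbl$protein_coding[match(extra[noncoding_extra], gene_tbl$entrez_id)] <- FALSE

  # -- write the bundle ----------------------------------------------------
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    morbid = file.path(dir, "morbidmap.tsv"),
    genes = file.path(dir, "gene_catalog.tsv"),
    ps = file.path(dir, "ps_membership.tsv"),
    obo = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    matches = file.path(dir, "mp_hp_bestmatch.tsv"),
    disease_hp = file.path(dir, "disease_hp.tsv"),
    gof = file.path(dir, "gof_flags.tsv"),
    truth = file.path(dir, "truth.json")
  )

  morbid_lines <- vapply(morbid, function(m) {
    pheno <- if (is.na(m$mim)) sprintf("%s (%d)", m$label, m$key) else
      sprintf("%s, %06d (%d)", m$label, m$mim, m$key)
    paste(pheno, entrez_to_symbol(m$gene),
          sprintf("%06d", entrez_to_mim(m$gene)), "1p36.1", sep = "\t")
  }, character(1))
  writeLines(c("# synthetic morbid map", morbid_lines), paths$morbid)

  readr::write_tsv(tibble::tibble(
    gene_mim = gene_tbl$gene_mim,
    entrez_id = gene_tbl$entrez_id,
    status = gene_tbl$status,
    protein_coding = gene_tbl$protein_coding
  ), paths$genes, progress = FALSE)

  ps_tbl <- if (length(ps_rows) > 0) do.call(rbind, ps_rows) else
    tibble::tibble(ps_id = character(0), phenotype_mim = integer(0))
  readr::write_tsv(ps_tbl, paths$ps, progress = FALSE)

  obo_lines <- c("format-version: 1.2", "ontology: synthetic-cc", "")
  for (t in terms) {
    obo_lines <- c(obo_lines, "[Term]", paste0("id: ", t$id),
                   paste0("name: ", t$name),
                   paste0("namespace: ", t$namespace))
    if (t$obsolete) obo_lines <- c(obo_lines, "is_obsolete: true")
    for (p in t$parents) {
      obo_lines <- c(obo_lines, if (t$relation == "part_of")
        paste0("relationship: part_of ", p, " ! ", p) else
          paste0("is_a: ", p, " ! ", p))
    }
    obo_lines <- c(obo_lines, "")
  }
  writeLines(obo_lines, paths$obo)

  annot_tbl <- if (length(annot) > 0) unique(do.call(rbind, annot)) else
    tibble::tibble(entrez_id = integer(0), term_id = character(0))
  readr::write_tsv(annot_tbl, paths$annotations, progress = FALSE)

  ortho_tbl <- if (length(ortho) > 0) do.call(rbind, ortho) else
    tibble::tibble(human_entrez_id = integer(0), mouse_gene_id = character(0),
                   mp_terms = character(0), lethality_stage = character(0))
  readr::write_tsv(ortho_tbl, paths$orthologs, progress = FALSE)

  match_tbl <- if (length(matches) > 0) unique(do.call(rbind, matches)) else
    tibble::tibble(mp_term = character(0), hp_term = character(0))
  readr::write_tsv(match_tbl, paths$matches, progress = FALSE)

  if (length(dis_hp) > 0) {
    dis_hp_tbl <- do.call(rbind, dis_hp)
    dis_hp_tbl <- stats::aggregate(hp_terms ~ phenotype_mim, dis_hp_tbl,
                                   function(h) paste(unique(h), collapse = ";"))
    dis_hp_tbl <- tibble::as_tibble(dis_hp_tbl[order(dis_hp_tbl$phenotype_mim), ])
  } else {
    dis_hp_tbl <- tibble::tibble(phenotype_mim = integer(0), hp_terms = character(0))
  }
  readr::write_tsv(dis_hp_tbl, paths$disease_hp, progress = FALSE)

  readr::write_tsv(tibble::tibble(entrez_id = gof), paths$gof, progress = FALSE)

  truth <- structure(list(
    planted = if (length(truth_planted) > 0) do.call(rbind, truth_planted) else NULL,
    removals = tibble::tibble(term_id = names(truth_removals),
                              reason = unlist(truth_removals, use.names = FALSE)),
    discards = if (length(truth_discards) > 0) do.call(rbind, truth_discards) else NULL,
    relations_one_to_many = if (length(truth_otm) > 0) do.call(rbind, truth_otm) else NULL,
    relations_many_to_one = if (length(truth_mto) > 0) do.call(rbind, truth_mto) else NULL,
    config = cfg
  ), class = "lh_truth")

  tr_json <- truth
  class(tr_json) <- NULL
  class(tr_json$config) <- NULL
  jsonlite::write_json(tr_json, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  invisible(list(dir = dir, paths = paths, truth = truth))
}

#' @export
print.lh_truth <- function(x, ...) {
  cat("<lh_truth> ",
      if (is.null(x$planted)) 0L else nrow(x$planted), " planted overlaps, ",
      nrow(x$removals), " expected removals, ",
      if (is.null(x$discards)) 0L else nrow(x$discards), " expected discards\n",
      sep = "")
  invisible(x)
}
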