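nadph_fixture <- function() {
  # 4 disease proteins of one series inside a 12-member complex; two other
  # members (NCF4-like, NOX4-like) have orthologs whose mouse phenotype
  # best-matches a human phenotype of the series
  group <- 1:4
  pc <- 1:12
  orthologs <- tibble::tibble(
    human_entrez_id = c(5L, 6L, 7L, 8L),
    mouse_gene_id = c("ncf4", "nox4", "dull1", "dull2"),
    mp_terms = list("MP:0002412", "MP:0002412", "MP:0009999", character(0)),
    lethality_stage = c("none", "none", "none", "embryonic")
  )
  matches <- tibble::tibble(mp_term = c("MP:0002412", "MP:0009999"),
                            hp_term = c("HP:0002719", "HP:0008888"))
  disease_hp <- tibble::tibble(
    phenotype_mim = c(101L, 102L),
    hp_terms = list(c("HP:0002719", "HP:0000001"), "HP:0002719")
  )
  list(group = group, pc = pc, diseases = c(101L, 102L),
       orthologs = orthologs, matches = matches, disease_hp = disease_hp)
}

test_that("presumptive proteins need a phenotype match through the ortholog", {
  fx <- nadph_fixture()
  pres <- find_presumptive_proteins(fx$group, fx$pc, fx$diseases,
                                    fx$orthologs, fx$matches, fx$disease_hp)
  expect_equal(pres, c(5L, 6L))
  # protein 7 maps to an HP term no disease of the series carries;
  # protein 8 has no MP terms at all; 9:12 have no ortholog
  expect_false(any(c(7L, 8L) %in% pres))
  # disease proteins themselves are never candidates
  expect_length(intersect(pres, fx$group), 0)
})

test_that("presumptive discovery is monotone in the match table", {
  fx <- nadph_fixture()
  base <- find_presumptive_proteins(fx$group, fx$pc, fx$diseases,
                                    fx$orthologs, fx$matches, fx$disease_hp)
  wider <- rbind(fx$matches,
                 tibble::tibble(mp_term = "MP:0009999", hp_term = "HP:0000001"))
  more <- find_presumptive_proteins(fx$group, fx$pc, fx$diseases,
                                    fx$orthologs, wider, fx$disease_hp)
  expect_true(all(base %in% more))
  expect_true(7L %in% more)
})

test_that("the augmented coefficient keeps the original group size", {
  expect_equal(round(augmented_jaccard(4L, 2L, 4L, 12L), 2), 0.60)
  expect_equal(augmented_jaccard(4L, 0L, 4L, 12L), jaccard(1:4, 1:12))
  expect_equal(augmented_jaccard(2L, 1L, 2L, 4L), 1)
  expect_error(augmented_jaccard(3L, 2L, 3L, 4L), "exceeds the complex size")
})

test_that("augmentation recomputes coefficients and creates new records", {
  fx <- nadph_fixture()
  groups <- make_groups(list(PSA = fx$group), diseases = list(PSA = fx$diseases))
  catalog <- make_catalog(list("GO:0000001" = fx$pc))
  aug <- augment_intersections(groups, catalog, fx$orthologs, fx$matches,
                               fx$disease_hp)
  expect_equal(nrow(aug), 1L)
  expect_equal(round(aug$jc, 2), 0.33)
  expect_equal(round(aug$jc_augmented, 2), 0.60)
  expect_setequal(aug$presumptive[[1]], c(5L, 6L))
  expect_false(aug$is_new)

  # a series sharing only ONE protein reaches the two-protein bar through a
  # presumptive member: a new record
  groups2 <- make_groups(list(PSB = c(1L, 90L, 91L)),
                         diseases = list(PSB = fx$diseases))
  aug2 <- augment_intersections(groups2, catalog, fx$orthologs, fx$matches,
                                fx$disease_hp)
  expect_equal(nrow(aug2), 1L)
  expect_true(aug2$is_new)
  expect_gte(aug2$n_shared + aug2$n_presumptive, 2L)
})

test_that("augmented coefficients never fall below base ones; equality iff m = 0", {
  w <- generate_universe(world_config(seed = 31), tempfile("aug"))
  res <- run_lh_pipeline(w$paths, run_nulls = FALSE)
  aug <- res$augmented
  expect_gt(nrow(aug), 0)
  expect_true(all(aug$jc_augmented >= aug$jc))
  expect_equal(aug$jc_augmented == aug$jc, aug$n_presumptive == 0)
  # augmentation never loses a group that had a base intersection
  expect_true(all(unique(res$records$group_id) %in% unique(aug$group_id)))
})

test_that("gain-of-function annotations list series proteins outside the complex", {
  groups <- make_groups(list(PSA = 1:4, PSN = 21:23))
  catalog <- make_catalog(list("GO:0000001" = c(1:3, 11:13)))
  rec <- find_intersections(groups, catalog)
  ann <- annotate_gof(groups, rec, gof_flags = c(4L, 2L, 21L, 22L), catalog)

  a <- ann$annotations
  expect_equal(nrow(a), 1L)
  expect_equal(a$gof_outside_pc[[1]], 4L)  # 2 is inside the complex

  # a series of flagged proteins hitting no complex lands in the side report
  expect_equal(ann$no_intersection$group_id, "PSN")
  expect_setequal(ann$no_intersection$gof_proteins[[1]], c(21L, 22L))

  # all flagged proteins inside the complex: empty annotation
  ann2 <- annotate_gof(groups, rec, gof_flags = 2L, catalog)
  expect_equal(ann2$annotations$n_gof_outside, 0L)
})

test_that("lethality annotations cover exactly the complexes with essential members", {
  catalog <- make_catalog(list("GO:0000001" = 1:3, "GO:0000002" = 11:13,
                               "GO:0000003" = 21:22))
  orthologs <- tibble::tibble(
    human_entrez_id = c(1L, 21L, 22L, 11L),
    mouse_gene_id = c("m1", "m21", "m22", "m11"),
    mp_terms = list(character(0), character(0), character(0), "MP:0000001"),
    lethality_stage = c("embryonic", "fetal", "prenatal", "none")
  )
  leth <- annotate_lethality(catalog, orthologs)
  expect_setequal(leth$term_id, c("GO:0000001", "GO:0000003"))
  one <- leth[leth$term_id == "GO:0000001", ]
  expect_equal(one$essential_proteins[[1]], 1L)
  expect_equal(one$stages[[1]], "embryonic")
  # all members essential: all listed
  three <- leth[leth$term_id == "GO:0000003", ]
  expect_setequal(three$essential_proteins[[1]], c(21L, 22L))
})
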