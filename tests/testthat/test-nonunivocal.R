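hier <- function(...) {
  x <- list(...)
  tibble::tibble(term_id = vapply(x, `[[`, character(1), 1),
                 parent_id = vapply(x, `[[`, character(1), 2),
                 relation = "is_a")
}

rec_tbl <- function(groups, catalog) find_intersections(groups, catalog)

test_that("parent-child complex pairs are discarded, transitively", {
  groups <- make_groups(list(PSC = c(1L, 2L)))
  catalog <- make_catalog(
    list("GO:0000001" = 1:4, "GO:0000003" = c(1:2, 21:22)),
    edges = hier(c("GO:0000003", "GO:0000002"), c("GO:0000002", "GO:0000001"))
  )
  # GO:0000002 was pruned from the analysis set but remains in the hierarchy
  cls <- filter_one_to_many(rec_tbl(groups, catalog), catalog)
  expect_equal(cls$status, "discarded")
  expect_equal(cls$reason, "parent_child")
})

test_that("complexes sharing a direct parent are discarded together", {
  groups <- make_groups(list(PSH = c(1L, 2L, 11L, 12L, 21L, 22L)))
  catalog <- make_catalog(
    list("GO:0000011" = c(1:2, 5L), "GO:0000012" = c(11:12, 15L),
         "GO:0000013" = c(21:22, 25L)),
    edges = hier(c("GO:0000011", "GO:0000010"), c("GO:0000012", "GO:0000010"),
                 c("GO:0000013", "GO:0000010"))
  )
  cls <- filter_one_to_many(rec_tbl(groups, catalog), catalog)
  expect_equal(nrow(cls), 3L)
  expect_true(all(cls$status == "discarded"))
  expect_true(all(cls$reason == "common_parent"))
})

test_that("the generic umbrella terms never count as a shared parent", {
  groups <- make_groups(list(PSG = c(1L, 2L, 11L, 12L)))
  catalog <- make_catalog(
    list("GO:0000021" = c(1:2, 5L), "GO:0000022" = c(11:12, 15L)),
    edges = hier(c("GO:0000021", "GO:0043234"), c("GO:0000022", "GO:0043234"))
  )
  cls <- filter_one_to_many(rec_tbl(groups, catalog), catalog)
  expect_equal(cls$status, "kept")
})

test_that("a fully enclosed complex pair is discarded as majority-shared", {
  small <- 1:18
  big <- 1:40
  groups <- make_groups(list(PSE = c(1L, 2L)))
  catalog <- make_catalog(list("GO:0000031" = big, "GO:0000032" = small))
  cls <- filter_one_to_many(rec_tbl(groups, catalog), catalog)
  expect_equal(cls$reason, "majority_shared")

  # exactly half is NOT discarded: the rule is strictly more than half
  catalog2 <- make_catalog(list("GO:0000031" = c(1:2, 31:38),
                                "GO:0000032" = c(1:2, 41:42)))
  cls2 <- filter_one_to_many(rec_tbl(groups, catalog2), catalog2)
  expect_equal(cls2$status, "kept")
})

test_that("disjoint unrelated complexes are kept, pair by pair", {
  groups <- make_groups(list(PSF = c(1L, 2L, 11L, 12L, 21L, 22L)))
  catalog <- make_catalog(list("GO:0000041" = c(1:2, 51:52),
                               "GO:0000042" = c(11:12, 61:62),
                               "GO:0000043" = c(21:22, 71:72)))
  cls <- filter_one_to_many(rec_tbl(groups, catalog), catalog)
  expect_equal(nrow(cls), 3L)
  expect_true(all(cls$status == "kept"))
})

test_that("discard precedence is parent-child, then common parent, then sharing", {
  groups <- make_groups(list(PSP = c(1L, 2L)))
  # child fully enclosed in its parent: both rules apply, parent_child wins
  catalog <- make_catalog(
    list("GO:0000051" = 1:10, "GO:0000052" = 1:4),
    edges = hier(c("GO:0000052", "GO:0000051"))
  )
  cls <- filter_one_to_many(rec_tbl(groups, catalog), catalog)
  expect_equal(cls$reason, "parent_child")
})

test_that("series pairs on one complex are discarded only on a shared protein", {
  groups <- make_groups(list(PSA = c(1L, 2L), PSB = c(1L, 3L),
                             PSC = c(11L, 12L), PSD = c(13L, 14L)))
  catalog <- make_catalog(list("GO:0000061" = 1:5, "GO:0000062" = 11:16))
  rec <- rec_tbl(groups, catalog)
  cls <- filter_many_to_one(rec, groups)

  ab <- cls[cls$term_id == "GO:0000061", ]
  expect_equal(ab$status, "discarded")
  expect_equal(ab$reason, "allele_heterogeneity")
  cd <- cls[cls$term_id == "GO:0000062", ]
  expect_equal(cd$status, "kept")

  # a complex hit by a single series is never classified
  expect_false(any(!cls$term_id %in% c("GO:0000061", "GO:0000062")))
})

test_that("univocality counts collapse redundant complexes into one", {
  groups <- make_groups(list(
    UNI = c(1L, 2L),                      # one complex only
    RED = c(11L, 12L),                    # two complexes, parent-child
    TRU = c(21L, 22L, 31L, 32L)           # two unrelated complexes
  ))
  catalog <- make_catalog(
    list("GO:0000071" = 1:4,
         "GO:0000072" = c(11:12, 41L), "GO:0000073" = c(11:12, 41:45),
         "GO:0000074" = c(21:22, 51:52), "GO:0000075" = c(31:32, 61:62)),
    edges = hier(c("GO:0000072", "GO:0000073"))
  )
  rec <- rec_tbl(groups, catalog)
  rel <- classify_relations(rec, groups, catalog)

  uni <- stats::setNames(rel$univocal$univocal, rel$univocal$group_id)
  expect_true(uni[["UNI"]])
  expect_true(uni[["RED"]])    # redundant pair collapses to one
  expect_false(uni[["TRU"]])
  expect_equal(sum(rel$univocal$univocal) + sum(!rel$univocal$univocal),
               length(unique(rec$group_id)))
})

test_that("the relation graph honours its coefficient floor", {
  groups <- make_groups(list(PSA = 1:4, PSB = 11:12))
  catalog <- make_catalog(list("GO:0000081" = c(1:3, 41:44),
                               "GO:0000082" = c(11:12, 51:88)))
  rec <- rec_tbl(groups, catalog)
  rel <- classify_relations(rec, groups, catalog)

  g_floor <- export_relation_graph(rec, rel, jc_floor = 0.1)
  expect_true(all(g_floor$jc >= 0.1))
  expect_false("GO:0000082" %in% g_floor$term_id)

  g_all <- export_relation_graph(rec, rel, jc_floor = 0)
  expect_equal(nrow(g_all), nrow(rec))
  expect_equal(g_all$jc, rec$jc)
})
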