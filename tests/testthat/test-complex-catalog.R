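chain_obo <- function(extra = character(0)) {
  write_lines_tmp(c(
    "[Term]", "id: GO:0000001", "name: alpha complex",
    "namespace: cellular_component", "",
    "[Term]", "id: GO:0000002", "name: beta complex",
    "is_a: GO:0000001 ! alpha complex", "",
    "[Term]", "id: GO:0000003", "name: gamma complex",
    "relationship: part_of GO:0000002 ! beta complex", "",
    extra
  ), ".obo")
}

annot_tbl <- function(...) {
  x <- list(...)
  tibble::tibble(
    entrez_id = unlist(lapply(x, `[[`, "genes")),
    term_id = rep(vapply(x, `[[`, character(1), "term"),
                  vapply(x, function(e) length(e$genes), integer(1)))
  )
}

test_that("a parent of parent with protein-bearing children is removed", {
  ont <- read_obo(chain_obo())
  ann <- annot_tbl(list(term = "GO:0000001", genes = 1:2),
                   list(term = "GO:0000002", genes = 3:5),
                   list(term = "GO:0000003", genes = 6:8))
  cat <- select_and_prune_complexes(ont, ann)

  expect_setequal(cat$complexes$term_id, c("GO:0000002", "GO:0000003"))
  expect_equal(cat$removal_log$reason[cat$removal_log$term_id == "GO:0000001"],
               "parent_of_parent")
  expect_equal(cat$selected$class,
               c("parent_of_parent", "parent", "non_parent"))
})

test_that("a parent of parent stays when a child is devoid of proteins", {
  ont <- read_obo(chain_obo())
  ann <- annot_tbl(list(term = "GO:0000001", genes = 1:3),
                   list(term = "GO:0000003", genes = 6:8))
  cat <- select_and_prune_complexes(ont, ann)

  # removing the grandparent would lose its annotations: kept; the empty
  # middle term falls to the singleton rule instead
  expect_true("GO:0000001" %in% cat$complexes$term_id)
  expect_equal(cat$removal_log$reason[cat$removal_log$term_id == "GO:0000002"],
               "singleton")
})

test_that("generic terms and singletons are removed with their own reasons", {
  ont <- read_obo(write_lines_tmp(c(
    "[Term]", "id: GO:0005667", "name: transcription factor complex", "",
    "[Term]", "id: GO:0000010", "name: lonely complex", "",
    "[Term]", "id: GO:0000011", "name: proper complex", "",
    "[Term]", "id: GO:0000012", "name: nuclear envelope", "",
    "[Term]", "id: GO:0000013", "name: bygone complex", "is_obsolete: true", ""
  ), ".obo"))
  ann <- annot_tbl(list(term = "GO:0005667", genes = 1:40),
                   list(term = "GO:0000010", genes = 50L),
                   list(term = "GO:0000011", genes = 60:62),
                   list(term = "GO:0000012", genes = 70:75))
  cat <- select_and_prune_complexes(ont, ann)

  expect_equal(cat$complexes$term_id, "GO:0000011")
  log <- stats::setNames(cat$removal_log$reason, cat$removal_log$term_id)
  expect_equal(log[["GO:0005667"]], "generic")
  expect_equal(log[["GO:0000010"]], "singleton")
  # name without "complex" and obsolete terms are never selected
  expect_false(any(c("GO:0000012", "GO:0000013") %in% cat$selected$term_id))
})

test_that("substring match on 'complex' is case-insensitive", {
  ont <- read_obo(write_lines_tmp(c(
    "[Term]", "id: GO:0000020", "name: NADPH Oxidase Complex", ""
  ), ".obo"))
  cat <- select_and_prune_complexes(ont, annot_tbl(
    list(term = "GO:0000020", genes = 1:4)))
  expect_equal(cat$complexes$term_id, "GO:0000020")
})

test_that("removal reasons partition: kept + removed = selected", {
  ont <- read_obo(chain_obo(c(
    "[Term]", "id: GO:0000021", "name: spare complex", "",
    "[Term]", "id: GO:0000022", "name: single complex", ""
  )))
  ann <- annot_tbl(list(term = "GO:0000001", genes = 1:2),
                   list(term = "GO:0000002", genes = 3:5),
                   list(term = "GO:0000003", genes = 6:8),
                   list(term = "GO:0000021", genes = 9:11),
                   list(term = "GO:0000022", genes = 12L))
  cat <- select_and_prune_complexes(ont, ann)
  expect_equal(nrow(cat$complexes) + nrow(cat$removal_log), nrow(cat$selected))
  expect_false(anyDuplicated(cat$removal_log$term_id) > 0)
  expect_length(intersect(cat$complexes$term_id, cat$removal_log$term_id), 0)
})

test_that("pruning is idempotent on its own output", {
  ont <- read_obo(chain_obo())
  ann <- annot_tbl(list(term = "GO:0000001", genes = 1:2),
                   list(term = "GO:0000002", genes = 3:5),
                   list(term = "GO:0000003", genes = 6:8))
  cat1 <- select_and_prune_complexes(ont, ann)

  kept <- cat1$complexes$term_id
  ont2 <- list(terms = ont$terms[ont$terms$term_id %in% kept, ],
               edges = ont$edges[ont$edges$term_id %in% kept &
                                   ont$edges$parent_id %in% kept, ])
  class(ont2) <- "lh_ontology"
  cat2 <- select_and_prune_complexes(ont2, ann[ann$term_id %in% kept, ])
  expect_setequal(cat2$complexes$term_id, kept)
  expect_equal(
    lapply(cat2$complexes$proteins, identity),
    lapply(cat1$complexes$proteins[match(cat2$complexes$term_id,
                                         cat1$complexes$term_id)], identity))
})

test_that("annotations to unknown terms are dropped with a warning", {
  ont <- read_obo(chain_obo())
  ann <- rbind(annot_tbl(list(term = "GO:0000002", genes = 1:3)),
               tibble::tibble(entrez_id = 99L, term_id = "GO:9999999"))
  expect_warning(cat <- select_and_prune_complexes(ont, ann), "absent from")
  expect_false(99L %in% unlist(cat$complexes$proteins))
})
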