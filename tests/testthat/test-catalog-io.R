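test_that("morbid map rows parse with markers, keys and identifiers intact", {
  path <- morbid_file(c(
    "# comment line",
    "Tuberous sclerosis-1, 191100 (3)\tTSC1\t605284\t9q34.13",
    "{Asthma}, 600807 (3)\tIL9R\t300007\tXq28",
    "[Blood group, ABO], 616093 (3)\tABO\t110300\t9q34.2",
    "?Mystery syndrome, 612345 (3)\tMYS1\t612000\t1p36",
    "No-mim phenotype (2)\tNOM1\t613000\t2q31"
  ))
  rows <- read_morbid_map(path)

  expect_equal(nrow(rows), 5L)
  expect_equal(attr(rows, "n_data_lines"), 5L)

  tsc <- rows[1, ]
  expect_equal(tsc$phenotype_label, "Tuberous sclerosis-1")
  expect_equal(tsc$phenotype_mim, 191100L)
  expect_equal(tsc$mapping_key, 3L)
  expect_equal(tsc$gene_mim, 605284L)
  expect_equal(tsc$marker, "none")
  expect_equal(tsc$gene_symbols[[1]], "TSC1")

  expect_equal(rows$marker, c("none", "braces", "brackets", "question", "none"))
  # markers are detected, never stripped
  expect_equal(rows$phenotype_label[2], "{Asthma}")
  expect_true(is.na(rows$phenotype_mim[5]))
  expect_equal(rows$mapping_key[5], 2L)
})

test_that("malformed morbid lines raise errors naming the line", {
  expect_error(read_morbid_map(morbid_file("No key here\tG1\t600001\t1p1")),
               "line 1.*missing mapping key")
  expect_error(read_morbid_map(morbid_file(c(
    "Fine, 100001 (3)\tG1\t600001\t1p1",
    "Bad key, 100002 (x)\tG2\t600002\t1p2"
  ))), "line 2.*non-integer")
  expect_error(read_morbid_map(morbid_file("{Unbalanced, 100003 (3)\tG3\t600003\t1p3")),
               "unbalanced")
  expect_error(read_morbid_map(morbid_file("Only one column (3)")),
               "3 tab-separated columns")
})

test_that("empty morbid map file yields an empty table", {
  rows <- read_morbid_map(morbid_file("# nothing but comments"))
  expect_equal(nrow(rows), 0L)
  expect_equal(attr(rows, "n_data_lines"), 0L)
})

test_that("morbid map survives a write/read round trip", {
  path <- morbid_file(c(
    "Tuberous sclerosis-1, 191100 (3)\tTSC1\t605284\t9q34.13",
    "{Asthma}, 600807 (3)\tIL9R, IL9RP3\t300007\tXq28",
    "Orphan disorder (3)\tORP1\t613001\t3q22"
  ))
  rows <- read_morbid_map(path)
  path2 <- tempfile(fileext = ".tsv")
  write_morbid_map(rows, path2)
  rows2 <- read_morbid_map(path2)
  rows$line <- rows2$line <- NULL
  expect_equal(as.data.frame(rows), as.data.frame(rows2))
})

test_that("OBO terms parse with both parent relation kinds and obsolete flags", {
  path <- write_lines_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: TAP complex",
    "namespace: cellular_component",
    "is_a: GO:0043234 ! protein complex", "",
    "[Term]", "id: GO:0000002", "name: dual parent complex",
    "is_a: GO:0000001 ! TAP complex",
    "relationship: part_of GO:0043234 ! protein complex", "",
    "[Term]", "id: GO:0000003", "name: retired complex", "is_obsolete: true", "",
    "[Term]", "id: GO:0043234", "name: protein complex", "",
    "[Typedef]", "id: part_of", "name: part of"
  ), ".obo")
  ont <- read_obo(path)

  expect_s3_class(ont, "lh_ontology")
  expect_equal(nrow(ont$terms), 4L)
  expect_equal(ont$terms$name[ont$terms$term_id == "GO:0000001"], "TAP complex")
  e1 <- ont$edges[ont$edges$term_id == "GO:0000001", ]
  expect_equal(nrow(e1), 1L)
  e2 <- ont$edges[ont$edges$term_id == "GO:0000002", ]
  expect_equal(nrow(e2), 2L)
  expect_setequal(e2$relation, c("is_a", "part_of"))
  expect_true(ont$terms$obsolete[ont$terms$term_id == "GO:0000003"])
  expect_true(all(ont$edges$resolved))
})

test_that("dangling parents warn and are flagged; self-loops are fatal", {
  dangling <- write_lines_tmp(c(
    "[Term]", "id: GO:0000001", "name: stray complex",
    "is_a: GO:9999999 ! not defined here"
  ), ".obo")
  expect_warning(ont <- read_obo(dangling), "unresolved")
  expect_false(ont$edges$resolved[1])

  loop <- write_lines_tmp(c(
    "[Term]", "id: GO:0000001", "name: loop complex",
    "is_a: GO:0000001 ! itself"
  ), ".obo")
  expect_error(read_obo(loop), "self-loop")
})

test_that("auxiliary tables parse, deduplicate and validate their headers", {
  orth <- read_ortholog_phenotypes(write_lines_tmp(c(
    "human_entrez_id\tmouse_gene_id\tmp_terms\tlethality_stage",
    "4688\tNcf4\tMP:0002412\t",
    "50507\tNox4\tMP:0002412;MP:0000001\tnone",
    "999\tLethal1\t\tembryonic"
  )))
  expect_equal(orth$human_entrez_id, c(4688L, 50507L, 999L))
  expect_equal(orth$mp_terms[[2]], c("MP:0002412", "MP:0000001"))
  expect_equal(orth$mp_terms[[3]], character(0))
  expect_equal(orth$lethality_stage, c("none", "none", "embryonic"))

  empty <- read_ortholog_phenotypes(write_lines_tmp(
    "human_entrez_id\tmouse_gene_id\tmp_terms\tlethality_stage"))
  expect_equal(nrow(empty), 0L)

  matches <- read_phenotype_matches(write_lines_tmp(c(
    "mp_term\thp_term",
    "MP:0002412\tHP:0002719",
    "MP:0002412\tHP:0002719"
  )))
  expect_equal(nrow(matches), 1L)

  expect_error(
    read_ps_membership(write_lines_tmp(c("ps_id\tbogus", "PS191100\t191100"))),
    "unknown column 'bogus'")
  expect_error(
    read_disease_phenotypes(write_lines_tmp(c("phenotype_mim\thp_terms",
                                              "191100\t"))),
    "empty hp_terms")
  expect_error(
    read_gene_catalog(write_lines_tmp(c(
      "gene_mim\tentrez_id\tstatus\tprotein_coding",
      "600001\t1001\tzombie\tTRUE"))),
    "unknown status")
  expect_warning(
    read_gene_catalog(write_lines_tmp(c(
      "gene_mim\tentrez_id\tstatus\tprotein_coding",
      "600001\t1001\tmoved\tTRUE"))),
    "non-active")
})
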