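# Folding, unfolding, validation and deepening of annotation corpora.

fx <- generate_fixtures(seed = 1)
ont <- fx$ontology
rels <- fx$relations
reg <- fx$registry

test_that("folding materializes classified terms and rewrites records", {
  makap <- fx$records[fx$records$db_object_symbol == "Akap6", ]
  res <- fold(makap, ont)
  expect_equal(nrow(res$mapping), 1L)
  fid <- res$mapping$folded_id
  expect_match(fid, "^GOX:")
  expect_equal(res$records$go_id, fid)
  expect_equal(res$records$annotation_extension, "")
  # the folded term is classified under its source term (and its ancestors)
  expect_true("GO:0005635" %in% subsumers(res$index, fid))
  expect_true("GO:0005575" %in% subsumers(res$index, fid))
  # and carries the equivalence axiom in the application ontology
  app_eq <- res$application_ontology$equivalence
  mine <- Filter(function(e) e$defined == fid, app_eq)
  expect_length(mine, 1L)
  expect_equal(mine[[1]]$genus, "GO:0005635")
})

test_that("folding an unextended corpus is the identity", {
  plain <- fx$records[vapply(fx$records$extension, n_conjunctions,
                             integer(1)) == 0L, ]
  res <- fold(plain, ont)
  expect_equal(nrow(res$mapping), 0L)
  expect_equal(res$records$go_id, plain$go_id)
})

test_that("identical (term, extension) pairs share one folded term", {
  two <- bind_records(
    gaf_record(db = "MGI", db_object_id = "a", go_id = "GO:0005634",
               aspect = "C",
               annotation_extension = "part_of(CL:0000127)"),
    gaf_record(db = "MGI", db_object_id = "b", go_id = "GO:0005634",
               aspect = "C",
               annotation_extension = "part_of(CL:0000127)"))
  res <- fold(two, ont)
  expect_equal(nrow(res$mapping), 1L)
  expect_equal(res$records$go_id[1], res$records$go_id[2])
  # content-addressed ids are stable across runs and corpora
  res2 <- fold(two[1, ], ont)
  expect_equal(res2$mapping$folded_id, res$mapping$folded_id)
  # record count is conserved after disjunction splitting
  expect_equal(nrow(res$records), 2L)
})

test_that("folding splits disjunctions and conserves record count", {
  res <- fold(fx$records, ont)
  expect_equal(nrow(res$records), nrow(split_disjunction(fx$records)))
  expect_true(all(res$records$go_id %in%
                    res$application_ontology$terms$id |
                    !startsWith(res$records$go_id, "GOX:")))
})

test_that("NOT-qualified and unknown-relation records are not folded", {
  recs <- bind_records(
    gaf_record(db = "MGI", db_object_id = "a", qualifier = "NOT",
               go_id = "GO:0005634", aspect = "C",
               annotation_extension = "part_of(CL:0000127)"),
    gaf_record(db = "MGI", db_object_id = "b", go_id = "GO:0005634",
               aspect = "C",
               annotation_extension = "mystery_rel(CL:0000127)"))
  res <- fold(recs, ont)
  expect_equal(nrow(res$mapping), 0L)
  expect_equal(res$records$go_id, recs$go_id)
  expect_setequal(res$report$rule, c("GRAMMAR", "UNKNOWN_RELATION"))
})

test_that("unsatisfiable folded terms are flagged and retained", {
  bad <- gaf_record(db = "PomBase", db_object_id = "x",
                    go_id = "GO:0051403", aspect = "P",
                    annotation_extension = "occurs_in(GO:0006915)")
  res <- fold(bad, ont)
  expect_equal(nrow(res$mapping), 1L)
  expect_true(res$mapping$unsatisfiable)
  expect_true(res$mapping$folded_id %in%
                res$application_ontology$terms$id)
  expect_true("UNSATISFIABLE" %in% res$report$rule)
})

test_that("unfolding rewrites logically defined terms to genus + extension", {
  rec <- gaf_record(db = "MGI", db_object_id = "a", go_id = "GO:0097483",
                    aspect = "C")
  out <- unfold(rec, ont)
  expect_equal(out$go_id, "GO:0014069")
  expect_equal(out$annotation_extension, "part_of(CL:0000243)")
  # a primitive term is untouched
  prim <- gaf_record(db = "MGI", db_object_id = "b", go_id = "GO:0005634",
                     aspect = "C")
  expect_equal(unfold(prim, ont)$go_id, "GO:0005634")
})

test_that("unfolding merges the differentia into existing conjunctions", {
  rec <- gaf_record(db = "MGI", db_object_id = "a", go_id = "GO:0097483",
                    aspect = "C",
                    annotation_extension = "part_of(UBERON:0000955)")
  out <- unfold(rec, ont)
  expect_equal(out$go_id, "GO:0014069")
  expect_equal(out$annotation_extension,
               "part_of(UBERON:0000955),part_of(CL:0000243)")
})

test_that("fold then unfold reproduces the corpus modulo conjunct order", {
  check_roundtrip <- function(records) {
    orig <- split_disjunction(records)
    res <- fold(records, ont)
    back <- unfold(res$records, res$application_ontology)
    expect_equal(back$go_id, orig$go_id)
    expect_equal(vapply(back$extension, canonical_conj_string, character(1)),
                 vapply(orig$extension, canonical_conj_string, character(1)))
  }
  check_roundtrip(fx$records)
  withr::with_seed(55, {
    for (i in 1:20) check_roundtrip(random_fixture_corpus(6L))
  })
})

test_that("recursive unfolding reaches a fixed point", {
  # two-level definition: deep = GO:0097483 and occurs_in neuron
  deep_ont <- ont
  deep_ont$terms <- rbind(deep_ont$terms,
                          term_tbl("GO:9999999", "deep psd",
                                   "cellular_component"))
  deep_ont$equivalence <- c(deep_ont$equivalence, list(list(
    defined = "GO:9999999", genus = "GO:0097483",
    differentia = tibble::tibble(relation = "occurs_in",
                                 filler = "CL:0000540"))))
  rec <- gaf_record(db = "X", db_object_id = "a", go_id = "GO:9999999",
                    aspect = "C")
  one <- unfold(rec, deep_ont)
  expect_equal(one$go_id, "GO:0097483")
  full <- unfold(rec, deep_ont, recursive = TRUE)
  expect_equal(full$go_id, "GO:0014069")
  expect_setequal(
    vapply(full$extension[[1]]$conjunctions[[1]], format, character(1)),
    c("occurs_in(CL:0000540)", "part_of(CL:0000243)"))
})

test_that("validation flags each rule class with the right severity", {
  txt <- paste(c(
    "!gaf-version: 2.0",
    # clean
    "MGI\ta\tg1\t\tGO:0005634\tPMID:1\tIDA\t\tC\t\t\tprotein\ttaxon:10090\t20140101\tMGI\tpart_of(CL:0000127)\t",
    # grammar error (nested parens)
    "MGI\tb\tg2\t\tGO:0005634\tPMID:1\tIDA\t\tC\t\t\tprotein\ttaxon:10090\t20140101\tMGI\tpart_of(x(CL:1))\t",
    # unknown relation
    "MGI\tc\tg3\t\tGO:0005634\tPMID:1\tIDA\t\tC\t\t\tprotein\ttaxon:10090\t20140101\tMGI\tmystery(CL:0000127)\t",
    # prefix not in registry
    "MGI\td\tg4\t\tGO:0005634\tPMID:1\tIDA\t\tC\t\t\tprotein\ttaxon:10090\t20140101\tMGI\tpart_of(NOPEDB:123)\t",
    # aspect misuse: occurs_in on a cellular_component term
    "MGI\te\tg5\t\tGO:0005634\tPMID:1\tIDA\t\tC\t\t\tprotein\ttaxon:10090\t20140101\tMGI\toccurs_in(CL:0000127)\t",
    # filler misuse: has_direct_input with a cell-type filler
    "MGI\tf\tg6\t\tGO:0004672\tPMID:1\tIDA\t\tF\t\t\tprotein\ttaxon:10090\t20140101\tMGI\thas_direct_input(CL:0000127)\t",
    # unsatisfiable: occurs_in a biological process
    "MGI\tg\tg7\t\tGO:0051403\tPMID:1\tIMP\t\tP\t\t\tprotein\ttaxon:10090\t20140101\tMGI\toccurs_in(GO:0006915)\t",
    # duplicate expression
    "MGI\th\tg8\t\tGO:0005634\tPMID:1\tIDA\t\tC\t\t\tprotein\ttaxon:10090\t20140101\tMGI\tpart_of(CL:0000127),part_of(CL:0000127)\t"),
    collapse = "\n")
  recs <- read_gaf(text = txt)
  report <- validate_annotations(recs, ont, rels, reg)
  by_rec <- split(report, report$record)
  expect_null(by_rec[["1"]])
  expect_equal(by_rec[["2"]]$rule, "GRAMMAR")
  expect_equal(by_rec[["3"]]$rule, "UNKNOWN_RELATION")
  expect_equal(by_rec[["4"]]$rule, "PREFIX")
  expect_equal(by_rec[["5"]]$rule, "USAGE_ASPECT")
  expect_equal(by_rec[["6"]]$rule, "USAGE_FILLER")
  expect_equal(by_rec[["7"]]$rule, "UNSATISFIABLE")
  expect_equal(by_rec[["8"]]$rule, "DUPLICATE")
  sev <- stats::setNames(report$severity, report$rule)
  expect_equal(unname(sev[c("GRAMMAR", "UNKNOWN_RELATION", "PREFIX",
                            "UNSATISFIABLE")]),
               rep("error", 4))
  expect_equal(unname(sev[c("USAGE_ASPECT", "USAGE_FILLER", "DUPLICATE")]),
               rep("warning", 3))
})

test_that("the clean fixture corpus validates with an empty report", {
  report <- validate_annotations(fx$records, ont, rels, reg)
  expect_equal(nrow(report), 0L)
})

test_that("ancestor-class filler constraints use the classification", {
  rels2 <- rels
  rels2[["part_of"]]$allowed_fillers <- "CL:0000243"  # glial cells only
  ok <- gaf_record(db = "MGI", db_object_id = "a", go_id = "GO:0005634",
                   aspect = "C",
                   annotation_extension = "part_of(CL:0000127)")
  bad <- gaf_record(db = "MGI", db_object_id = "b", go_id = "GO:0005634",
                    aspect = "C",
                    annotation_extension = "part_of(CL:0000540)")
  expect_equal(nrow(validate_annotations(ok, ont, rels2, reg)), 0L)
  rep_bad <- validate_annotations(bad, ont, rels2, reg)
  expect_equal(rep_bad$rule, "USAGE_FILLER")
})

test_that("deepening moves the psd+astrocyte record to the glial-cell term", {
  rec <- gaf_record(db = "MGI", db_object_id = "a", go_id = "GO:0014069",
                    aspect = "C",
                    annotation_extension = "part_of(CL:0000127)")
  out <- deepen(rec, ont)
  expect_equal(out$go_id, "GO:0097483")
  # the astrocyte qualifier is strictly more specific than the glial-cell
  # definition, so the extension still carries information and is retained
  expect_equal(out$annotation_extension, "part_of(CL:0000127)")
})

test_that("deepening drops the extension when the MSC is equivalent to it", {
  rec <- gaf_record(db = "MGI", db_object_id = "a", go_id = "GO:0014069",
                    aspect = "C",
                    annotation_extension = "part_of(CL:0000243)")
  out <- deepen(rec, ont)
  expect_equal(out$go_id, "GO:0097483")
  expect_equal(out$annotation_extension, "")
})

test_that("deepening leaves unextended, NOT-qualified and unmovable records alone", {
  recs <- bind_records(
    gaf_record(db = "MGI", db_object_id = "a", go_id = "GO:0005634",
               aspect = "C"),
    gaf_record(db = "MGI", db_object_id = "b", qualifier = "NOT",
               go_id = "GO:0014069", aspect = "C",
               annotation_extension = "part_of(CL:0000127)"),
    gaf_record(db = "MGI", db_object_id = "c", go_id = "GO:0005634",
               aspect = "C",
               annotation_extension = "part_of(CL:0000312)"))
  out <- deepen(recs, ont)
  expect_equal(out$go_id, recs$go_id)
  expect_equal(out$annotation_extension, recs$annotation_extension)
})

test_that("deepening is idempotent", {
  once <- deepen(fx$records, ont)
  twice <- deepen(once, ont)
  expect_equal(twice$go_id, once$go_id)
  expect_equal(twice$annotation_extension, once$annotation_extension)
})

test_that("deepening an unsatisfiable extension is an error pointing to validation", {
  rec <- gaf_record(db = "MGI", db_object_id = "a", go_id = "GO:0051403",
                    aspect = "P",
                    annotation_extension = "occurs_in(GO:0006915)")
  expect_error(deepen(rec, ont), "validate",
               class = "goext_unsatisfiable")
})

test_that("deepened terms always subsume the translated expression", {
  withr::with_seed(77, {
    recs <- random_fixture_corpus(12L)
    out <- deepen(recs, ont)
    for (i in seq_len(nrow(out))) {
      f <- recs$extension[[i]]
      if (n_conjunctions(f) != 1L) next
      expr <- conjunction_to_class_expression(recs$go_id[i],
                                              f$conjunctions[[1]], rels)
      expect_true(is_subsumed(expr, ce_named(out$go_id[i]), ont),
                  info = sprintf("record %d", i))
    }
  })
})
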