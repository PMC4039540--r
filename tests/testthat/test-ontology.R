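# OBO-subset parsing/writing, built-in relations, registry, fixtures.

fx <- generate_fixtures(seed = 1)

test_that("a minimal Term stanza yields one term and no axioms", {
  ont <- parse_obo(text = c("[Term]", "id: GO:0000001", "name: thing"))
  expect_equal(nrow(ont$terms), 1L)
  expect_equal(ont$terms$id, "GO:0000001")
  expect_equal(nrow(ont$subclass), 0L)
  expect_length(ont$equivalence, 0L)
})

test_that("intersection_of blocks become genus-differentia equivalence axioms", {
  txt <- c(
    "[Term]", "id: GO:0014069", "name: postsynaptic density",
    "namespace: cellular_component", "",
    "[Term]", "id: GO:0097483", "name: glial cell postsynaptic density",
    "namespace: cellular_component",
    "is_a: GO:0014069",
    "intersection_of: GO:0014069",
    "intersection_of: part_of CL:0000243")
  ont <- parse_obo(text = txt)
  expect_length(ont$equivalence, 1L)
  eq <- ont$equivalence[[1]]
  expect_equal(eq$defined, "GO:0097483")
  expect_equal(eq$genus, "GO:0014069")
  expect_equal(eq$differentia$relation, "part_of")
  expect_equal(eq$differentia$filler, "CL:0000243")
})

test_that("malformed stanzas raise errors naming the stanza", {
  dup <- c("[Term]", "id: GO:1", "name: a", "[Term]", "id: GO:1", "name: b")
  expect_error(parse_obo(text = dup), "duplicate stanza id",
               class = "goext_obo_error")
  no_genus <- c("[Term]", "id: GO:2", "name: x",
                "intersection_of: part_of CL:1")
  expect_error(parse_obo(text = no_genus), "GO:2",
               class = "goext_obo_error")
  no_diff <- c("[Term]", "id: GO:3", "name: y",
               "intersection_of: GO:4")
  expect_error(parse_obo(text = no_diff), "GO:3",
               class = "goext_obo_error")
})

test_that("unsupported tags are ignored with a warning, never an error", {
  txt <- c("[Term]", "id: GO:1", "name: a",
           "def: \"something\" [PMID:1]", "comment: hello")
  expect_warning(ont <- parse_obo(text = txt), "def",
                 class = "goext_obo_warning")
  expect_equal(nrow(ont$terms), 1L)
})

test_that("is_a count in the fixture OBO matches the parsed subclass axioms", {
  # independent line-count oracle over the serialized text
  n_lines <- sum(grepl("^is_a:", fx$obo$go))
  ont <- suppressWarnings(parse_obo(text = fx$obo$go))
  expect_equal(nrow(ont$subclass), n_lines)
  expect_gt(n_lines, 0L)
})

test_that("parse_obo and write_obo are mutually inverse on the subset", {
  for (obo in list(fx$obo$go, fx$obo$cl, fx$obo$uberon)) {
    ont <- parse_obo(text = obo)
    expect_identical(write_obo(ont), obo)
  }
  # typedef metadata round-trips through the relations file
  rel_ont <- parse_obo(text = fx$relations_obo)
  expect_identical(write_obo(rel_ont), fx$relations_obo)
  roi <- rel_ont$relations[["regulates_occurs_in"]]
  expect_equal(roi$chain, c("regulates", "occurs_in"))
  expect_equal(roi$range_category, "continuant")
  oc <- rel_ont$relations[["occurs_in"]]
  expect_equal(sort(oc$allowed_aspects),
               sort(c("molecular_function", "biological_process")))
  expect_true("CL" %in% oc$allowed_fillers)
})

test_that("built-in relation set covers the common extension relations", {
  rels <- builtin_relations()
  for (lab in c("part_of", "occurs_in", "happens_during",
                "has_regulation_target", "has_input", "has_direct_input",
                "regulates_occurs_in")) {
    expect_true(lab %in% names(rels), info = lab)
  }
  expect_equal(rels[["part_of"]]$property_id, "BFO:0000050")
  expect_equal(rels[["regulates_occurs_in"]]$chain,
               c("regulates", "occurs_in"))
  expect_null(rels[["no_such_relation"]])
})

test_that("relation chains must resolve and have length 0 or >= 2", {
  expect_error(relation_def("x", chain = "part_of"),
               class = "goext_obo_error")
  expect_error(
    ontology(relations = list(
      bad = relation_def("bad", chain = c("nope", "part_of")))),
    class = "goext_obo_error")
})

test_that("registry matching is exact and case-sensitive", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(fx$registry_tsv, tmp)
  reg <- read_registry(tmp)
  expect_true("PomBase" %in% names(reg))
  expect_false("pombase" %in% names(reg))
  expect_identical(write_registry(reg), fx$registry_tsv)
})

test_that("fixture generation is deterministic per seed", {
  a <- generate_fixtures(seed = 11)
  b <- generate_fixtures(seed = 11)
  expect_identical(a$gaf, b$gaf)
  expect_identical(a$gpad, b$gpad)
  c <- generate_fixtures(seed = 12)
  expect_false(identical(a$gaf, c$gaf))
  # the Nep1 worked example is present verbatim
  expect_true(any(grepl(
    "has_direct_input\\(PomBase:SPAC17G6.12\\),has_direct_input\\(PomBase:SPAC24H6.03\\),has_direct_input\\(PomBase:SPAC3A11.08\\)",
    a$gaf)))
})

test_that("obsolete terms are excluded from reasoning", {
  ont <- parse_obo(text = c(
    "[Term]", "id: GO:1", "name: live", "",
    "[Term]", "id: GO:2", "name: dead", "is_obsolete: true",
    "is_a: GO:1"))
  idx <- classify(ont)
  expect_false("GO:1" %in% subsumers(idx, "GO:2"))
})
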