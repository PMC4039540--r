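# EL completion reasoner: normalization, saturation, queries, and
# agreement with the independent brute-force oracle.

fx <- generate_fixtures(seed = 1)
ont <- fx$ontology
rels <- fx$relations

test_that("normalization keeps atomic axioms and encodes equivalences both ways", {
  simple <- ontology(terms = rbind(term_tbl("A:1"), term_tbl("A:2")),
                     subclass = data.frame(child = "A:1", parent = "A:2"))
  ax <- normalize_axioms(simple)
  expect_true(any(ax$sub$sub == "A:1" & ax$sub$sup == "A:2"))
  expect_equal(ax$n_fresh, 0L)

  # the mAKAP query class: deterministic fresh names, definitional axioms
  # in both directions (query <-> intersection representative)
  q <- conjunction_to_class_expression(
    "GO:0005635", list(rel_expr("part_of", "CL:0002495"),
                       rel_expr("part_of", "UBERON:0002082")), rels)
  ax2 <- normalize_axioms(ontology(), queries = list("FRESHQ:q" = q),
                          relations = rels)
  # two existentials + the intersection representative + one conjunction
  # intermediate: deterministic for this encoder
  expect_equal(ax2$n_fresh, 4L)
  expect_true(any(ax2$sub$sub == "FRESHQ:q" & grepl("^FRESH:", ax2$sub$sup)))
  expect_true(any(ax2$sub$sup == "FRESHQ:q" & grepl("^FRESH:", ax2$sub$sub)))
  # rerunning yields identical normal forms
  ax3 <- normalize_axioms(ontology(), queries = list("FRESHQ:q" = q),
                          relations = rels)
  expect_identical(ax2$sub, ax3$sub)
})

test_that("an empty axiom set saturates to reflexive subsumptions only", {
  empty <- ontology(terms = rbind(term_tbl("A:1"), term_tbl("A:2")))
  idx <- classify(empty)
  expect_equal(sort(subsumers(idx, "A:1")), "A:1")
  expect_length(idx$unsatisfiable, 0L)
})

test_that("occurs_in with a process filler is unsatisfiable (range is a continuant)", {
  bad <- conjunction_to_class_expression(
    "GO:0051403", list(rel_expr("occurs_in", "GO:0006915")), rels)
  expect_false(is_satisfiable(bad, ont))
  ok <- conjunction_to_class_expression(
    "GO:0051403", list(rel_expr("occurs_in", "CL:0000540")), rels)
  expect_true(is_satisfiable(ok, ont))
  expect_true(is_satisfiable(ce_named("GO:0005634"), ont))
})

test_that("subsumption queries respect the told hierarchy", {
  astro_nucleus <- conjunction_to_class_expression(
    "GO:0005634", list(rel_expr("part_of", "CL:0000127")), rels)
  glial_nucleus <- conjunction_to_class_expression(
    "GO:0005634", list(rel_expr("part_of", "CL:0000243")), rels)
  expect_true(is_subsumed(astro_nucleus, glial_nucleus, ont))
  expect_false(is_subsumed(glial_nucleus, astro_nucleus, ont))
  expect_true(is_subsumed(astro_nucleus, astro_nucleus, ont))
})

test_that("MSC finds the logically defined term and errors on unsatisfiable input", {
  q <- conjunction_to_class_expression(
    "GO:0014069", list(rel_expr("part_of", "CL:0000127")), rels)
  expect_equal(most_specific_classes(q, ont), "GO:0097483")
  expect_equal(most_specific_classes(ce_named("GO:0097483"), ont),
               "GO:0097483")
  bad <- conjunction_to_class_expression(
    "GO:0051403", list(rel_expr("occurs_in", "GO:0006915")), rels)
  expect_error(most_specific_classes(bad, ont),
               class = "goext_unsatisfiable")
})

test_that("saturation agrees with the brute-force oracle on random ontologies", {
  withr::with_seed(101, {
    for (trial in 1:100) {
      ro <- random_small_ontology()
      idx_main <- classify(ro)
      idx_oracle <- brute_force_subsumption(ro)
      ids <- ro$terms$id
      for (x in ids) {
        expect_identical(named_subsumers(idx_main, x, ids),
                         named_subsumers(idx_oracle, x, ids),
                         info = sprintf("trial %d class %s", trial, x))
      }
      expect_setequal(intersect(idx_main$unsatisfiable, ids),
                      intersect(idx_oracle$unsatisfiable, ids))
    }
  })
})

test_that("query subsumers agree with the brute-force oracle", {
  withr::with_seed(202, {
    for (trial in 1:40) {
      ro <- random_small_ontology()
      q <- random_query(ro)
      idx_main <- classify(ro, queries = list("FRESHQ:q" = query_expr(q)))
      idx_oracle <- brute_force_subsumption(ro, queries = list("FRESHQ:q" = q))
      ids <- ro$terms$id
      expect_identical(named_subsumers(idx_main, "FRESHQ:q", ids),
                       named_subsumers(idx_oracle, "FRESHQ:q", ids),
                       info = sprintf("trial %d", trial))
    }
  })
})

test_that("adding axioms never removes derived subsumptions (monotonicity)", {
  withr::with_seed(303, {
    for (trial in 1:20) {
      ro <- random_small_ontology()
      idx1 <- classify(ro)
      ids <- ro$terms$id
      extra <- data.frame(child = sample(ids, 1L),
                          parent = sample(ids, 1L))
      ro2 <- ro
      ro2$subclass <- rbind(ro2$subclass, extra)
      idx2 <- classify(ro2)
      for (x in ids) {
        expect_true(all(subsumers(idx1, x) %in% subsumers(idx2, x)),
                    info = sprintf("trial %d class %s", trial, x))
      }
    }
  })
})

test_that("saturation is idempotent", {
  withr::with_seed(404, {
    ro <- random_small_ontology()
    idx1 <- classify(ro)
    # feed every derived subsumption back as a told axiom; the closure
    # must not change
    derived <- do.call(rbind, lapply(names(idx1$subsumers), function(x) {
      sups <- setdiff(idx1$subsumers[[x]], c(x, "owl:Nothing"))
      if (length(sups)) data.frame(child = x, parent = sups)
    }))
    derived <- derived[derived$child %in% ro$terms$id &
                         derived$parent %in% ro$terms$id, ]
    ro2 <- ro
    ro2$subclass <- unique(rbind(ro2$subclass, derived))
    idx2 <- classify(ro2)
    for (x in ro$terms$id) {
      expect_setequal(subsumers(idx2, x), subsumers(idx1, x))
    }
  })
})

test_that("cyclic is_a chains collapse into mutual equivalence", {
  cyc <- ontology(
    terms = rbind(term_tbl("A:1"), term_tbl("A:2"), term_tbl("A:3")),
    subclass = data.frame(child = c("A:1", "A:2"),
                          parent = c("A:2", "A:1")))
  idx <- classify(cyc)
  expect_true("A:2" %in% subsumers(idx, "A:1"))
  expect_true("A:1" %in% subsumers(idx, "A:2"))
  expect_length(idx$unsatisfiable, 0L)
})

test_that("the brute-force oracle refuses oversized ontologies", {
  big <- ontology(terms = do.call(rbind, lapply(1:25, function(i) {
    term_tbl(sprintf("T:%03d", i))
  })))
  expect_error(brute_force_subsumption(big), class = "goext_size_error")
})

test_that("the subsumption index dumps as two-column TSV", {
  idx <- classify(fx$cl)
  lines <- dump_subsumptions(idx)
  expect_true(all(grepl("\t", lines)))
  expect_true("CL:0000127\tCL:0000243" %in% lines)
})
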