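# Shared generators for property-style tests.

.test_relations <- builtin_relations()

random_rel_expr <- function(labels = c("part_of", "occurs_in",
                                       "happens_during",
                                       "has_direct_input")) {
  rel_expr(sample(labels, 1L),
           sprintf("%s:%04d", sample(c("CL", "UBERON", "GO", "PomBase"), 1L),
                   sample(9999L, 1L)))
}

random_extension_field <- function(max_alts = 3L, max_conj = 3L) {
  n_alts <- sample(0:max_alts, 1L)
  if (n_alts == 0L) return(extension_field())
  extension_field(lapply(seq_len(n_alts), function(i) {
    lapply(seq_len(sample(max_conj, 1L)), function(j) random_rel_expr())
  }))
}

# Small random EL ontology over the built-in relations: a random is_a DAG,
# a few told relationships, genus-differentia definitions, and sometimes a
# disjointness. Aspects drive the category assignment, exercising the
# range-constraint compilation.
random_small_ontology <- function(n_min = 8L, n_max = 15L) {
  n <- sample(n_min:n_max, 1L)
  ids <- sprintf("T:%03d", seq_len(n))
  terms <- tibble::tibble(
    id = ids, label = ids,
    aspect = sample(c("biological_process", "cellular_component",
                      "external"), n, replace = TRUE),
    obsolete = FALSE
  )
  sc <- NULL
  for (i in 2:n) {
    for (j in sample(seq_len(i - 1L), min(i - 1L, sample(0:2, 1L)))) {
      sc <- rbind(sc, data.frame(child = ids[i], parent = ids[j]))
    }
  }
  rels <- .test_relations[c("part_of", "occurs_in", "regulates",
                            "regulates_occurs_in")]
  rr <- NULL
  for (k in seq_len(sample(0:3, 1L))) {
    rr <- rbind(rr, data.frame(
      child = sample(ids, 1L),
      relation = sample(c("part_of", "occurs_in", "regulates"), 1L),
      filler = sample(ids, 1L)))
  }
  eqs <- list()
  for (k in seq_len(sample(0:2, 1L))) {
    d <- sample(ids, 1L)
    g <- sample(setdiff(ids, d), 1L)
    nd <- sample(1:2, 1L)
    eqs[[length(eqs) + 1L]] <- list(
      defined = d, genus = g,
      differentia = tibble::tibble(
        relation = sample(c("part_of", "occurs_in"), nd, replace = TRUE),
        filler = sample(ids, nd)))
  }
  dj <- NULL
  if (stats::runif(1) < 0.3) {
    dj <- data.frame(a = sample(ids, 1L), b = sample(ids, 1L))
  }
  ontology(terms = terms, relations = rels, subclass = sc,
           relationship = rr, equivalence = eqs, disjoint = dj)
}

# A random flat query over an ontology's terms: genus plus differentia, in
# the form accepted by both the main reasoner (as a class expression) and
# the brute-force oracle.
random_query <- function(ont) {
  ids <- ont$terms$id
  nd <- sample(0:2, 1L)
  diffs <- lapply(seq_len(nd), function(j) {
    rel_expr(sample(c("part_of", "occurs_in"), 1L), sample(ids, 1L))
  })
  list(genus = sample(ids, 1L), diffs = diffs)
}

query_expr <- function(q, relations = .test_relations) {
  conjunction_to_class_expression(q$genus, q$diffs, relations)
}

# Subsumers restricted to the comparable universe (named terms + bottom).
named_subsumers <- function(idx, x, ids) {
  sort(intersect(subsumers(idx, x), c(ids, "owl:Nothing")))
}

# A small clean corpus over the fixture ontologies, for fold/unfold
# round-trip properties.
random_fixture_corpus <- function(n = 6L) {
  goext:::fixture_random_records(n)
}

canonical_conj_string <- function(field) {
  if (n_conjunctions(field) == 0L) return("")
  paste(sort(vapply(field$conjunctions, function(conj) {
    paste(sort(vapply(conj, format, character(1))), collapse = ",")
  }, character(1))), collapse = "|")
}
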