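# Synthetic fixture generation: mini-ontologies, relation typedefs, a
# prefix registry, and a GAF 2.0 corpus.
#
# The fixtures emulate the shape of real curated data at desk scale: a
# three-aspect GO subset, Cell Ontology and Uberon subsets, the built-in
# extension relation set, and an annotation corpus mixing unextended,
# conjunctive and disjunctive records. Three curation vignettes from the
# literature are included verbatim: the fission-yeast Nep1 protease with
# its three deneddylation targets, the rat mAKAP scaffold located on the
# nuclear envelope of fetal cardiomyocytes of the cardiac ventricle, and a
# postsynaptic-density annotation refined with part_of(astrocyte) that
# exercises MSC deepening against the glial-cell postsynaptic density
# logical definition.

fixture_go <- function() {
  terms <- rbind(
    term_tbl("GO:0003674", "molecular_function", "molecular_function"),
    term_tbl("GO:0008150", "biological_process", "biological_process"),
    term_tbl("GO:0005575", "cellular_component", "cellular_component"),
    term_tbl("GO:0008233", "peptidase activity", "molecular_function"),
    term_tbl("GO:0019784", "NEDD8-specific protease activity",
             "molecular_function"),
    term_tbl("GO:0004930", "G protein-coupled receptor activity",
             "molecular_function"),
    term_tbl("GO:0008020", "G protein-coupled photoreceptor activity",
             "molecular_function"),
    term_tbl("GO:0016301", "kinase activity", "molecular_function"),
    term_tbl("GO:0004672", "protein kinase activity", "molecular_function"),
    term_tbl("GO:0008219", "cell death", "biological_process"),
    term_tbl("GO:0006915", "apoptotic process", "biological_process"),
    term_tbl("GO:0006355", "regulation of DNA-templated transcription",
             "biological_process"),
    term_tbl("GO:0006357",
             "regulation of transcription by RNA polymerase II",
             "biological_process"),
    term_tbl("GO:0071470", "cellular response to osmotic stress",
             "biological_process"),
    term_tbl("GO:0051403", "stress-activated MAPK cascade",
             "biological_process"),
    term_tbl("GO:0006470", "protein dephosphorylation",
             "biological_process"),
    term_tbl("GO:0005634", "nucleus", "cellular_component"),
    term_tbl("GO:0005635", "nuclear envelope", "cellular_component"),
    term_tbl("GO:0005739", "mitochondrion", "cellular_component"),
    term_tbl("GO:0014069", "postsynaptic density", "cellular_component"),
    term_tbl("GO:0097483", "glial cell postsynaptic density",
             "cellular_component")
  )
  subclass <- pair_tbl(
    c("GO:0008233", "GO:0019784", "GO:0004930", "GO:0008020", "GO:0016301",
      "GO:0004672", "GO:0008219", "GO:0006915", "GO:0006355", "GO:0006357",
      "GO:0071470", "GO:0051403", "GO:0006470", "GO:0005634", "GO:0005635",
      "GO:0005739", "GO:0014069", "GO:0097483"),
    c("GO:0003674", "GO:0008233", "GO:0003674", "GO:0004930", "GO:0003674",
      "GO:0016301", "GO:0008150", "GO:0008219", "GO:0008150", "GO:0006355",
      "GO:0008150", "GO:0008150", "GO:0008150", "GO:0005575", "GO:0005575",
      "GO:0005575", "GO:0005575", "GO:0014069"),
    cols = c("child", "parent")
  )
  relationship <- pair_tbl(
    "GO:0005635", "part_of", "GO:0005634",
    cols = c("child", "relation", "filler")
  )
  # the glial-cell postsynaptic density logical definition:
  # GO:0097483 = GO:0014069 and part_of some CL:0000243
  equivalence <- list(list(
    defined = "GO:0097483", genus = "GO:0014069",
    differentia = tibble::tibble(relation = "part_of",
                                 filler = "CL:0000243")
  ))
  ontology(terms = terms, subclass = subclass, relationship = relationship,
           equivalence = equivalence)
}

fixture_cl <- function() {
  terms <- rbind(
    term_tbl("CL:0000000", "cell"),
    term_tbl("CL:0000540", "neuron"),
    term_tbl("CL:0000243", "glial cell"),
    term_tbl("CL:0000127", "astrocyte"),
    term_tbl("CL:0000312", "keratinocyte"),
    term_tbl("CL:0000746", "cardiac muscle cell"),
    term_tbl("CL:0002495", "fetal cardiomyocyte"),
    term_tbl("CL:0000740", "retinal ganglion cell"),
    term_tbl("CL:0000066", "epithelial cell")
  )
  subclass <- pair_tbl(
    c("CL:0000540", "CL:0000243", "CL:0000127", "CL:0000312", "CL:0000746",
      "CL:0002495", "CL:0000740", "CL:0000066"),
    c("CL:0000000", "CL:0000000", "CL:0000243", "CL:0000066", "CL:0000000",
      "CL:0000746", "CL:0000540", "CL:0000000"),
    cols = c("child", "parent")
  )
  ontology(terms = terms, subclass = subclass)
}

fixture_uberon <- function() {
  terms <- rbind(
    term_tbl("UBERON:0000465", "material anatomical entity"),
    term_tbl("UBERON:0000948", "heart"),
    term_tbl("UBERON:0002082", "cardiac ventricle"),
    term_tbl("UBERON:0000955", "brain"),
    term_tbl("UBERON:0002421", "hippocampal formation")
  )
  subclass <- pair_tbl(
    c("UBERON:0000948", "UBERON:0002082", "UBERON:0000955",
      "UBERON:0002421"),
    c("UBERON:0000465", "UBERON:0000465", "UBERON:0000465",
      "UBERON:0000955"),
    cols = c("child", "parent")
  )
  relationship <- pair_tbl(
    c("UBERON:0002082", "UBERON:0002421"),
    c("part_of", "part_of"),
    c("UBERON:0000948", "UBERON:0000955"),
    cols = c("child", "relation", "filler")
  )
  ontology(terms = terms, subclass = subclass, relationship = relationship)
}

fixture_registry <- function() {
  id_registry(
    c("GO", "CL", "UBERON", "PO", "CHEBI", "UniProtKB", "PomBase", "SGD",
      "MGI", "RGD", "WB", "WBbt", "FB", "TAIR", "dictyBase", "EcoCyc"),
    c("Gene Ontology", "Cell Ontology", "Uber anatomy ontology",
      "Plant Ontology", "Chemical Entities of Biological Interest",
      "Universal Protein Knowledgebase", "S. pombe database",
      "Saccharomyces Genome Database", "Mouse Genome Informatics",
      "Rat Genome Database", "WormBase", "C. elegans gross anatomy",
      "FlyBase", "The Arabidopsis Information Resource",
      "dictyBase", "Encyclopedia of E. coli genes and metabolism")
  )
}

# the three curation worked examples, verbatim
fixture_worked_examples <- function() {
  bind_records(list(
    gaf_record(db = "PomBase", db_object_id = "SPBC17D11.06",
               db_object_symbol = "nep1", go_id = "GO:0019784",
               db_reference = "PMID:18826954", evidence_code = "IMP",
               aspect = "F", taxon = "taxon:4896", date = "20140210",
               assigned_by = "PomBase",
               annotation_extension = paste0(
                 "has_direct_input(PomBase:SPAC17G6.12),",
                 "has_direct_input(PomBase:SPAC24H6.03),",
                 "has_direct_input(PomBase:SPAC3A11.08)")),
    gaf_record(db = "RGD", db_object_id = "621870",
               db_object_symbol = "Akap6", go_id = "GO:0005635",
               db_reference = "PMID:15935150", evidence_code = "IDA",
               aspect = "C", taxon = "taxon:10116", date = "20130507",
               assigned_by = "BHF-UCL",
               annotation_extension =
                 "part_of(CL:0002495),part_of(UBERON:0002082)"),
    gaf_record(db = "MGI", db_object_id = "MGI:1277959",
               db_object_symbol = "Dlg4", go_id = "GO:0014069",
               db_reference = "PMID:20382076", evidence_code = "IDA",
               aspect = "C", taxon = "taxon:10090", date = "20130911",
               assigned_by = "MGI",
               annotation_extension = "part_of(CL:0000127)"),
    gaf_record(db = "MGI", db_object_id = "MGI:1353425",
               db_object_symbol = "Opn4", go_id = "GO:0008020",
               db_reference = "PMID:15190009", evidence_code = "IDA",
               aspect = "F", taxon = "taxon:10090", date = "20121120",
               assigned_by = "MGI",
               annotation_extension =
                 "occurs_in(CL:0000740)|occurs_in(CL:0000540)"),
    gaf_record(db = "PomBase", db_object_id = "SPAC24B11.06c",
               db_object_symbol = "wis4", go_id = "GO:0051403",
               db_reference = "PMID:8654926", evidence_code = "IMP",
               aspect = "P", taxon = "taxon:4896", date = "20130218",
               assigned_by = "PomBase",
               annotation_extension = "happens_during(GO:0071470)"),
    # unextended records, one carrying a NOT qualifier
    gaf_record(db = "PomBase", db_object_id = "SPBC17D11.06",
               db_object_symbol = "nep1", go_id = "GO:0005634",
               db_reference = "PMID:18826954", evidence_code = "IDA",
               aspect = "C", taxon = "taxon:4896", date = "20140210",
               assigned_by = "PomBase"),
    gaf_record(db = "MGI", db_object_id = "MGI:1277959",
               db_object_symbol = "Dlg4", qualifier = "NOT",
               go_id = "GO:0005739", db_reference = "PMID:20382076",
               evidence_code = "IDA", aspect = "C", taxon = "taxon:10090",
               date = "20130911", assigned_by = "MGI")
  ))
}

# seeded random records drawn from the fixture term pools; extensions are
# constructed to be clean under validate_annotations()
fixture_random_records <- function(n) {
  terms <- list(
    list(go = "GO:0004672", aspect = "F"),
    list(go = "GO:0019784", aspect = "F"),
    list(go = "GO:0008020", aspect = "F"),
    list(go = "GO:0005634", aspect = "C"),
    list(go = "GO:0005739", aspect = "C"),
    list(go = "GO:0014069", aspect = "C"),
    list(go = "GO:0006357", aspect = "P"),
    list(go = "GO:0051403", aspect = "P"),
    list(go = "GO:0006470", aspect = "P")
  )
  cl_pool <- c("CL:0000540", "CL:0000243", "CL:0000127", "CL:0000312",
               "CL:0002495", "CL:0000740", "CL:0000066")
  ub_pool <- c("UBERON:0000948", "UBERON:0002082", "UBERON:0000955",
               "UBERON:0002421")
  bp_pool <- c("GO:0071470", "GO:0006915", "GO:0051403")
  gp_pool <- sprintf("PomBase:SPAC%02d.%02d", 1:20, 21:40)
  dbs <- c("PomBase", "MGI", "RGD", "UniProtKB")
  taxa <- c(PomBase = "taxon:4896", MGI = "taxon:10090",
            RGD = "taxon:10116", UniProtKB = "taxon:9606")

  sample_expr <- function(term) {
    kind <- sample(c("part_of", "occurs_in", "happens_during",
                     "has_direct_input", "has_input"), 1L)
    if (term$aspect == "C" && kind != "part_of") kind <- "part_of"
    if (term$aspect != "P" && kind == "happens_during") kind <- "occurs_in"
    filler <- switch(kind,
      part_of = sample(c(cl_pool, ub_pool), 1L),
      occurs_in = sample(cl_pool, 1L),
      happens_during = sample(bp_pool, 1L),
      sample(gp_pool, 1L))
    rel_expr(kind, filler)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    term <- terms[[sample(length(terms), 1L)]]
    db <- sample(dbs, 1L)
    kind <- sample(c("plain", "plain", "conj", "conj", "disj"), 1L)
    ext <- ""
    if (kind != "plain") {
      e1 <- sample_expr(term)
      if (kind == "conj") {
        k <- sample(1:2, 1L)
        conj <- list(e1)
        if (k == 2L) {
          e2 <- sample_expr(term)
          if (format(e2) != format(e1)) conj <- c(conj, list(e2))
        }
        ext <- serialize_extension_field(extension_field(list(conj)))
      } else {
        e2 <- sample_expr(term)
        f <- if (format(e2) == format(e1)) {
          extension_field(list(list(e1)))
        } else {
          extension_field(list(list(e1), list(e2)))
        }
        ext <- serialize_extension_field(f)
      }
    }
    rows[[i]] <- gaf_record(
      db = db,
      db_object_id = sprintf("%s%04d", if (db == "UniProtKB") "P" else "G",
                             sample(9999L, 1L)),
      db_object_symbol = sprintf("gene%03d", i),
      go_id = term$go, db_reference = sprintf("PMID:%d", sample(1e7L, 1L)),
      evidence_code = sample(c("IDA", "IMP", "IGI"), 1L),
      aspect = term$aspect, taxon = taxa[[db]],
      date = "20140101", assigned_by = db,
      annotation_extension = ext)
  }
  bind_records(rows)
}

#' Generate the synthetic fixture bundle
#'
#' Deterministically (per seed) builds the mini-GO, mini-CL and mini-Uberon
#' ontologies, the built-in relation set serialized as an OBO typedef file,
#' a prefix registry, and a GAF 2.0 corpus containing the worked curation
#' examples verbatim (Nep1 deneddylation targets, mAKAP locational context,
#' postsynaptic density + astrocyte, a disjunctive photoreceptor-activity
#' record) followed by seeded random extended, unextended, conjunctive and
#' disjunctive records. The same seed yields byte-identical outputs.
#'
#' @param seed integer RNG seed.
#' @param size `"small"` (~30 records) or `"medium"` (~120 records).
#' @return an object of class `goext_fixtures`: the component ontologies,
#'   the merged reasoning ontology, relations, registry, the record tibble,
#'   and the serialized artifacts (`gaf`, `gpad`, `obo$go/cl/uberon`,
#'   `relations_obo`, `registry_tsv`).
#' @export
#' @examples
#' fx <- generate_fixtures(seed = 1)
#' nrow(fx$records)
generate_fixtures <- function(seed = 1L, size = c("small", "medium")) {
  size <- match.arg(size)
  go <- fixture_go()
  cl <- fixture_cl()
  ub <- fixture_uberon()
  relations <- builtin_relations()
  merged <- merge_ontologies(go, cl, ub)
  merged$relations <- relations
  registry <- fixture_registry()

  records <- withr::with_seed(seed, {
    bind_records(fixture_worked_examples(),
                 fixture_random_records(if (size == "small") 24L else 120L))
  })

  rel_ont <- ontology(relations = relations)
  structure(list(
    go = go, cl = cl, uberon = ub, ontology = merged,
    relations = relations, registry = registry, records = records,
    gaf = write_gaf(records),
    gpad = write_gpad(records),
    obo = list(go = write_obo(go), cl = write_obo(cl),
               uberon = write_obo(ub)),
    relations_obo = write_obo(rel_ont),
    registry_tsv = write_registry(registry),
    seed = seed, size = size
  ), class = "goext_fixtures")
}

#' @export
print.goext_fixtures <- function(x, ...) {
  cat(sprintf("<goext_fixtures: seed %d, %s; %d records, %d GO terms>\n",
              x$seed, x$size, nrow(x$records), nrow(x$go$terms)))
  invisible(x)
}

#' Write a fixture bundle to disk
#'
#' @param fixtures output of [generate_fixtures()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixtures <- function(fixtures, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(fixtures$obo$go, file.path(dir, "go-subset.obo"))
  writeLines(fixtures$obo$cl, file.path(dir, "cl-subset.obo"))
  writeLines(fixtures$obo$uberon, file.path(dir, "uberon-subset.obo"))
  writeLines(fixtures$relations_obo, file.path(dir, "relations.obo"))
  writeLines(fixtures$registry_tsv, file.path(dir, "registry.tsv"))
  writeLines(fixtures$gaf, file.path(dir, "corpus.gaf"))
  writeLines(fixtures$gpad, file.path(dir, "corpus.gpad"))
  invisible(dir)
}
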