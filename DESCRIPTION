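Package: goext
Title: Gene Ontology Annotation Extensions: Parsing, Reasoning, Folding and Deepening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with Gene Ontology (GO) annotation extensions:
    the Relation(Entity) expressions placed in column 16 of GAF 2.0 files and
    column 11 of GPAD files that refine a basic gene-product-to-GO-term
    association with effector targets and cellular, anatomical or temporal
    context. Provides readers and writers for GAF 2.0/1.0 and GPAD, a parser
    and serializer for the extension grammar, an OBO-subset ontology reader
    with genus-differentia logical definitions, translation of extended
    annotations to EL-profile OWL class expressions (including property-chain
    relations such as regulates_occurs_in), a polynomial-time EL completion
    reasoner with an independent brute-force oracle, and the annotation
    folding, unfolding, validation and deepening procedures that interconvert
    pre-composed ontology terms and post-composed extended annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tibble,
    withr,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
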