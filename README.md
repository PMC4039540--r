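# goext

Tools for Gene Ontology **annotation extensions** — the `Relation(Entity)`
expressions in column 16 of GAF 2.0 files (column 11 of GPAD) that refine a
basic gene-product-to-GO-term association with the targets of an activity
and its cellular, anatomical or temporal context.

The package is aimed at annotation-pipeline developers and curation-QC
engineers who need to parse, check, and logically transform extended
annotations: GO Consortium member groups producing extended GAFs,
downstream tool authors who want to fold extensions into pre-composed
terms before term enrichment, and ontology engineers working with
genus–differentia logical definitions.

## The model

An extended annotation to a term *t* with extension conjunction
*e = r1(f1), …, rk(fk)* denotes the EL-profile OWL class expression

```
t ⊓ ∃p1.f1 ⊓ … ⊓ ∃pk.fk
```

where *pi* is the object property behind relation label *ri* (e.g.
`part_of` → `BFO:0000050`). The comma is conjunction; the pipe is
disjunction and is equivalent to multiple independent annotations.
Chain-defined relations expand to nested existentials
(`regulates_occurs_in(c)` ⇔ `∃regulates.∃occurs_in.c`). Everything stays
inside EL++, so classification is polynomial, and the package ships a
small EL completion reasoner plus an independent brute-force oracle used
to cross-check it in the tests.

On top of the reasoner sit the four corpus operations:

* **fold** — materialize each distinct (t, e) as a term `t^A ≡ t ⊓ e` in an
  application ontology, classify it, and rewrite records to basic
  annotations;
* **unfold** — the inverse: rewrite an annotation to a logically defined
  term as its genus plus the differentia in the extension field;
* **validate** — grammar, relation-existence, identifier-prefix, usage
  (aspect/filler), satisfiability and duplicate checks, returned as a
  report table;
* **deepen** — move an annotation to the Most Specific Class entailed by
  its translated expression (e.g. *postsynaptic density* +
  `part_of(astrocyte)` deepens to *glial cell postsynaptic density* via
  the equivalence axiom and `astrocyte ⊑ glial cell`).

## Worked example

```r
library(goext)
fx <- generate_fixtures(seed = 1)   # mini-GO/CL/Uberon + GAF corpus

# the fission-yeast Nep1 protease: one annotation, three substrates
fx$records$extension[[1]]
#> <extension_field: 1 conjunction(s), 3 expression(s)>
#>   has_direct_input(PomBase:SPAC17G6.12),has_direct_input(PomBase:SPAC24H6.03),has_direct_input(PomBase:SPAC3A11.08)

# the rat mAKAP record: nuclear envelope in fetal cardiomyocytes of the
# cardiac ventricle, as an OWL class expression
f <- parse_extension_field("part_of(CL:0002495),part_of(UBERON:0002082)")
render_owl(conjunction_to_class_expression("GO:0005635", f$conjunctions[[1]]))
#> [1] "GO_0005635 and (BFO_0000050 some CL_0002495) and (BFO_0000050 some UBERON_0002082)"

# fold the corpus into an application ontology
res <- fold(fx$records, fx$ontology)
res
#> <fold_result: 34 records, 22 folded terms (0 unsatisfiable)>
head(res$mapping, 3)
#> # A tibble: 3 × 4
#>   folded_id    source_term expression                              unsatisfiable
#> 1 GOX:35E8FDE8 GO:0019784  has_direct_input(PomBase:SPAC17G6.12),… FALSE
#> 2 GOX:5E3D8DF9 GO:0005635  part_of(CL:0002495),part_of(UBERON:000… FALSE
#> 3 GOX:25531259 GO:0014069  part_of(CL:0000127)                     FALSE

# MSC deepening: postsynaptic density + part_of(astrocyte)
rec <- gaf_record(db = "MGI", db_object_id = "Dlg4", go_id = "GO:0014069",
                  aspect = "C", annotation_extension = "part_of(CL:0000127)")
deepen(rec, fx$ontology)$go_id
#> [1] "GO:0097483"
```

The 34 fold-result records are the 31 corpus records after splitting one
disjunctive extension and expanding others; the 22 folded terms are the
distinct (term, conjunction) pairs. The deepened record lands on the
glial-cell postsynaptic-density term because an astrocyte is a glial
cell; its `part_of(CL:0000127)` extension is retained since the astrocyte
detail is strictly more specific than the new term's definition.

A thin command-line interface is installed at
`system.file("cli", "goext.R", package = "goext")` with subcommands
`parse`, `validate`, `fold`, `unfold`, `deepen`, `stats` and `fixtures`
(exit codes: 0 clean, 1 findings, 2 I/O failure).

See `vignettes/annotation-extensions.Rmd` for the full account of the
model, the reasoner's completion rules and range-constraint compilation,
and the design decisions behind folding, unfolding and deepening.

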