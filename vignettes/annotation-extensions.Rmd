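---
title: "Annotation extensions: model, reasoning, and the folding procedures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation extensions: model, reasoning, and the folding procedures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goext)
```

## The annotation-extension model

A basic Gene Ontology annotation is a pair: a gene product and a GO term,
plus evidence metadata. That model cannot say *which* substrate a protease
acts on, or *in which cell type* a component is found. Annotation
extensions add that context as a list of `Relation(Entity)` expressions
attached to the annotation: `part_of(CL:0000312)` combined with the term
*nucleus* describes a keratinocyte nucleus; three
`has_direct_input(PomBase:...)` expressions on a protease-activity
annotation name its three substrates.

Within the exchange formats, the extension occupies one optional field:
1-based column 16 of GAF 2.0 and column 11 of GPAD. Its grammar is

```
Field ::= Conj ('|' Conj)*
Conj  ::= Rel '(' Entity ')' (',' Rel '(' Entity ')')*
```

where the comma is conjunction (all expressions refine the term at once)
and the pipe is disjunction — shorthand for multiple independent
annotations, which `split_disjunction()` makes explicit. Parentheses never
nest; `parse_extension_field()` rejects nesting with a character offset so
the grammar can grow nesting later without silently changing meaning
today. Whitespace after separators is tolerated on input and never
emitted, relation labels are case-sensitive (they are ontology
identifiers), and duplicate expressions inside a conjunction are preserved
by the parser and reported by validation as a warning rather than an
error, since they are redundant but not wrong.

## Formal semantics

An extended annotation denotes an OWL class expression in the EL profile:
the conjunction `t, [r1(f1), ..., rk(fk)]` translates to

```
t and (p1 some f1) and ... and (pk some fk)
```

with `pi` the object property behind relation `ri`
(`conjunction_to_class_expression()`). Entities — including gene products —
are modeled as classes, not individuals. Relations defined by a binary
property chain, such as `regulates_occurs_in = regulates o occurs_in`,
expand to a nested existential `regulates some (occurs_in some f)` and are
re-folded to the chain label on the way back
(`class_expression_to_conjunction()`). The profile deliberately stops
there: no negation, union, or universal quantification, which keeps
classification polynomial.

`render_owl()` prints expressions in underscore-identifier Manchester
style, e.g. for the mAKAP worked example:

```{r}
f <- parse_extension_field("part_of(CL:0002495),part_of(UBERON:0002082)")
render_owl(conjunction_to_class_expression("GO:0005635",
                                           f$conjunctions[[1]]))
```

Relations lacking a published property identifier render under a reserved
`GOREL_` namespace so that every expression has a deterministic text form.

## The relation set and its usage metadata

`builtin_relations()` provides the common extension relations in two broad
groups: contextual relations (`part_of`, `occurs_in`, `happens_during`)
whose fillers are cells, anatomical parts, stages or GO terms, and
molecular relations (`has_input`, `has_direct_input`,
`has_regulation_target`) whose fillers are gene products or chemicals.
Each `relation_def()` carries:

* `allowed_aspects` — which GO aspects the primary term may have
  (`occurs_in` makes no sense on a cellular-component annotation);
* `allowed_fillers` — ID-prefix constraints (e.g. `CL`) and/or
  required-ancestor classes (e.g. `CL:0000000`), checked against the
  registry and the classification respectively;
* `range_category` — `continuant` or `occurrent`, the upper-level category
  the filler must belong to;
* `chain` — the defining property chain, if any (length 0 or ≥ 2; chains
  longer than two are rejected, as every composite relation in scope is
  binary).

A relations file in OBO typedef form is also read by `parse_obo()`. Usage
metadata rides on standard tags: `xref` carries the object-property CURIE,
`domain` the allowed aspects, and `range` either a category keyword or a
filler constraint (CURIE = ancestor class, bare token = prefix). This
keeps the file parseable by generic OBO tooling while round-tripping
through `write_obo()`.

## The EL reasoner

`normalize_axioms()` compiles an ontology — is_a links, told
relationships, genus–differentia equivalence axioms from
`intersection_of` blocks, disjointness axioms — plus any query expressions
into the standard EL normal forms (atomic subsumptions, binary
conjunctions, left/right existentials, role chains). Every complex
expression is replaced by a fresh name with definitional axioms in both
directions; fresh names are numbered sequentially in input order, so a
given input always normalizes identically. `saturate()` then runs the EL
completion rules to a fixed point and returns a `subsumption_index`:
per-class subsumer sets (reflexive, transitively closed) and the set of
unsatisfiable classes.

Two design choices are worth spelling out:

* **Ranges as axioms.** "The range of `occurs_in` is a continuant" is
  compiled to `(occurs_in some Occurrent) SubClassOf Nothing`, supported
  by per-class category assignments (biological processes and molecular
  functions are occurrents; components, cells, anatomical parts and
  chemicals are continuants — derivable from aspect and identifier prefix,
  overridable per class) plus the Continuant/Occurrent disjointness. This
  is what makes `occurs_in(<apoptotic process>)` come out unsatisfiable
  with no special-case code.
* **Cycles are fine.** Cyclic is_a chains collapse into mutual
  equivalence, as EL semantics prescribe, rather than erroring.

`is_subsumed()`, `is_satisfiable()` and `most_specific_classes()` are thin
query wrappers; the MSC operation returns the *minimal* named, non-fresh,
non-obsolete classes above a query expression, with incomparable minima
all returned.

Because the reasoner is the load-bearing component, the package also ships
`brute_force_subsumption()`: a naive fixpoint engine over the
*unnormalized* axioms, written independently (no normal forms, no fresh
names), capped at 20 classes. The test suite and the acceptance script
compare the two engines on 100 random ontologies per run; they must agree
exactly on subsumer sets and unsatisfiable classes. The oracle is a test
instrument, never the implementation.

## Folding, unfolding, deepening

**Folding** (`fold()`) rewrites each extended annotation `(t, e)` to a
basic annotation to a materialized term `t^A` with the axiom
`t^A EquivalentTo (t and e)` in an application ontology, which is then
classified so `t^A` sits under all its entailed superclasses (at minimum
`t`). Folded-term ids are content-addressed — a stable hash of the source
term plus the canonicalized (sorted) expression — so repeated runs and
merged corpora agree without coordination; labels are generated as
`"<source label> [relation filler, ...]"` for human browsing. Records that
become identical after rewriting are kept distinct: folding changes the
vocabulary, not the corpus cardinality (after disjunction splitting).
An unsatisfiable folded term is retained and flagged rather than dropped,
so the defect stays visible downstream.

**Unfolding** (`unfold()`) is the inverse: an annotation to a term with an
eligible logical definition `t = t' and e` (GO-prefixed genus, same
aspect, differentia within the extension profile) becomes an annotation to
`t'` with `e` merged conjunctively into the extension. One rewrite step is
the default — that is the granularity change a data consumer asks for —
with `recursive = TRUE` iterating to a fixed point for fully primitive
output. When a term has several eligible definitions the first in
ontology order is used, with a warning entry, so output is deterministic.
Fold followed by unfold reproduces the corpus up to conjunct order; this
round trip is property-tested on generated corpora.

**Validation** (`validate_annotations()`) applies the checks in a fixed
order per record — grammar, relation existence, registry prefix, usage
(aspect and filler), satisfiability of the translated expression,
duplicates — and returns all findings as report rows rather than raising.
Severities mirror the difference between hard logical incoherence and
curation-guideline breaches: grammar, unknown-relation, prefix and
unsatisfiability findings are errors; usage and duplicate findings are
warnings.

**Deepening** (`deepen()`) computes the MSC of each record's translated
expression and moves the annotation down when a unique MSC strictly below
the current term exists. If the MSC is logically *equivalent* to the whole
expression, the extension has been fully absorbed into the new term and is
dropped; otherwise it is retained, because it still carries information
the new term does not entail. The postsynaptic-density example
illustrates both sides: with `part_of(<glial cell>)` the record moves to
the glial-cell postsynaptic-density term and the extension is dropped
(exact match with the term's definition); with `part_of(<astrocyte>)` the
record moves to the same term but keeps its extension, since an astrocyte
is a *kind* of glial cell and the cell-type detail would otherwise be
lost. Deepening is idempotent by construction: the deepened record's
expression is equivalent to the original one, so a second pass finds the
same MSC.

NOT-qualified records are excluded from folding, unfolding and deepening
and pass through with a warning. Negation over a conjunction is not the
conjunction of negations, so rewriting a NOT annotation by any of these
procedures would change its meaning; the records still travel intact
through I/O and are validated normally.

## The fixture generator

`generate_fixtures()` builds everything the tests and the command-line
examples need, deterministically per seed: a 21-term three-aspect GO
subset (including the glial-cell postsynaptic-density logical definition),
Cell Ontology and Uberon subsets, the built-in relations as an OBO typedef
file, a 16-prefix registry, and a GAF 2.0 corpus. The corpus opens with
the worked curation examples verbatim — the Nep1 protease with its three
deneddylation targets, the mAKAP record with cell-type and anatomy
context, the postsynaptic-density + astrocyte record, a disjunctive
photoreceptor-activity record — followed by seeded random records
(24 in the `small` size, 120 in `medium`) mixing unextended, conjunctive
and disjunctive extensions drawn so as to be clean under validation.

What the fixtures emulate: the column layout and comment conventions of
real GAF/GPAD, the grammar as curators actually write it, logical
definitions of the genus-differentia form used for GO cross-products, and
category/range interactions. What they do not emulate: full-GO scale (the
reasoner here is quadratic-ish and tested at tens of classes, not tens of
thousands), evidence-code semantics, qualifier vocabularies beyond NOT,
isoform (column 17) semantics, or the messiness of real legacy files
(escaped characters, encoding drift). A green suite therefore demonstrates
correctness of the model and procedures, not performance at consortium
scale.

Problem sizes were chosen so the whole suite runs in about a minute:
100 random ontologies of 8–15 classes for the reasoner/oracle comparison,
100 five-record corpora for the fold/unfold round trip, 200 random fields
for the grammar fixed point, and 25 corpora for deepening idempotence.

## Known limitations and open edges

* The registry check is exact and case-sensitive; no alias table.
* GPAD carries fewer columns than GAF, so GAF→GPAD→GAF restores the
  GAF-only columns (symbol, aspect, taxon, object metadata) as empty; the
  conversion contract is fidelity on all shared columns and verbatim
  extension text.
* Role hierarchies are limited to inclusions plus binary chains; no
  transitive-role or reflexivity axioms.
* Relation subsets (`subset_tags`, e.g. a `chemical` grouping) are carried
  and round-tripped but no canonical subset membership is asserted, since
  none is fixed by the sources the relation file models.
* Folding keeps duplicate rewritten records distinct; merging them is a
  corpus-editing policy, not a logical consequence, and is left to the
  caller.
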