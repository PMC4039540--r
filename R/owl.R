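# EL-profile class expressions and translation to/from extension
# conjunctions.
#
# The extension model is a fragment of EL++: named classes, intersections,
# and existential restrictions ("some values from"), with no negation, union
# or universal quantification. An extension conjunction on a GO term t
# translates to the intersection of t with one existential per expression;
# a chain-defined relation such as regulates_occurs_in expands to a nested
# existential (regulates some (occurs_in some filler)).

#' EL class-expression constructors
#'
#' `ce_named()` wraps a named class, `ce_some()` builds an existential
#' restriction, `ce_intersection()` an intersection (nested intersections
#' are flattened; a single operand is returned as-is), and `ce_bottom()` the
#' unsatisfiable class.
#'
#' @param id class CURIE.
#' @param property object-property CURIE or relation label.
#' @param filler a class expression (or a CURIE, wrapped automatically).
#' @param ... class expressions (or a single list of them).
#' @return an object of class `class_expr`.
#' @export
#' @examples
#' ce_intersection(ce_named("GO:0005635"),
#'                 ce_some("BFO:0000050", "CL:0002495"))
ce_named <- function(id) {
  structure(list(type = "named", id = curie_normalize(id)),
            class = "class_expr")
}

#' @rdname ce_named
#' @export
ce_bottom <- function() structure(list(type = "bottom"), class = "class_expr")

#' @rdname ce_named
#' @export
ce_some <- function(property, filler) {
  if (is.character(filler)) filler <- ce_named(filler)
  if (!inherits(filler, "class_expr")) {
    goext_error("filler must be a class expression", "goext_profile_error")
  }
  structure(list(type = "some", property = property_normalize(property),
                 filler = filler),
            class = "class_expr")
}

#' @rdname ce_named
#' @export
ce_intersection <- function(...) {
  ops <- list(...)
  if (length(ops) == 1L && !inherits(ops[[1]], "class_expr")) {
    ops <- ops[[1]]
  }
  flat <- list()
  for (op in ops) {
    if (!inherits(op, "class_expr")) {
      goext_error("intersection operands must be class expressions",
                  "goext_profile_error")
    }
    if (op$type == "and") flat <- c(flat, op$operands) else
      flat <- c(flat, list(op))
  }
  if (length(flat) == 0L) {
    goext_error("intersection needs at least one operand",
                "goext_profile_error")
  }
  if (length(flat) == 1L) return(flat[[1]])
  structure(list(type = "and", operands = flat), class = "class_expr")
}

#' @export
print.class_expr <- function(x, ...) {
  cat("<class_expr>", render_owl(x), "\n")
  invisible(x)
}

# Property CURIE used when translating a relation: its declared object
# property, else a reserved GOREL identifier built from the label.
relation_property <- function(rd) {
  if (!is.na(rd$property_id)) rd$property_id else paste0("GOREL:", rd$label)
}

lookup_relation <- function(relations, label) {
  rd <- relations[[label]]
  if (is.null(rd)) {
    goext_error(sprintf("unknown extension relation '%s'", label),
                "goext_unknown_relation")
  }
  rd
}

#' Translate an extension conjunction to an EL class expression
#'
#' The conjunction `[r1(f1), ..., rk(fk)]` on GO term `t` becomes
#' `t and (p1 some f1) and ... and (pk some fk)` where `pi` is the object
#' property of relation `ri`; an empty conjunction yields the named term
#' alone. A relation defined by a property chain `[s1, s2]` yields the
#' nested existential `s1 some (s2 some filler)`.
#'
#' @param go_term CURIE of the primary GO term.
#' @param conj a conjunction: list of [rel_expr()] objects (an
#'   [extension_field()] with exactly one conjunction is also accepted).
#' @param relations named list of [relation_def()] objects.
#' @return a class expression.
#' @export
conjunction_to_class_expression <- function(go_term, conj,
                                            relations = builtin_relations()) {
  if (inherits(conj, "extension_field")) {
    if (n_conjunctions(conj) > 1L) {
      goext_error("field has multiple conjunctions; split the disjunction first",
                  "goext_profile_error")
    }
    conj <- if (n_conjunctions(conj) == 1L) conj$conjunctions[[1]] else list()
  }
  if (length(conj) == 0L) return(ce_named(go_term))
  parts <- lapply(conj, function(e) {
    rd <- lookup_relation(relations, e$relation)
    if (length(rd$chain) >= 2L) {
      expr <- ce_named(e$entity)
      for (lab in rev(rd$chain)) {
        link <- lookup_relation(relations, lab)
        expr <- ce_some(relation_property(link), expr)
      }
      expr
    } else {
      ce_some(relation_property(rd), ce_named(e$entity))
    }
  })
  ce_intersection(c(list(ce_named(go_term)), parts))
}

# Reverse map: property CURIE (and label) -> relation label. Chain-defined
# relations are excluded from the direct map since they never appear as a
# property in translated output.
property_label_map <- function(relations) {
  map <- character(0)
  for (rd in relations) {
    if (length(rd$chain) == 0L) {
      map[relation_property(rd)] <- rd$label
      map[rd$label] <- rd$label
    }
  }
  map
}

find_chain_relation <- function(relations, labels) {
  for (rd in relations) {
    if (length(rd$chain) == length(labels) &&
        all(rd$chain == labels)) return(rd$label)
  }
  NULL
}

#' Translate an EL class expression back to an extension conjunction
#'
#' Inverse of [conjunction_to_class_expression()] on the extension profile:
#' the expression must be a bare GO-prefixed named class, or an intersection
#' of exactly one GO-prefixed named class with existential restrictions over
#' named fillers. A two-deep nested existential whose property pair matches
#' a declared chain relation is re-folded to that relation's label; anything
#' else outside the profile raises a not-expressible error.
#'
#' @param expr a class expression.
#' @param relations named list of [relation_def()] objects.
#' @return `list(go_term =, conjunction =)` where `conjunction` is a list of
#'   [rel_expr()] objects.
#' @export
class_expression_to_conjunction <- function(expr,
                                            relations = builtin_relations()) {
  map <- property_label_map(relations)
  not_expressible <- function(why) {
    goext_error(paste0("expression is outside the extension profile: ", why),
                "goext_not_expressible")
  }
  label_of <- function(property) {
    lab <- map[property]
    if (is.na(lab)) not_expressible(
      sprintf("no extension relation for property '%s'", property))
    unname(lab)
  }
  if (expr$type == "named") {
    if (curie_prefix(expr$id) != "GO") {
      not_expressible("primary class is not a GO term")
    }
    return(list(go_term = expr$id, conjunction = list()))
  }
  if (expr$type != "and") not_expressible("not a named class or intersection")
  named <- Filter(function(op) op$type == "named", expr$operands)
  go_named <- Filter(function(op) curie_prefix(op$id) == "GO", named)
  if (length(go_named) != 1L || length(named) != length(go_named)) {
    not_expressible("expected exactly one named operand, a GO term")
  }
  rest <- Filter(function(op) op$type != "named", expr$operands)
  conj <- lapply(rest, function(op) {
    if (op$type != "some") not_expressible("operand is not an existential")
    if (op$filler$type == "named") {
      rel_expr(label_of(op$property), op$filler$id)
    } else if (op$filler$type == "some" &&
               op$filler$filler$type == "named") {
      labels <- c(label_of(op$property), label_of(op$filler$property))
      chain_lab <- find_chain_relation(relations, labels)
      if (is.null(chain_lab)) {
        not_expressible(sprintf("no chain relation declared for %s o %s",
                                labels[1], labels[2]))
      }
      rel_expr(chain_lab, op$filler$filler$id)
    } else {
      not_expressible("existential nesting deeper than a declared chain")
    }
  })
  list(go_term = go_named[[1]]$id, conjunction = conj)
}

#' Render a class expression as OWL Manchester-style text
#'
#' Identifiers are written in underscore form, intersection operands are
#' joined by `" and "` with every non-leading conjunct parenthesized, and
#' existentials are written `"P some F"` (complex fillers parenthesized).
#' The output is deterministic given the expression.
#'
#' @param expr a class expression.
#' @return a single character string, e.g.
#'   `"GO_0005635 and (BFO_0000050 some CL_0002495) and (BFO_0000050 some UBERON_0002082)"`.
#' @export
render_owl <- function(expr) {
  render <- function(e) {
    switch(e$type,
      named = curie_underscore(e$id),
      bottom = "owl:Nothing",
      some = paste(curie_underscore(e$property), "some",
                   if (e$filler$type == "named") render(e$filler)
                   else paste0("(", render(e$filler), ")")),
      "and" = {
        parts <- vapply(e$operands, render, character(1))
        paste(c(parts[1], paste0("(", parts[-1], ")")), collapse = " and ")
      },
      goext_error("unknown expression type", "goext_profile_error"))
  }
  render(expr)
}
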