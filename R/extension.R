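# The Relation(Entity) annotation-extension grammar.
#
# An extension field is a disjunction (pipe-separated) of conjunctions
# (comma-separated) of relational expressions, each written Relation(Entity).
# A disjunction is equivalent to multiple independent annotations; a
# conjunction refines the primary GO term with every expression at once.
# Nesting of parentheses is not part of the grammar and is rejected.

#' Relational expression
#'
#' A single `Relation(Entity)` pair: a relation label from the extension
#' relations ontology and a `DB:ID` entity identifier (ontology term or
#' gene-product accession).
#'
#' @param relation relation label, e.g. `"part_of"`. Case-sensitive.
#' @param entity entity CURIE, e.g. `"CL:0000312"`. The underscore form is
#'   accepted and normalized.
#' @return an object of class `rel_expr`.
#' @export
#' @examples
#' rel_expr("part_of", "CL:0000312")
rel_expr <- function(relation, entity) {
  relation <- trimws(relation)
  if (!nzchar(relation)) {
    goext_error("relation label must be non-empty", "goext_syntax_error")
  }
  entity <- curie_normalize(trimws(entity))
  if (!is_curie(entity)) {
    goext_error(
      sprintf("malformed entity identifier '%s' (expected DB:ID)", entity),
      "goext_malformed_entity"
    )
  }
  structure(list(relation = relation, entity = entity), class = "rel_expr")
}

#' @export
format.rel_expr <- function(x, ...) paste0(x$relation, "(", x$entity, ")")

#' @export
print.rel_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Extension field
#'
#' Container for the parsed content of GAF column 16 / GPAD column 11: an
#' ordered list of conjunctions, each an ordered list of [rel_expr()]
#' objects. An empty field (zero conjunctions) is an unextended annotation.
#'
#' @param conjunctions list of conjunctions; each conjunction is a non-empty
#'   list of `rel_expr` objects.
#' @return an object of class `extension_field`.
#' @export
extension_field <- function(conjunctions = list()) {
  for (conj in conjunctions) {
    if (length(conj) == 0L) {
      goext_error("a conjunction must contain at least one expression",
                  "goext_syntax_error")
    }
    for (e in conj) {
      if (!inherits(e, "rel_expr")) {
        goext_error("conjunction elements must be rel_expr objects",
                    "goext_syntax_error")
      }
    }
  }
  structure(list(conjunctions = conjunctions), class = "extension_field")
}

#' Number of conjunctions / expressions in an extension field
#' @param field an [extension_field()].
#' @return integer count.
#' @export
n_conjunctions <- function(field) length(field$conjunctions)

#' @rdname n_conjunctions
#' @export
n_expressions <- function(field) {
  sum(vapply(field$conjunctions, length, integer(1)))
}

ext_is_empty <- function(field) {
  is.null(field) || length(field$conjunctions) == 0L
}

parse_rel_expr <- function(token) {
  m <- regmatches(token,
                  regexec("^\\s*([^(),|]+?)\\s*\\(\\s*([^(),|]+?)\\s*\\)\\s*$",
                          token))[[1]]
  if (length(m) != 3L) {
    goext_error(
      sprintf("cannot parse relational expression '%s' (expected Relation(Entity))",
              trimws(token)),
      "goext_syntax_error"
    )
  }
  rel_expr(m[2], m[3])
}

#' Parse an annotation-extension field
#'
#' Parses the text of GAF column 16 (or GPAD column 11) into an
#' [extension_field()]. The pipe character separates alternatives
#' (disjunction, OR); the comma separates expressions within an alternative
#' (conjunction, AND). Whitespace around separators is tolerated on input and
#' never emitted by [serialize_extension_field()]. Nested parentheses are a
#' syntax error: the grammar reserves nesting for future use.
#'
#' @param text a single field value (no tabs). `""` or `NA` yields an empty
#'   field, i.e. an unextended annotation.
#' @return an [extension_field()].
#' @export
#' @examples
#' f <- parse_extension_field("part_of(CL:0002495),part_of(UBERON:0002082)")
#' n_conjunctions(f)  # 1
#' n_expressions(f)   # 2
parse_extension_field <- function(text) {
  if (length(text) != 1L) {
    goext_error("parse_extension_field() expects a single field value",
                "goext_syntax_error")
  }
  if (is.na(text)) text <- ""
  if (!nzchar(trimws(text))) return(extension_field())
  if (grepl("\t", text, fixed = TRUE)) {
    goext_error("extension field must not contain tab characters",
                "goext_syntax_error")
  }

  # Parenthesis discipline: balanced, never nested.
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      depth <- depth + 1L
      if (depth > 1L) {
        goext_error(sprintf("nested parenthesis at character %d", i),
                    "goext_syntax_error")
      }
    } else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        goext_error(sprintf("unbalanced ')' at character %d", i),
                    "goext_syntax_error")
      }
    }
  }
  if (depth != 0L) {
    goext_error(sprintf("unbalanced '(' (still open at character %d)",
                        nchar(text)),
                "goext_syntax_error")
  }

  if (grepl("(^\\s*\\|)|(\\|\\s*$)|(\\|\\s*\\|)", text)) {
    goext_error("empty alternative between '|' separators",
                "goext_syntax_error")
  }
  alternatives <- strsplit(text, "|", fixed = TRUE)[[1]]
  conjunctions <- lapply(alternatives, function(alt) {
    if (grepl("(^\\s*,)|(,\\s*$)|(,\\s*,)", alt)) {
      goext_error("empty conjunct between ',' separators",
                  "goext_syntax_error")
    }
    lapply(strsplit(alt, ",", fixed = TRUE)[[1]], parse_rel_expr)
  })
  extension_field(conjunctions)
}

#' Serialize an extension field to its canonical text form
#'
#' Conjuncts are joined by `","` with no spaces and alternatives by `"|"`,
#' so that `parse_extension_field(serialize_extension_field(f))` reproduces
#' `f` exactly. An empty field serializes to `""`.
#'
#' @param field an [extension_field()].
#' @return a single character string.
#' @export
serialize_extension_field <- function(field) {
  if (ext_is_empty(field)) return("")
  paste(vapply(field$conjunctions, function(conj) {
    paste(vapply(conj, format.rel_expr, character(1)), collapse = ",")
  }, character(1)), collapse = "|")
}

#' @export
format.extension_field <- function(x, ...) serialize_extension_field(x)

#' @export
print.extension_field <- function(x, ...) {
  if (ext_is_empty(x)) {
    cat("<extension_field: empty>\n")
  } else {
    cat(sprintf("<extension_field: %d conjunction(s), %d expression(s)>\n",
                n_conjunctions(x), n_expressions(x)))
    cat(" ", serialize_extension_field(x), "\n")
  }
  invisible(x)
}
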