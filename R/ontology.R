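# In-memory ontology model and OBO-subset reader/writer.
#
# An ontology holds named terms (GO plus external ontologies such as CL and
# Uberon), is_a axioms, relationship axioms (child SubClassOf r some filler),
# genus-differentia equivalence axioms parsed from intersection_of blocks,
# disjointness axioms, and upper-level category assignments (continuant vs
# occurrent) used to enforce relation range constraints.

.aspects <- c("molecular_function", "biological_process", "cellular_component")

#' Define an annotation-extension relation
#'
#' Extension relations carry usage metadata beyond their identifier: which GO
#' aspects the primary term may have, which entity identifiers may fill them
#' (ID-prefix or required-ancestor-class constraints), the upper-level
#' category of the filler (the range of `occurs_in` is a continuant), and --
#' for composite relations such as `regulates_occurs_in` -- a property chain
#' of length two or more.
#'
#' @param label relation label used in extension text, e.g. `"part_of"`.
#' @param id CURIE of the relation; defaults to a reserved `GOREL:` id.
#' @param property_id CURIE of the underlying OWL object property (e.g.
#'   `BFO:0000050` for `part_of`), or `NA` when none is assigned.
#' @param allowed_aspects GO aspects the primary term may have.
#' @param allowed_fillers character vector of constraints: bare prefixes
#'   (e.g. `"CL"`) or ancestor CURIEs (e.g. `"CL:0000000"`); empty means
#'   unconstrained.
#' @param range_category `"continuant"`, `"occurrent"`, or `"any"`.
#' @param chain character vector of relation labels (length 0 or >= 2).
#' @param subset_tags free-text subset labels (e.g. `"chemical"`).
#' @param obsolete logical flag.
#' @return an object of class `relation_def`.
#' @export
relation_def <- function(label,
                         id = paste0("GOREL:", label),
                         property_id = NA_character_,
                         allowed_aspects = .aspects,
                         allowed_fillers = character(0),
                         range_category = c("any", "continuant", "occurrent"),
                         chain = character(0),
                         subset_tags = character(0),
                         obsolete = FALSE) {
  range_category <- match.arg(range_category)
  if (length(chain) == 1L) {
    goext_error(sprintf("relation '%s': chain must have length 0 or >= 2",
                        label),
                "goext_obo_error")
  }
  structure(list(
    label = label, id = id, property_id = property_id,
    allowed_aspects = allowed_aspects, allowed_fillers = allowed_fillers,
    range_category = range_category, chain = chain,
    subset_tags = subset_tags, obsolete = obsolete
  ), class = "relation_def")
}

#' @export
print.relation_def <- function(x, ...) {
  cat(sprintf("<relation_def %s (%s)%s>\n", x$label,
              if (is.na(x$property_id)) x$id else x$property_id,
              if (length(x$chain)) paste0(" = ",
                                          paste(x$chain, collapse = " o "))
              else ""))
  invisible(x)
}

empty_terms <- function() {
  tibble::tibble(id = character(0), label = character(0),
                 aspect = character(0), obsolete = logical(0))
}

term_tbl <- function(id, label = id, aspect = "external", obsolete = FALSE) {
  tibble::tibble(id = curie_normalize(id), label = label, aspect = aspect,
                 obsolete = obsolete)
}

pair_tbl <- function(..., cols) {
  args <- list(...)
  if (length(args) == 0 || is.null(args[[1]])) {
    return(tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(cols)), cols)))
  }
  tibble::as_tibble(stats::setNames(args, cols))
}

# Default continuant/occurrent assignment: processes and activities are
# occurrents; components, cells, anatomical parts and chemicals persist
# through time and are continuants. External terms are classified by prefix.
.continuant_prefixes <- c("CL", "UBERON", "PO", "CHEBI", "WBbt", "EMAPA",
                          "FBbt", "ZFA", "MA")

default_categories <- function(terms) {
  cat <- rep(NA_character_, nrow(terms))
  cat[terms$aspect %in% c("biological_process", "molecular_function")] <-
    "occurrent"
  cat[terms$aspect == "cellular_component"] <- "continuant"
  ext <- terms$aspect == "external"
  cat[ext & curie_prefix(terms$id) %in% .continuant_prefixes] <- "continuant"
  stats::setNames(cat, terms$id)[!is.na(cat)]
}

#' Construct an ontology
#'
#' Programmatic constructor for the ontology container used throughout the
#' package; [parse_obo()] builds the same structure from OBO text.
#'
#' @param terms tibble with columns `id`, `label`, `aspect`
#'   (`molecular_function`, `biological_process`, `cellular_component` or
#'   `external`) and `obsolete`.
#' @param relations named list of [relation_def()] objects, keyed by label.
#' @param subclass tibble (`child`, `parent`) of is_a axioms.
#' @param relationship tibble (`child`, `relation`, `filler`): child
#'   SubClassOf relation some filler.
#' @param equivalence list of equivalence axioms, each
#'   `list(defined =, genus =, differentia =)` where `differentia` is a
#'   tibble (`relation`, `filler`); encodes defined = genus and
#'   (r1 some f1) and ...
#' @param disjoint tibble (`a`, `b`): the intersection of `a` and `b` is
#'   unsatisfiable.
#' @param categories named character vector mapping term ids to
#'   `"continuant"`/`"occurrent"`; defaults are derived from aspect and
#'   identifier prefix and can be overridden here.
#' @return an object of class `go_ontology`.
#' @export
ontology <- function(terms = empty_terms(), relations = list(),
                     subclass = NULL, relationship = NULL,
                     equivalence = list(), disjoint = NULL,
                     categories = NULL) {
  terms <- tibble::as_tibble(terms)
  if (anyDuplicated(terms$id)) {
    goext_error(sprintf("duplicate term id: %s",
                        terms$id[duplicated(terms$id)][1]),
                "goext_obo_error")
  }
  subclass <- if (is.null(subclass)) {
    pair_tbl(cols = c("child", "parent"))
  } else tibble::as_tibble(subclass)
  relationship <- if (is.null(relationship)) {
    pair_tbl(cols = c("child", "relation", "filler"))
  } else tibble::as_tibble(relationship)
  disjoint <- if (is.null(disjoint)) {
    pair_tbl(cols = c("a", "b"))
  } else tibble::as_tibble(disjoint)

  for (eq in equivalence) {
    if (nrow(eq$differentia) == 0L) {
      goext_error(sprintf("equivalence axiom for %s has no differentia",
                          eq$defined),
                  "goext_obo_error")
    }
    if (identical(eq$defined, eq$genus)) {
      goext_error(sprintf("equivalence axiom for %s: genus equals the defined class",
                          eq$defined),
                  "goext_obo_error")
    }
  }
  for (rd in relations) {
    missing <- setdiff(rd$chain, names(relations))
    if (length(missing)) {
      goext_error(sprintf("relation '%s': chain element '%s' is not a defined relation",
                          rd$label, missing[1]),
                  "goext_obo_error")
    }
  }

  cats <- default_categories(terms)
  if (!is.null(categories)) cats[names(categories)] <- categories

  mentioned <- unique(c(subclass$child, subclass$parent,
                        relationship$child, disjoint$a, disjoint$b,
                        vapply(equivalence, function(e) e$defined,
                               character(1))))
  dangling <- setdiff(mentioned, terms$id)

  structure(list(
    terms = terms, relations = relations, subclass = subclass,
    relationship = relationship, equivalence = equivalence,
    disjoint = disjoint, categories = cats, dangling = dangling
  ), class = "go_ontology")
}

#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf(paste0("<go_ontology: %d terms, %d relations, %d is_a, ",
                     "%d relationship, %d equivalence, %d disjointness>\n"),
              nrow(x$terms), length(x$relations), nrow(x$subclass),
              nrow(x$relationship), length(x$equivalence),
              nrow(x$disjoint)))
  invisible(x)
}

term_aspect <- function(ont, id) {
  i <- match(id, ont$terms$id)
  ifelse(is.na(i), NA_character_, ont$terms$aspect[i])
}

term_label <- function(ont, id) {
  i <- match(id, ont$terms$id)
  out <- ont$terms$label[i]
  out[is.na(i)] <- id[is.na(i)]
  out
}

#' Merge ontologies
#'
#' Concatenates terms and axioms of several ontologies (e.g. a mini-GO with
#' CL and Uberon subsets) into one reasoning namespace. Term ids must be
#' disjoint; relation sets are merged by label with later arguments
#' overriding earlier ones.
#'
#' @param ... `go_ontology` objects.
#' @return a merged `go_ontology`.
#' @export
merge_ontologies <- function(...) {
  onts <- list(...)
  terms <- do.call(rbind, lapply(onts, function(o) o$terms))
  relations <- list()
  for (o in onts) relations[names(o$relations)] <- o$relations
  cats <- character(0)
  for (o in onts) cats[names(o$categories)] <- o$categories
  ontology(
    terms = terms, relations = relations,
    subclass = do.call(rbind, lapply(onts, function(o) o$subclass)),
    relationship = do.call(rbind, lapply(onts, function(o) o$relationship)),
    equivalence = do.call(c, lapply(onts, function(o) o$equivalence)),
    disjoint = do.call(rbind, lapply(onts, function(o) o$disjoint)),
    categories = cats
  )
}

# ---- OBO subset parser -----------------------------------------------------

.term_tags <- c("id", "name", "namespace", "is_a", "relationship",
                "intersection_of", "is_obsolete", "disjoint_from", "subset")
.typedef_tags <- c("id", "name", "namespace", "xref", "domain", "range",
                   "holds_over_chain", "is_obsolete", "subset")

strip_obo_comment <- function(x) sub("\\s*!.*$", "", x)

#' Parse an OBO-format document (supported subset)
#'
#' Reads `[Term]` and `[Typedef]` stanzas. Supported term tags: `id`,
#' `name`, `namespace`, `is_a`, `relationship`, `intersection_of`,
#' `is_obsolete`, `disjoint_from`, `subset`. Supported typedef tags: `id`,
#' `name`, `namespace`, `xref` (the underlying object-property CURIE),
#' `domain` (allowed GO aspects), `range` (category, ancestor-class or
#' prefix constraints on fillers), `holds_over_chain`, `is_obsolete`,
#' `subset`. Every `intersection_of` block (one bare genus plus one or more
#' relation-qualified clauses) becomes an equivalence axiom. Unknown tags
#' are ignored with a single warning listing them; duplicate stanza ids and
#' malformed intersection_of blocks are errors.
#'
#' @param file path to an OBO file.
#' @param text alternatively, OBO content as a character vector of lines or
#'   one string with embedded newlines.
#' @return a [ontology()] object.
#' @export
parse_obo <- function(file = NULL, text = NULL) {
  lines <- read_annotation_lines(file, text)
  lines <- sub("\\s+$", "", lines)

  stanza_type <- NA_character_
  stanzas <- list()
  current <- NULL
  flush <- function() {
    if (!is.null(current) && length(current$tags)) {
      stanzas[[length(stanzas) + 1L]] <<- current
    }
  }
  unknown_tags <- character(0)

  for (line in lines) {
    if (grepl("^\\[.*\\]$", line)) {
      flush()
      stanza_type <- sub("^\\[(.*)\\]$", "\\1", line)
      current <- list(type = stanza_type,
                      tags = character(0), values = character(0))
      next
    }
    if (is.null(current) || !nzchar(line)) next
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
    if (length(m) != 3L) next
    tag <- m[2]
    value <- trimws(strip_obo_comment(m[3]))
    supported <- switch(current$type,
                        Term = .term_tags, Typedef = .typedef_tags,
                        character(0))
    if (!(tag %in% supported)) {
      unknown_tags <- c(unknown_tags, tag)
      next
    }
    current$tags <- c(current$tags, tag)
    current$values <- c(current$values, value)
  }
  flush()
  if (length(unknown_tags)) {
    goext_warn(sprintf("ignoring unsupported OBO tags: %s",
                       paste(sort(unique(unknown_tags)), collapse = ", ")),
               "goext_obo_warning")
  }

  terms <- list(); subclass <- list(); relationship <- list()
  equivalence <- list(); disjoint <- list(); relations <- list()
  seen_ids <- character(0)

  for (st in stanzas) {
    vals <- function(tag) st$values[st$tags == tag]
    id <- vals("id")[1]
    if (is.na(id)) {
      goext_error("stanza without an id tag", "goext_obo_error")
    }
    if (st$type == "Term") {
      id <- curie_normalize(id)
      if (id %in% seen_ids) {
        goext_error(sprintf("duplicate stanza id: %s", id),
                    "goext_obo_error")
      }
      seen_ids <- c(seen_ids, id)
      ns <- vals("namespace")[1]
      aspect <- if (!is.na(ns) && ns %in% .aspects) ns else "external"
      nm <- vals("name")[1]
      if (is.na(nm)) nm <- id
      terms[[length(terms) + 1L]] <- term_tbl(
        id, label = nm, aspect = aspect,
        obsolete = identical(vals("is_obsolete")[1], "true")
      )
      for (p in vals("is_a")) {
        subclass[[length(subclass) + 1L]] <- c(id, curie_normalize(p))
      }
      for (r in vals("relationship")) {
        tok <- strsplit(trimws(r), "\\s+")[[1]]
        if (length(tok) != 2L) {
          goext_error(sprintf("malformed relationship tag in %s: '%s'", id, r),
                      "goext_obo_error")
        }
        relationship[[length(relationship) + 1L]] <-
          c(id, tok[1], curie_normalize(tok[2]))
      }
      for (d in vals("disjoint_from")) {
        disjoint[[length(disjoint) + 1L]] <- c(id, curie_normalize(d))
      }
      xp <- vals("intersection_of")
      if (length(xp)) {
        toks <- lapply(xp, function(v) strsplit(trimws(v), "\\s+")[[1]])
        genus <- vapply(toks[lengths(toks) == 1L], `[[`, character(1), 1L)
        diffs <- toks[lengths(toks) == 2L]
        if (length(genus) != 1L) {
          goext_error(sprintf(
            "intersection_of block in stanza %s must have exactly one genus (found %d)",
            id, length(genus)), "goext_obo_error")
        }
        if (length(diffs) == 0L) {
          goext_error(sprintf(
            "intersection_of block in stanza %s has no differentia", id),
            "goext_obo_error")
        }
        equivalence[[length(equivalence) + 1L]] <- list(
          defined = id, genus = curie_normalize(genus),
          differentia = tibble::tibble(
            relation = vapply(diffs, `[[`, character(1), 1L),
            filler = curie_normalize(vapply(diffs, `[[`, character(1), 2L))
          )
        )
      }
    } else if (st$type == "Typedef") {
      label <- vals("name")[1]
      if (is.na(label)) label <- id
      if (label %in% names(relations)) {
        goext_error(sprintf("duplicate stanza id: %s", label),
                    "goext_obo_error")
      }
      xrefs <- vals("xref")
      prop <- xrefs[is_curie(curie_normalize(xrefs))][1]
      if (!is.na(prop)) prop <- curie_normalize(prop)
      domains <- vals("domain")
      aspects <- intersect(domains, .aspects)
      if (length(aspects) == 0L || "any" %in% domains) aspects <- .aspects
      ranges <- vals("range")
      range_cat <- "any"
      fillers <- character(0)
      for (rv in ranges) {
        if (rv %in% c("continuant", .CONTINUANT)) {
          range_cat <- "continuant"
        } else if (rv %in% c("occurrent", .OCCURRENT)) {
          range_cat <- "occurrent"
        } else if (is_curie(curie_normalize(rv))) {
          fillers <- c(fillers, curie_normalize(rv))
        } else {
          fillers <- c(fillers, rv)
        }
      }
      chain <- character(0)
      hoc <- vals("holds_over_chain")
      if (length(hoc)) chain <- strsplit(trimws(hoc[1]), "\\s+")[[1]]
      rid <- if (grepl(":", id, fixed = TRUE)) curie_normalize(id) else
        paste0("GOREL:", label)
      relations[[label]] <- relation_def(
        label, id = rid, property_id = prop, allowed_aspects = aspects,
        allowed_fillers = fillers, range_category = range_cat,
        chain = chain, subset_tags = vals("subset"),
        obsolete = identical(vals("is_obsolete")[1], "true")
      )
    }
  }

  ontology(
    terms = if (length(terms)) do.call(rbind, terms) else empty_terms(),
    relations = relations,
    subclass = if (length(subclass)) {
      m <- do.call(rbind, subclass)
      pair_tbl(m[, 1], m[, 2], cols = c("child", "parent"))
    } else NULL,
    relationship = if (length(relationship)) {
      m <- do.call(rbind, relationship)
      pair_tbl(m[, 1], m[, 2], m[, 3], cols = c("child", "relation", "filler"))
    } else NULL,
    equivalence = equivalence,
    disjoint = if (length(disjoint)) {
      m <- do.call(rbind, disjoint)
      pair_tbl(m[, 1], m[, 2], cols = c("a", "b"))
    } else NULL
  )
}

#' Serialize an ontology to OBO text (supported subset)
#'
#' Writes `[Term]` and `[Typedef]` stanzas for the tags honored by
#' [parse_obo()], so that parse and write are mutually inverse on that
#' subset. Used to emit fixture ontologies and fold-generated application
#' ontologies (folded terms appear with their `intersection_of` logical
#' definition).
#'
#' @param ont a [ontology()] object.
#' @param file optional output path.
#' @return the OBO lines, invisibly when `file` is given.
#' @export
write_obo <- function(ont, file = NULL) {
  out <- c("format-version: 1.2", "")
  eq_by_term <- split(ont$equivalence,
                      vapply(ont$equivalence, function(e) e$defined,
                             character(1)))
  for (i in seq_len(nrow(ont$terms))) {
    id <- ont$terms$id[i]
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", ont$terms$label[i]))
    if (ont$terms$aspect[i] != "external") {
      out <- c(out, paste0("namespace: ", ont$terms$aspect[i]))
    }
    if (ont$terms$obsolete[i]) out <- c(out, "is_obsolete: true")
    for (p in ont$subclass$parent[ont$subclass$child == id]) {
      out <- c(out, paste0("is_a: ", p))
    }
    rel <- ont$relationship[ont$relationship$child == id, ]
    for (j in seq_len(nrow(rel))) {
      out <- c(out, paste0("relationship: ", rel$relation[j], " ",
                           rel$filler[j]))
    }
    for (eq in eq_by_term[[id]] %||% list()) {
      out <- c(out, paste0("intersection_of: ", eq$genus))
      for (j in seq_len(nrow(eq$differentia))) {
        out <- c(out, paste0("intersection_of: ", eq$differentia$relation[j],
                             " ", eq$differentia$filler[j]))
      }
    }
    for (d in ont$disjoint$b[ont$disjoint$a == id]) {
      out <- c(out, paste0("disjoint_from: ", d))
    }
    out <- c(out, "")
  }
  for (rd in ont$relations) {
    out <- c(out, "[Typedef]", paste0("id: ", rd$id),
             paste0("name: ", rd$label))
    if (!is.na(rd$property_id)) out <- c(out, paste0("xref: ", rd$property_id))
    if (!setequal(rd$allowed_aspects, .aspects)) {
      for (a in rd$allowed_aspects) out <- c(out, paste0("domain: ", a))
    }
    if (rd$range_category != "any") {
      out <- c(out, paste0("range: ", rd$range_category))
    }
    for (f in rd$allowed_fillers) out <- c(out, paste0("range: ", f))
    if (length(rd$chain)) {
      out <- c(out, paste0("holds_over_chain: ",
                           paste(rd$chain, collapse = " ")))
    }
    for (s in rd$subset_tags) out <- c(out, paste0("subset: ", s))
    if (rd$obsolete) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# ---- Built-in relation set -------------------------------------------------

#' Built-in annotation-extension relations
#'
#' The relations most commonly used in annotation extensions, with their
#' usage metadata. Contextual relations (`part_of`, `occurs_in`,
#' `happens_during`) take cell, anatomy or GO terms; molecular relations
#' (`has_input`, `has_direct_input`, `has_regulation_target`) take gene
#' products or chemicals. `regulates_occurs_in` is defined by the property
#' chain `regulates o occurs_in` and expands to a nested existential.
#'
#' @return a named list of [relation_def()] objects, keyed by label.
#' @export
#' @examples
#' builtin_relations()[["part_of"]]$property_id  # "BFO:0000050"
builtin_relations <- function() {
  gp_dbs <- c("UniProtKB", "PomBase", "SGD", "MGI", "RGD", "WB", "FB",
              "TAIR", "dictyBase", "EcoCyc", "CHEBI")
  ctx <- c("CL", "UBERON", "PO", "GO", "WBbt", "EMAPA", "FBbt")
  rels <- list(
    relation_def("part_of", id = "BFO:0000050", property_id = "BFO:0000050",
                 range_category = "continuant",
                 subset_tags = "contextual"),
    relation_def("occurs_in", id = "BFO:0000066",
                 property_id = "BFO:0000066",
                 allowed_aspects = c("molecular_function",
                                     "biological_process"),
                 allowed_fillers = ctx, range_category = "continuant",
                 subset_tags = "contextual"),
    relation_def("happens_during", id = "RO:0002092",
                 property_id = "RO:0002092",
                 allowed_aspects = c("molecular_function",
                                     "biological_process"),
                 allowed_fillers = "GO", range_category = "occurrent",
                 subset_tags = "contextual"),
    relation_def("regulates", id = "RO:0002211",
                 property_id = "RO:0002211",
                 allowed_aspects = "biological_process",
                 range_category = "occurrent",
                 subset_tags = "contextual"),
    relation_def("has_regulation_target",
                 allowed_aspects = c("biological_process",
                                     "molecular_function"),
                 allowed_fillers = gp_dbs, subset_tags = "molecular"),
    relation_def("has_input", id = "RO:0002233",
                 property_id = "RO:0002233",
                 allowed_aspects = c("molecular_function",
                                     "biological_process"),
                 allowed_fillers = gp_dbs, subset_tags = "molecular"),
    relation_def("has_direct_input", id = "RO:0002400",
                 property_id = "RO:0002400",
                 allowed_aspects = c("molecular_function",
                                     "biological_process"),
                 allowed_fillers = gp_dbs, subset_tags = "molecular"),
    relation_def("regulates_occurs_in",
                 allowed_aspects = "biological_process",
                 allowed_fillers = ctx, range_category = "continuant",
                 chain = c("regulates", "occurs_in"),
                 subset_tags = "contextual")
  )
  stats::setNames(rels, vapply(rels, function(r) r$label, character(1)))
}

# ---- Identifier prefix registry -------------------------------------------

#' Identifier prefix registry
#'
#' The registry of database abbreviations against which extension entity
#' prefixes are checked. Matching is exact and case-sensitive.
#'
#' @param prefixes character vector of prefixes.
#' @param descriptions optional character vector of the same length.
#' @return an object of class `id_registry`.
#' @export
id_registry <- function(prefixes, descriptions = rep("", length(prefixes))) {
  structure(stats::setNames(descriptions, prefixes), class = "id_registry")
}

#' @export
print.id_registry <- function(x, ...) {
  cat(sprintf("<id_registry: %d prefixes>\n", length(x)))
  invisible(x)
}

registry_has <- function(registry, prefix) prefix %in% names(registry)

#' Read / write a prefix registry as two-column TSV
#'
#' @param file path to a TSV with columns prefix, description (no header).
#' @return an [id_registry()].
#' @export
read_registry <- function(file) {
  lines <- read_annotation_lines(file, NULL)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  id_registry(vapply(parts, `[[`, character(1), 1L),
              vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                     character(1)))
}

#' @rdname read_registry
#' @param registry an [id_registry()].
#' @export
write_registry <- function(registry, file = NULL) {
  lines <- paste(names(registry), unname(unclass(registry)), sep = "\t")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
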