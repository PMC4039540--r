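# Annotation folding, unfolding, validation and deepening.
#
# Folding rewrites each extended annotation (t, e) as a basic annotation to
# a materialized term t^A with the equivalence axiom t^A = t and e in a new
# application ontology, which is then classified so every folded term sits
# under its entailed named subsumers (at minimum t). Unfolding is the
# inverse: an annotation to a logically defined term t = t' and e becomes
# an annotation to t' with e in the extension field. The two directions are
# logically equivalent, so fold followed by unfold reproduces the corpus
# modulo conjunct order and disjunction splitting.

# Content-addressed folded-term ids: a stable 31-bit polynomial hash over
# the source term plus the canonicalized (sorted) expression, so repeated
# runs and merged corpora assign the same id to the same meaning.
content_hash <- function(x) {
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08X", h)
}

conj_canonical <- function(conj) {
  paste(sort(vapply(conj, format.rel_expr, character(1))), collapse = ",")
}

folded_term_id <- function(go_term, conj) {
  paste0(.FOLD_PREFIX, ":",
         content_hash(paste0(go_term, "|", conj_canonical(conj))))
}

is_not_qualified <- function(qualifier) {
  vapply(strsplit(qualifier, "|", fixed = TRUE),
         function(q) "NOT" %in% q, logical(1))
}

report_entry <- function(record, rule, severity, message) {
  tibble::tibble(record = record, rule = rule, severity = severity,
                 message = message)
}

empty_report <- function() {
  tibble::tibble(record = integer(0), rule = character(0),
                 severity = character(0), message = character(0))
}

.rule_order <- c("GRAMMAR", "UNKNOWN_RELATION", "PREFIX", "USAGE_ASPECT",
                 "USAGE_FILLER", "UNSATISFIABLE", "DUPLICATE")

sort_report <- function(report) {
  report[order(report$record, match(report$rule, .rule_order)), ]
}

aspect_letter_to_name <- c(F = "molecular_function",
                           P = "biological_process",
                           C = "cellular_component")

record_term_aspect <- function(records, ont) {
  asp <- term_aspect(ont, records$go_id)
  fallback <- unname(aspect_letter_to_name[records$aspect])
  ifelse(is.na(asp) | asp == "external", fallback, asp)
}

#' Fold extended annotations into an application ontology
#'
#' For every distinct (term, extension-conjunction) pair in the corpus a new
#' term is materialized in a reserved namespace, defined by the equivalence
#' axiom `folded = term and e`, and each extended record is rewritten to its
#' folded term with an empty extension field. Disjunctive extensions are
#' split into independent records first. The application ontology (input
#' ontology plus folded terms) is classified with the EL reasoner, so every
#' folded term acquires its entailed named superclasses -- at minimum its
#' source term; the inferred direct parents are added as is_a links for
#' browsing. Records with an empty extension pass through unchanged;
#' NOT-qualified records and records using unknown relations pass through
#' with a report entry.
#'
#' @param records an annotation tibble.
#' @param ont a [ontology()] supplying the reasoning context.
#' @param relations relation set; defaults to the ontology's.
#' @return an object of class `fold_result`: `application_ontology`,
#'   rewritten `records`, the folded-term `mapping`, the classification
#'   `index`, and a `report` tibble.
#' @export
fold <- function(records, ont, relations = ont$relations) {
  records <- split_disjunction(records)
  n <- nrow(records)
  report <- list()
  skip <- logical(n)

  not_mask <- is_not_qualified(records$qualifier)
  ext_mask <- !vapply(records$extension, ext_is_empty, logical(1))
  for (i in which(not_mask & ext_mask)) {
    report[[length(report) + 1L]] <- report_entry(
      i, "GRAMMAR", "warning",
      "NOT-qualified record excluded from folding")
    skip[i] <- TRUE
  }
  for (i in which(ext_mask & !skip)) {
    labels <- vapply(records$extension[[i]]$conjunctions[[1]],
                     function(e) e$relation, character(1))
    unknown <- setdiff(labels, names(relations))
    if (length(unknown)) {
      report[[length(report) + 1L]] <- report_entry(
        i, "UNKNOWN_RELATION", "error",
        sprintf("unknown relation '%s'; record not folded", unknown[1]))
      skip[i] <- TRUE
    }
  }

  todo <- which(ext_mask & !skip)
  keys <- character(0)
  fold_ids <- character(n)
  new_terms <- list()
  new_eq <- list()
  mapping_rows <- list()
  aspects <- record_term_aspect(records, ont)
  for (i in todo) {
    conj <- records$extension[[i]]$conjunctions[[1]]
    key <- paste0(records$go_id[i], "|", conj_canonical(conj))
    fid <- folded_term_id(records$go_id[i], conj)
    fold_ids[i] <- fid
    if (!(key %in% keys)) {
      keys <- c(keys, key)
      lab <- sprintf("%s [%s]", term_label(ont, records$go_id[i]),
                     paste(vapply(conj, function(e) {
                       paste(e$relation, term_label(ont, e$entity))
                     }, character(1)), collapse = ", "))
      asp <- aspects[i]
      new_terms[[length(new_terms) + 1L]] <- term_tbl(
        fid, label = lab,
        aspect = if (is.na(asp)) "external" else asp)
      new_eq[[length(new_eq) + 1L]] <- list(
        defined = fid, genus = records$go_id[i],
        differentia = tibble::tibble(
          relation = vapply(conj, function(e) e$relation, character(1)),
          filler = vapply(conj, function(e) e$entity, character(1))
        )
      )
      mapping_rows[[length(mapping_rows) + 1L]] <- tibble::tibble(
        folded_id = fid, source_term = records$go_id[i],
        expression = conj_canonical(conj)
      )
    }
  }

  app <- ontology(
    terms = rbind(ont$terms,
                  if (length(new_terms)) do.call(rbind, new_terms)),
    relations = relations,
    subclass = ont$subclass,
    relationship = ont$relationship,
    equivalence = c(ont$equivalence, new_eq),
    disjoint = ont$disjoint,
    categories = ont$categories
  )
  idx <- classify(app, relations = relations)

  mapping <- if (length(mapping_rows)) {
    do.call(rbind, mapping_rows)
  } else {
    tibble::tibble(folded_id = character(0), source_term = character(0),
                   expression = character(0))
  }
  mapping$unsatisfiable <- mapping$folded_id %in% idx$unsatisfiable
  for (i in todo) {
    if (fold_ids[i] %in% idx$unsatisfiable) {
      report[[length(report) + 1L]] <- report_entry(
        i, "UNSATISFIABLE", "error",
        sprintf("folded term %s is unsatisfiable", fold_ids[i]))
    }
  }

  # inferred is_a links for folded terms: their minimal named subsumers
  extra_sub <- list()
  for (fid in mapping$folded_id[!mapping$unsatisfiable]) {
    sups <- setdiff(subsumers(idx, fid), fid)
    parents <- minimal_classes(sups, idx, app)
    parents <- setdiff(parents, fid)
    for (p in parents) extra_sub[[length(extra_sub) + 1L]] <- c(fid, p)
  }
  if (length(extra_sub)) {
    m <- do.call(rbind, extra_sub)
    app$subclass <- unique(rbind(app$subclass,
                                 pair_tbl(m[, 1], m[, 2],
                                          cols = c("child", "parent"))))
  }

  out <- records
  rewrite <- which(nzchar(fold_ids))
  out$go_id[rewrite] <- fold_ids[rewrite]
  out$annotation_extension[rewrite] <- ""
  out$extension[rewrite] <- list(extension_field())

  structure(list(
    application_ontology = app,
    records = out,
    mapping = mapping,
    index = idx,
    report = sort_report(if (length(report)) do.call(rbind, report)
                         else empty_report())
  ), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result: %d records, %d folded terms (%d unsatisfiable)>\n",
              nrow(x$records), nrow(x$mapping), sum(x$mapping$unsatisfiable)))
  invisible(x)
}

eligible_unfold_axioms <- function(ont, relations) {
  ok <- vapply(ont$equivalence, function(eq) {
    curie_prefix(eq$genus) == "GO" &&
      all(eq$differentia$relation %in% names(relations)) &&
      all(is_curie(eq$differentia$filler))
  }, logical(1))
  ont$equivalence[ok]
}

#' Unfold annotations to logically defined terms
#'
#' For each record whose term `t` carries an equivalence axiom
#' `t = t' and e` with `t'` a GO term of the same aspect and `e` within the
#' extension profile, the record is rewritten to `t'` with `e` merged
#' conjunctively into each existing extension conjunction (or becoming the
#' extension when the record was unextended). Terms with several eligible
#' axioms use the first in ontology order, with a warning entry. By default
#' a single rewrite step is applied; `recursive = TRUE` iterates to a fixed
#' point. Records on primitive terms, and NOT-qualified records, pass
#' through unchanged.
#'
#' @param records an annotation tibble.
#' @param ont a [ontology()] supplying the equivalence axioms (e.g. a fold
#'   result's application ontology).
#' @param relations relation set; defaults to the ontology's.
#' @param recursive iterate until no record changes.
#' @return the rewritten annotation tibble, with an `unfold_report`
#'   attribute.
#' @export
unfold <- function(records, ont, relations = ont$relations,
                   recursive = FALSE) {
  eligible <- eligible_unfold_axioms(ont, relations)
  defined <- vapply(eligible, function(e) e$defined, character(1))
  report <- list()
  for (d in unique(defined[duplicated(defined)])) {
    report[[length(report) + 1L]] <- report_entry(
      NA_integer_, "GRAMMAR", "warning",
      sprintf("term %s has multiple eligible equivalence axioms; using the first",
              d))
  }
  first_ax <- eligible[!duplicated(defined)]
  names(first_ax) <- defined[!duplicated(defined)]
  not_mask <- is_not_qualified(records$qualifier)

  step <- function(recs) {
    changed <- FALSE
    asp <- record_term_aspect(recs, ont)
    for (i in seq_len(nrow(recs))) {
      if (not_mask[i]) next
      eq <- first_ax[[recs$go_id[i]]]
      if (is.null(eq)) next
      genus_aspect <- term_aspect(ont, eq$genus)
      if (!is.na(asp[i]) && !is.na(genus_aspect) &&
          genus_aspect != "external" && asp[i] != genus_aspect) next
      diffs <- lapply(seq_len(nrow(eq$differentia)), function(j) {
        rel_expr(eq$differentia$relation[j], eq$differentia$filler[j])
      })
      f <- recs$extension[[i]]
      newf <- if (ext_is_empty(f)) {
        extension_field(list(diffs))
      } else {
        extension_field(lapply(f$conjunctions, function(conj) {
          c(conj, diffs)
        }))
      }
      recs$go_id[i] <- eq$genus
      recs$extension[[i]] <- newf
      recs$annotation_extension[i] <- serialize_extension_field(newf)
      changed <- TRUE
    }
    list(recs = recs, changed = changed)
  }

  res <- step(records)
  if (recursive) {
    iter <- 1L
    while (res$changed && iter < 25L) {
      res <- step(res$recs)
      iter <- iter + 1L
    }
  }
  out <- res$recs
  attr(out, "unfold_report") <-
    sort_report(if (length(report)) do.call(rbind, report)
                else empty_report())
  out
}

#' Validate extended annotations
#'
#' Applies, in order per record: a grammar re-check of the extension text;
#' relation existence; entity-prefix membership in the identifier registry;
#' usage checks (the primary term's aspect against the relation's allowed
#' aspects, and the filler against the relation's ID-prefix or
#' ancestor-class constraints); satisfiability of the translated class
#' expression under the ontology; and a duplicate-expression check.
#' Grammar, unknown-relation, prefix and unsatisfiability findings are
#' errors; usage and duplicate findings are warnings. All findings are
#' report entries -- the function itself never fails on bad input.
#'
#' @param records an annotation tibble.
#' @param ont a [ontology()].
#' @param relations relation set; defaults to the ontology's.
#' @param registry an [id_registry()] of permitted entity prefixes.
#' @return a tibble (`record`, `rule`, `severity`, `message`) ordered by
#'   record then rule.
#' @export
validate_annotations <- function(records, ont, relations = ont$relations,
                                 registry) {
  report <- list()
  add <- function(i, rule, severity, message) {
    report[[length(report) + 1L]] <<- report_entry(i, rule, severity,
                                                   message)
  }
  aspects <- record_term_aspect(records, ont)
  queries <- list()
  query_rec <- integer(0)

  for (i in seq_len(nrow(records))) {
    f <- records$extension[[i]]
    if (is.null(f)) {
      msg <- tryCatch({
        parse_extension_field(records$annotation_extension[i])
        "unparseable extension"
      }, goext_error = function(e) conditionMessage(e))
      add(i, "GRAMMAR", "error", msg)
      next
    }
    if (ext_is_empty(f)) next
    satisfiable_checkable <- TRUE
    for (ci in seq_along(f$conjunctions)) {
      conj <- f$conjunctions[[ci]]
      seen <- character(0)
      for (e in conj) {
        key <- format.rel_expr(e)
        if (key %in% seen) {
          add(i, "DUPLICATE", "warning",
              sprintf("duplicate expression %s within a conjunction", key))
        }
        seen <- c(seen, key)
        rd <- relations[[e$relation]]
        if (is.null(rd)) {
          add(i, "UNKNOWN_RELATION", "error",
              sprintf("unknown relation '%s'", e$relation))
          satisfiable_checkable <- FALSE
          next
        }
        if (!registry_has(registry, curie_prefix(e$entity))) {
          add(i, "PREFIX", "error",
              sprintf("entity prefix '%s' not in the database-abbreviation registry",
                      curie_prefix(e$entity)))
        }
        if (!is.na(aspects[i]) && !(aspects[i] %in% rd$allowed_aspects)) {
          add(i, "USAGE_ASPECT", "warning",
              sprintf("relation '%s' is not used with %s terms",
                      e$relation, aspects[i]))
        }
        if (length(rd$allowed_fillers)) {
          prefixes <- rd$allowed_fillers[!is_curie(rd$allowed_fillers)]
          ancestors <- rd$allowed_fillers[is_curie(rd$allowed_fillers)]
          if (!(curie_prefix(e$entity) %in% prefixes) &&
              length(ancestors) == 0L) {
            add(i, "USAGE_FILLER", "warning",
                sprintf("filler %s not permitted for relation '%s'",
                        e$entity, e$relation))
          }
          # ancestor-class constraints need the classification and are
          # resolved in the second pass below
        }
      }
      if (satisfiable_checkable) {
        qname <- sprintf("FRESHQ:v%04d_%02d", i, ci)
        queries[[qname]] <- conjunction_to_class_expression(
          records$go_id[i], conj, relations)
        query_rec <- c(query_rec, i)
        names(query_rec)[length(query_rec)] <- qname
      }
    }
  }

  idx <- classify(ont, queries = queries, relations = relations)

  # ancestor-class filler constraints, resolved against the classification
  for (i in seq_len(nrow(records))) {
    f <- records$extension[[i]]
    if (is.null(f) || ext_is_empty(f)) next
    for (conj in f$conjunctions) {
      for (e in conj) {
        rd <- relations[[e$relation]]
        if (is.null(rd) || length(rd$allowed_fillers) == 0L) next
        prefixes <- rd$allowed_fillers[!is_curie(rd$allowed_fillers)]
        ancestors <- rd$allowed_fillers[is_curie(rd$allowed_fillers)]
        if (curie_prefix(e$entity) %in% prefixes) next
        if (length(ancestors) == 0L) next
        if (!any(ancestors %in% subsumers(idx, e$entity))) {
          add(i, "USAGE_FILLER", "warning",
              sprintf("filler %s is not a descendant of %s",
                      e$entity, paste(ancestors, collapse = "/")))
        }
      }
    }
  }

  for (k in seq_along(query_rec)) {
    qname <- names(query_rec)[k]
    if (qname %in% idx$unsatisfiable) {
      add(query_rec[[k]], "UNSATISFIABLE", "error",
          "translated class expression is unsatisfiable")
    }
  }

  sort_report(if (length(report)) do.call(rbind, report)
              else empty_report())
}

#' Deepen annotations to their most specific class
#'
#' Translates each record's extension conjunction to a class expression,
#' computes its most specific named classes under the ontology, and -- when
#' a unique MSC strictly below the current term exists -- replaces the term.
#' When the MSC is logically equivalent to the full expression the consumed
#' extension is dropped; otherwise the extension is retained, since it still
#' carries information the new term does not entail. Records with an empty
#' extension, NOT-qualified records, records with disjunctive extensions,
#' and records whose MSC equals the current term or is ambiguous
#' (incomparable minima) are left unchanged. Deepening is idempotent.
#'
#' @param records an annotation tibble.
#' @param ont a [ontology()].
#' @param relations relation set; defaults to the ontology's.
#' @return the annotation tibble with deepened terms, carrying a
#'   `deepen_log` attribute describing skipped/tied records.
#' @export
deepen <- function(records, ont, relations = ont$relations) {
  log <- list()
  not_mask <- is_not_qualified(records$qualifier)
  queries <- list()
  cand_rows <- integer(0)
  for (i in seq_len(nrow(records))) {
    f <- records$extension[[i]]
    if (is.null(f) || ext_is_empty(f) || not_mask[i]) next
    if (n_conjunctions(f) > 1L) {
      log[[length(log) + 1L]] <- sprintf(
        "record %d: disjunctive extension left unchanged", i)
      next
    }
    qname <- sprintf("FRESHQ:d%04d", i)
    queries[[qname]] <- conjunction_to_class_expression(
      records$go_id[i], f$conjunctions[[1]], relations)
    cand_rows <- c(cand_rows, i)
    names(cand_rows)[length(cand_rows)] <- qname
  }
  if (length(queries) == 0L) {
    attr(records, "deepen_log") <- unlist(log) %||% character(0)
    return(records)
  }
  idx <- classify(ont, queries = queries, relations = relations)
  bad <- names(cand_rows)[names(cand_rows) %in% idx$unsatisfiable]
  if (length(bad)) {
    goext_error(sprintf(
      "record %d has an unsatisfiable extension; run validate_annotations() first",
      cand_rows[[bad[1]]]),
      "goext_unsatisfiable")
  }
  for (k in seq_along(cand_rows)) {
    qname <- names(cand_rows)[k]
    i <- cand_rows[[k]]
    msc <- minimal_classes(subsumers(idx, qname), idx, ont)
    if (length(msc) != 1L) {
      if (length(msc) > 1L) {
        log[[length(log) + 1L]] <- sprintf(
          "record %d: incomparable minima (%s); left unchanged",
          i, paste(msc, collapse = ", "))
      }
      next
    }
    t0 <- records$go_id[i]
    strictly_below <- t0 %in% subsumers(idx, msc) &&
      !(msc %in% subsumers(idx, t0))
    if (!strictly_below) next
    records$go_id[i] <- msc
    if (qname %in% subsumers(idx, msc)) {
      # MSC equivalent to the whole expression: extension fully consumed
      records$extension[[i]] <- extension_field()
      records$annotation_extension[i] <- ""
    }
  }
  attr(records, "deepen_log") <- unlist(log) %||% character(0)
  records
}
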