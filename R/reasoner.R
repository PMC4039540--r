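# Minimal EL completion reasoner.
#
# The extension model lives in EL++ (intersection, existential restriction,
# role chains), which admits polynomial-time classification. The reasoner
# normalizes the ontology plus any query expressions into the standard EL
# normal forms, saturates with the completion rules, and answers
# subsumption, satisfiability and most-specific-class queries from the
# resulting index. A deliberately naive brute-force engine over the
# *unnormalized* axioms serves as an independent oracle in the tests.
#
# Range constraints are compiled to axioms: range(r) = continuant becomes
# "(r some Occurrent) SubClassOf Nothing" via the per-class category
# assignments plus the Continuant/Occurrent disjointness, which is how the
# reasoner flags e.g. "occurs_in some <biological process>" as
# unsatisfiable.

new_axiom_acc <- function() {
  env <- new.env(parent = emptyenv())
  env$sub <- list()      # c(sub, sup)
  env$conj <- list()     # c(a, b, sup)
  env$exr <- list()      # c(sub, role, filler)
  env$exl <- list()      # c(role, filler, sup)
  env$rsub <- list()     # c(r, s)
  env$rchain <- list()   # c(r1, r2, s)
  env$fresh_n <- 0L
  env$classes <- character(0)
  env
}

acc_fresh <- function(acc) {
  acc$fresh_n <- acc$fresh_n + 1L
  sprintf("%s:%04d", .FRESH_PREFIX, acc$fresh_n)
}

acc_add <- function(acc, slot, row) {
  acc[[slot]][[length(acc[[slot]]) + 1L]] <- row
}

acc_df <- function(acc, slot, cols) {
  rows <- acc[[slot]]
  if (length(rows) == 0L) {
    return(tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(cols)), cols)))
  }
  m <- do.call(rbind, rows)
  tbl <- tibble::as_tibble(stats::setNames(
    lapply(seq_along(cols), function(j) m[, j]), cols))
  tbl[!duplicated(tbl), ]
}

# Canonical role name: the relation label when the property CURIE (or the
# label itself) is declared; otherwise the raw property string.
role_canon <- function(property, relations) {
  for (rd in relations) {
    if (identical(property, rd$label) ||
        (!is.na(rd$property_id) && identical(property, rd$property_id))) {
      return(rd$label)
    }
  }
  property
}

# Recursively encode an expression, returning an atomic class name A with
# A equivalent to the expression (definitional axioms in both directions).
encode_expr <- function(expr, acc, relations) {
  switch(expr$type,
    named = expr$id,
    bottom = .BOTTOM,
    some = {
      r <- role_canon(expr$property, relations)
      fa <- encode_expr(expr$filler, acc, relations)
      n <- acc_fresh(acc)
      acc_add(acc, "exr", c(n, r, fa))   # N SubClassOf r some fa
      acc_add(acc, "exl", c(r, fa, n))   # r some fa SubClassOf N
      n
    },
    "and" = {
      parts <- vapply(expr$operands, encode_expr, character(1),
                      acc = acc, relations = relations)
      m <- acc_fresh(acc)
      for (p in parts) acc_add(acc, "sub", c(m, p))
      if (length(parts) == 1L) {
        acc_add(acc, "sub", c(parts[1], m))
      } else {
        cur <- parts[1]
        for (i in seq_along(parts)[-1]) {
          nxt <- if (i == length(parts)) m else acc_fresh(acc)
          acc_add(acc, "conj", c(cur, parts[i], nxt))
          cur <- nxt
        }
      }
      m
    },
    goext_error("non-EL construct in expression", "goext_profile_error"))
}

encode_equivalence <- function(name, expr, acc, relations) {
  a <- encode_expr(expr, acc, relations)
  acc_add(acc, "sub", c(name, a))
  acc_add(acc, "sub", c(a, name))
}

#' Normalize an ontology (plus query expressions) to EL normal forms
#'
#' Produces the axiom set consumed by [saturate()]: atomic subsumptions,
#' binary conjunctions, left/right existentials, role inclusions and binary
#' role chains, with every complex expression replaced by a deterministic
#' fresh name carrying definitional axioms in both directions. Obsolete
#' terms are excluded from reasoning. Equivalence axioms become general
#' concept inclusions in both directions; category assignments, the
#' continuant/occurrent disjointness, and relation range constraints are
#' compiled in. Role chains longer than two are rejected.
#'
#' @param ont a [ontology()].
#' @param queries named list of class expressions; each name becomes a class
#'   equivalent to its expression.
#' @param relations relation set used to canonicalize property identifiers;
#'   defaults to the ontology's own relations.
#' @return an object of class `el_axioms`.
#' @export
normalize_axioms <- function(ont, queries = list(),
                             relations = ont$relations) {
  acc <- new_axiom_acc()
  obsolete <- ont$terms$id[ont$terms$obsolete]
  live <- function(x) !(x %in% obsolete)

  sc <- ont$subclass[live(ont$subclass$child) & live(ont$subclass$parent), ]
  for (i in seq_len(nrow(sc))) {
    acc_add(acc, "sub", c(sc$child[i], sc$parent[i]))
  }
  rel <- ont$relationship[live(ont$relationship$child) &
                            live(ont$relationship$filler), ]
  for (i in seq_len(nrow(rel))) {
    acc_add(acc, "exr", c(rel$child[i],
                          role_canon(rel$relation[i], relations),
                          rel$filler[i]))
  }
  for (eq in ont$equivalence) {
    if (!live(eq$defined)) next
    conj <- lapply(seq_len(nrow(eq$differentia)), function(j) {
      rel_expr(eq$differentia$relation[j], eq$differentia$filler[j])
    })
    expr <- conjunction_to_class_expression_raw(eq$genus, conj, relations)
    encode_equivalence(eq$defined, expr, acc, relations)
  }
  dj <- ont$disjoint
  for (i in seq_len(nrow(dj))) {
    acc_add(acc, "conj", c(dj$a[i], dj$b[i], .BOTTOM))
  }
  acc_add(acc, "conj", c(.CONTINUANT, .OCCURRENT, .BOTTOM))
  cats <- ont$categories[live(names(ont$categories))]
  for (i in seq_along(cats)) {
    acc_add(acc, "sub", c(names(cats)[i],
                          if (cats[[i]] == "continuant") .CONTINUANT
                          else .OCCURRENT))
  }
  for (rd in relations) {
    if (rd$range_category == "continuant") {
      acc_add(acc, "exl", c(rd$label, .OCCURRENT, .BOTTOM))
    } else if (rd$range_category == "occurrent") {
      acc_add(acc, "exl", c(rd$label, .CONTINUANT, .BOTTOM))
    }
    if (length(rd$chain) > 2L) {
      goext_error(sprintf("relation '%s': role chains longer than 2 are not supported",
                          rd$label),
                  "goext_profile_error")
    }
    if (length(rd$chain) == 2L) {
      acc_add(acc, "rchain", c(rd$chain[1], rd$chain[2], rd$label))
    }
  }
  for (nm in names(queries)) {
    encode_equivalence(nm, queries[[nm]], acc, relations)
  }

  acc$classes <- unique(c(ont$terms$id[!ont$terms$obsolete], names(queries)))
  structure(list(
    sub = acc_df(acc, "sub", c("sub", "sup")),
    conj = acc_df(acc, "conj", c("a", "b", "sup")),
    exr = acc_df(acc, "exr", c("sub", "role", "filler")),
    exl = acc_df(acc, "exl", c("role", "filler", "sup")),
    rsub = acc_df(acc, "rsub", c("r", "s")),
    rchain = acc_df(acc, "rchain", c("r1", "r2", "s")),
    classes = acc$classes,
    n_fresh = acc$fresh_n
  ), class = "el_axioms")
}

# Translation helper shared with normalize: like
# conjunction_to_class_expression() but tolerant of relations that are not
# declared (treated as primitive roles under their own label), so that
# ontologies mentioning undeclared relations still classify.
conjunction_to_class_expression_raw <- function(genus, conj, relations) {
  parts <- lapply(conj, function(e) {
    rd <- relations[[e$relation]]
    if (!is.null(rd) && length(rd$chain) >= 2L) {
      expr <- ce_named(e$entity)
      for (lab in rev(rd$chain)) expr <- ce_some(lab, expr)
      expr
    } else {
      ce_some(e$relation, ce_named(e$entity))
    }
  })
  ce_intersection(c(list(ce_named(genus)), parts))
}

#' Saturate a normalized axiom set (EL completion)
#'
#' Runs the EL completion rules to their fixed point: atomic subsumption,
#' binary conjunction, existential introduction and elimination, role
#' inclusion, binary role chains, and bottom propagation (a class whose
#' reached existential filler is unsatisfiable, or whose subsumer pair hits
#' a disjointness, is unsatisfiable). Termination is polynomial in the
#' input size; saturating a saturated set is a no-op.
#'
#' @param ax an `el_axioms` object from [normalize_axioms()].
#' @return an object of class `subsumption_index` with elements `subsumers`
#'   (named list: class -> character vector of subsumers, reflexive and
#'   transitively closed) and `unsatisfiable` (character vector).
#' @export
saturate <- function(ax) {
  classes <- unique(c(ax$classes, ax$sub$sub, ax$sub$sup,
                      ax$conj$a, ax$conj$b, ax$conj$sup,
                      ax$exr$sub, ax$exr$filler, ax$exl$filler, ax$exl$sup))
  classes <- setdiff(classes, .BOTTOM)
  S <- stats::setNames(lapply(classes, function(x) x), classes)
  roles <- unique(c(ax$exr$role, ax$exl$role, ax$rsub$r, ax$rsub$s,
                    ax$rchain$r1, ax$rchain$r2, ax$rchain$s))
  P <- stats::setNames(lapply(roles, function(r) {
    matrix(character(0), ncol = 2)
  }), roles)

  sub_by_sub <- split(ax$sub$sup, ax$sub$sub)
  exr_by_sub <- split(ax$exr[, c("role", "filler")], ax$exr$sub)
  exl_rows <- ax$exl
  conj_rows <- ax$conj
  rsub_rows <- ax$rsub
  rchain_rows <- ax$rchain

  add_pairs <- function(role, from, to) {
    if (length(from) == 0L) return(FALSE)
    old <- P[[role]]
    key_old <- paste(old[, 1], old[, 2], sep = "\r")
    key_new <- paste(from, to, sep = "\r")
    fresh <- !(key_new %in% key_old) & !duplicated(key_new)
    if (!any(fresh)) return(FALSE)
    P[[role]] <<- rbind(old, cbind(from[fresh], to[fresh]))
    TRUE
  }

  repeat {
    changed <- FALSE
    for (x in classes) {
      sx <- S[[x]]
      # CR1: A' in S(X), A' SubClassOf B  =>  B in S(X)
      new <- unique(unlist(sub_by_sub[sx], use.names = FALSE))
      # CR2: A,B in S(X), A and B SubClassOf C  =>  C in S(X)
      if (nrow(conj_rows)) {
        hit <- conj_rows$a %in% sx & conj_rows$b %in% sx
        new <- c(new, conj_rows$sup[hit])
      }
      new <- setdiff(unique(new), c(sx, x))
      if (length(new)) {
        S[[x]] <- c(sx, new)
        changed <- TRUE
        sx <- S[[x]]
      }
      # CR3: A' in S(X), A' SubClassOf r some B  =>  (X,B) in R(r)
      for (a in intersect(sx, names(exr_by_sub))) {
        rows <- exr_by_sub[[a]]
        for (j in seq_len(nrow(rows))) {
          if (add_pairs(rows$role[j], x, rows$filler[j])) changed <- TRUE
        }
      }
    }
    # CR4 / CR5 over role pairs
    for (r in names(P)) {
      prs <- P[[r]]
      if (nrow(prs) == 0L) next
      exl_r <- exl_rows[exl_rows$role == r, ]
      for (k in seq_len(nrow(prs))) {
        x <- prs[k, 1]; y <- prs[k, 2]
        sy <- if (y == .BOTTOM) .BOTTOM else S[[y]]
        if (nrow(exl_r)) {
          sups <- exl_r$sup[exl_r$filler %in% sy]
          sups <- setdiff(unique(sups), S[[x]])
          if (length(sups)) {
            S[[x]] <- c(S[[x]], sups)
            changed <- TRUE
          }
        }
        if ((.BOTTOM %in% sy) && !(.BOTTOM %in% S[[x]])) {
          S[[x]] <- c(S[[x]], .BOTTOM)
          changed <- TRUE
        }
      }
      # CR10: role inclusion
      if (nrow(rsub_rows)) {
        for (s in rsub_rows$s[rsub_rows$r == r]) {
          if (add_pairs(s, prs[, 1], prs[, 2])) changed <- TRUE
        }
      }
    }
    # CR11: binary role chains r1 o r2 SubClassOf s
    for (k in seq_len(nrow(rchain_rows))) {
      p1 <- P[[rchain_rows$r1[k]]]; p2 <- P[[rchain_rows$r2[k]]]
      if (is.null(p1) || is.null(p2) || nrow(p1) == 0L || nrow(p2) == 0L) next
      for (i in seq_len(nrow(p1))) {
        m <- p2[, 1] == p1[i, 2]
        if (any(m)) {
          if (add_pairs(rchain_rows$s[k],
                        rep(p1[i, 1], sum(m)), p2[m, 2])) changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  unsat <- names(S)[vapply(S, function(s) .BOTTOM %in% s, logical(1))]
  structure(list(subsumers = S, unsatisfiable = unsat),
            class = "subsumption_index")
}

#' @export
print.subsumption_index <- function(x, ...) {
  cat(sprintf("<subsumption_index: %d classes, %d unsatisfiable>\n",
              length(x$subsumers), length(x$unsatisfiable)))
  invisible(x)
}

#' Classify an ontology (normalize + saturate)
#'
#' @inheritParams normalize_axioms
#' @return a `subsumption_index`.
#' @export
classify <- function(ont, queries = list(), relations = ont$relations) {
  saturate(normalize_axioms(ont, queries = queries, relations = relations))
}

#' Named subsumers of a class
#'
#' @param index a `subsumption_index`.
#' @param class class CURIE.
#' @return character vector of subsumers (reflexive), `character(0)` for an
#'   unknown class.
#' @export
subsumers <- function(index, class) {
  index$subsumers[[class]] %||% character(0)
}

#' Write a subsumption index as two-column TSV (debug aid)
#'
#' @param index a `subsumption_index`.
#' @param file optional output path.
#' @return the lines, invisibly when `file` is given.
#' @export
dump_subsumptions <- function(index, file = NULL) {
  lines <- unlist(lapply(sort(names(index$subsumers)), function(cls) {
    paste(cls, sort(index$subsumers[[cls]]), sep = "\t")
  }), use.names = FALSE)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

.QUERY_SUB <- "FRESHQ:sub"
.QUERY_SUP <- "FRESHQ:sup"
.QUERY_MSC <- "FRESHQ:msc"

#' Subsumption between two class expressions
#'
#' Introduces fresh classes equivalent to each expression, saturates, and
#' reads the index; sound and complete for the EL semantics of the supplied
#' axioms. An unsatisfiable subclass expression is subsumed by everything.
#'
#' @param sub,sup class expressions.
#' @param ont a [ontology()].
#' @param relations relation set; defaults to the ontology's.
#' @return logical.
#' @export
is_subsumed <- function(sub, sup, ont, relations = ont$relations) {
  idx <- classify(ont,
                  queries = stats::setNames(list(sub, sup),
                                            c(.QUERY_SUB, .QUERY_SUP)),
                  relations = relations)
  (.QUERY_SUB %in% idx$unsatisfiable) ||
    (.QUERY_SUP %in% subsumers(idx, .QUERY_SUB))
}

#' Satisfiability of a class expression
#'
#' @param expr a class expression.
#' @inheritParams is_subsumed
#' @return logical: `FALSE` when the expression entails `owl:Nothing` under
#'   the ontology's axioms (e.g. `occurs_in some <process>` given that the
#'   range of `occurs_in` is a continuant).
#' @export
is_satisfiable <- function(expr, ont, relations = ont$relations) {
  idx <- classify(ont, queries = stats::setNames(list(expr), .QUERY_SUB),
                  relations = relations)
  !(.QUERY_SUB %in% idx$unsatisfiable)
}

#' Most specific named classes subsuming an expression
#'
#' Returns the minimal elements, under the entailed subsumption order, of
#' the set of named (non-fresh, non-obsolete) ontology classes that subsume
#' the expression. Incomparable minima are all returned; equivalent minima
#' are all returned.
#'
#' @param expr a satisfiable class expression.
#' @inheritParams is_subsumed
#' @return character vector of class CURIEs.
#' @export
most_specific_classes <- function(expr, ont, relations = ont$relations) {
  idx <- classify(ont, queries = stats::setNames(list(expr), .QUERY_MSC),
                  relations = relations)
  if (.QUERY_MSC %in% idx$unsatisfiable) {
    goext_error("expression is unsatisfiable; no most specific class exists",
                "goext_unsatisfiable")
  }
  minimal_classes(subsumers(idx, .QUERY_MSC), idx, ont)
}

minimal_classes <- function(cand, idx, ont) {
  cand <- intersect(cand, ont$terms$id[!ont$terms$obsolete])
  keep <- vapply(cand, function(x) {
    !any(vapply(cand, function(y) {
      y != x && x %in% subsumers(idx, y) && !(y %in% subsumers(idx, x))
    }, logical(1)))
  }, logical(1))
  cand[keep]
}

# ---- Brute-force oracle ----------------------------------------------------

#' Brute-force subsumption over unnormalized axioms (test oracle)
#'
#' A naive iterate-to-fixpoint derivation implemented independently of
#' [saturate()]: it works directly on the told is_a, relationship,
#' genus-differentia equivalence, disjointness, category and range axioms,
#' with no normalization and no fresh names. Intended as an oracle for
#' small inputs; the class count is capped.
#'
#' @param ont a [ontology()].
#' @param queries optional named list of flat query classes, each
#'   `list(genus = CURIE, diffs = list of rel_expr)`; every query name is
#'   treated as a class equivalent to genus-and-differentia.
#' @param max_classes refuse larger ontologies (default 20 terms).
#' @return a `subsumption_index` over term ids and query names.
#' @export
brute_force_subsumption <- function(ont, queries = list(),
                                    max_classes = 20L) {
  if (nrow(ont$terms) > max_classes) {
    goext_error(sprintf("brute-force oracle capped at %d classes (got %d)",
                        max_classes, nrow(ont$terms)),
                "goext_size_error")
  }
  live_terms <- ont$terms$id[!ont$terms$obsolete]
  universe <- c(live_terms, .CONTINUANT, .OCCURRENT, names(queries))
  universe <- unique(universe)
  subs <- stats::setNames(lapply(universe, function(x) x), universe)
  unsat <- character(0)
  # x SubClassOf role some y, all named
  rels <- unique(rbind(
    data.frame(x = ont$relationship$child, role = ont$relationship$relation,
               y = ont$relationship$filler, stringsAsFactors = FALSE)
  ))
  rels <- rels[rels$x %in% universe, , drop = FALSE]

  eqs <- lapply(ont$equivalence, function(e) {
    list(defined = e$defined, genus = e$genus, diffs = e$differentia)
  })
  for (nm in names(queries)) {
    q <- queries[[nm]]
    diffs <- tibble::tibble(
      relation = vapply(q$diffs, function(e) e$relation, character(1)),
      filler = vapply(q$diffs, function(e) e$entity, character(1))
    )
    if (nrow(diffs) == 0L) {
      # bare named query: equivalent to its genus
      subs[[nm]] <- unique(c(subs[[nm]], q$genus))
      subs[[q$genus]] <- unique(c(subs[[q$genus]], nm))
    } else {
      eqs[[length(eqs) + 1L]] <- list(defined = nm, genus = q$genus,
                                      diffs = diffs)
    }
  }
  # chains declared on the relation set (expand composite relations in
  # differentia on the fly)
  chains <- list()
  for (rd in ont$relations) {
    if (length(rd$chain) == 2L) {
      chains[[length(chains) + 1L]] <- c(rd$chain, rd$label)
    }
  }
  expand_diff <- function(diffs) diffs  # composite relations kept symbolic
  ranges <- list()
  for (rd in ont$relations) {
    if (rd$range_category != "any") {
      ranges[[rd$label]] <- rd$range_category
    }
  }
  told_parents <- split(ont$subclass$parent, ont$subclass$child)
  cats <- ont$categories

  add_sub <- function(x, y) {
    if (!(y %in% subs[[x]])) {
      subs[[x]] <<- c(subs[[x]], y)
      TRUE
    } else FALSE
  }
  add_rel <- function(x, role, y) {
    hit <- rels$x == x & rels$role == role & rels$y == y
    if (!any(hit)) {
      rels[nrow(rels) + 1L, ] <<- list(x, role, y)
      TRUE
    } else FALSE
  }

  repeat {
    changed <- FALSE
    for (x in universe) {
      # told is_a closure + category links
      for (s in subs[[x]]) {
        for (p in told_parents[[s]] %||% character(0)) {
          if (p %in% universe && add_sub(x, p)) changed <- TRUE
        }
        cat_s <- cats[s]
        if (!is.na(cat_s)) {
          catc <- if (cat_s == "continuant") .CONTINUANT else .OCCURRENT
          if (add_sub(x, catc)) changed <- TRUE
        }
      }
      # transitive closure through derived subsumers
      for (s in setdiff(subs[[x]], x)) {
        if (s %in% universe) {
          for (t in subs[[s]]) if (add_sub(x, t)) changed <- TRUE
        }
      }
    }
    # equivalence, forward: defined SubClassOf genus and each existential
    for (eq in eqs) {
      d <- eq$defined
      if (!(d %in% universe)) next
      if (eq$genus %in% universe || TRUE) {
        if (add_sub(d, eq$genus)) changed <- TRUE
      }
      for (j in seq_len(nrow(eq$diffs))) {
        if (add_rel(d, eq$diffs$relation[j], eq$diffs$filler[j])) {
          changed <- TRUE
        }
      }
    }
    # inherit relational facts through subsumers
    for (x in universe) {
      for (s in setdiff(subs[[x]], x)) {
        hit <- which(rels$x == s)
        for (k in hit) {
          if (add_rel(x, rels$role[k], rels$y[k])) changed <- TRUE
        }
      }
    }
    # role chains: (x r1 y), (y r2 z), r1 o r2 -> s  =>  (x s z)
    for (ch in chains) {
      h1 <- which(rels$role == ch[1])
      for (k in h1) {
        h2 <- which(rels$x == rels$y[k] & rels$role == ch[2])
        for (k2 in h2) {
          if (add_rel(rels$x[k], ch[3], rels$y[k2])) changed <- TRUE
        }
      }
    }
    # equivalence, backward: X below genus with all differentia entailed
    for (eq in eqs) {
      d <- eq$defined
      for (x in universe) {
        if (d %in% subs[[x]]) next
        if (!(eq$genus %in% subs[[x]])) next
        ok <- TRUE
        for (j in seq_len(nrow(eq$diffs))) {
          r <- eq$diffs$relation[j]; f <- eq$diffs$filler[j]
          hit <- which(rels$x == x & rels$role == r)
          sat <- any(vapply(hit, function(k) {
            y <- rels$y[k]
            y == f || (y %in% universe && f %in% subs[[y]])
          }, logical(1)))
          if (!sat) { ok <- FALSE; break }
        }
        if (ok && add_sub(x, d)) changed <- TRUE
      }
    }
    # incoherence
    for (x in universe) {
      if (x %in% unsat) next
      bad <- FALSE
      dj <- ont$disjoint
      for (i in seq_len(nrow(dj))) {
        if (dj$a[i] %in% subs[[x]] && dj$b[i] %in% subs[[x]]) bad <- TRUE
      }
      if (.CONTINUANT %in% subs[[x]] && .OCCURRENT %in% subs[[x]]) bad <- TRUE
      hit <- which(rels$x == x)
      for (k in hit) {
        y <- rels$y[k]
        if (y %in% unsat) bad <- TRUE
        rng <- ranges[[rels$role[k]]]
        if (!is.null(rng) && y %in% universe) {
          wrong <- if (rng == "continuant") .OCCURRENT else .CONTINUANT
          if (wrong %in% subs[[y]]) bad <- TRUE
        }
      }
      for (s in subs[[x]]) if (s %in% unsat) bad <- TRUE
      if (bad) {
        unsat <- c(unsat, x)
        subs[[x]] <- unique(c(subs[[x]], .BOTTOM))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(list(subsumers = subs, unsatisfiable = unsat),
            class = "subsumption_index")
}
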