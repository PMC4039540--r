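# Test-only reader for the rendered OWL text form, used as a parse-back
# oracle for render_owl(): independent of the renderer, it tokenizes the
# Manchester-style string and rebuilds a nested structure that is compared
# against the source expression's shape.

read_owl_text <- function(s) {
  toks <- strsplit(trimws(gsub("([()])", " \\1 ", s)), "\\s+")[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  parse_unit <- function() {
    if (identical(peek(), "(")) {
      take()
      e <- parse_expr()
      stopifnot(identical(take(), ")"))
      return(e)
    }
    id <- take()
    if (identical(peek(), "some")) {
      take()
      return(list(type = "some", p = id, f = parse_unit()))
    }
    list(type = "named", id = id)
  }
  parse_expr <- function() {
    parts <- list(parse_unit())
    while (identical(peek(), "and")) {
      take()
      parts[[length(parts) + 1L]] <- parse_unit()
    }
    if (length(parts) == 1L) parts[[1]] else
      list(type = "and", ops = parts)
  }
  out <- parse_expr()
  stopifnot(is.na(peek()))
  out
}

# The shape a class_expr should have after rendering (underscored ids).
expr_shape <- function(e) {
  underscore <- function(x) sub(":", "_", x, fixed = TRUE)
  switch(e$type,
    named = list(type = "named", id = underscore(e$id)),
    some = list(type = "some", p = underscore(e$property),
                f = expr_shape(e$filler)),
    "and" = list(type = "and", ops = lapply(e$operands, expr_shape)))
}
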