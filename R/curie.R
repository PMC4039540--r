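# Compact identifiers (CURIEs) and shared error helpers.

# Reserved identifiers used by the reasoner and the fold procedure.
.BOTTOM <- "owl:Nothing"
.CONTINUANT <- "BFO:0000002"
.OCCURRENT <- "BFO:0000003"
.FRESH_PREFIX <- "FRESH"
.FOLD_PREFIX <- "GOX"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a CURIE to colon form
#'
#' Identifiers are held internally in the `Prefix:Local` form (e.g.
#' `GO:0005635`). The underscore form used in rendered OWL text
#' (`GO_0005635`) is accepted on input and converted.
#'
#' @param x character vector of identifiers.
#' @return character vector in canonical colon form.
#' @export
#' @examples
#' curie_normalize(c("GO_0005635", "CL:0000540"))
curie_normalize <- function(x) {
  fix <- !grepl(":", x, fixed = TRUE) & grepl("^[A-Za-z][A-Za-z0-9]*_.+$", x)
  x[fix] <- sub("_", ":", x[fix])
  x
}

# Underscore form, produced only by the OWL renderer.
curie_underscore <- function(x) sub(":", "_", x, fixed = TRUE)

# Property identifiers may be relation labels (part_of) or CURIEs; only the
# digit-local underscore form (BFO_0000050) is rewritten to colon form.
property_normalize <- function(x) {
  fix <- !grepl(":", x, fixed = TRUE) &
    grepl("^[A-Za-z][A-Za-z0-9]*_[0-9]+$", x)
  x[fix] <- sub("_", ":", x[fix])
  x
}

curie_prefix <- function(x) sub(":.*$", "", x)
curie_local <- function(x) sub("^[^:]*:", "", x)

is_curie <- function(x) grepl("^[^:[:space:]]+:[^:[:space:]]+$", x)

# Classed conditions so callers and tests can discriminate failure modes.
goext_error <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(class, "goext_error", "error")))
}

goext_warn <- function(msg, class = "goext_warning") {
  warning(warningCondition(msg, class = c(class, "goext_warning", "warning")))
}
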