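# GAF 2.0 / GAF 1.0 / GPAD annotation file I/O.
#
# Annotation records are held as a tibble with the 17 GAF 2.0 columns plus
# two GPAD passthrough columns, a parsed-extension list column, and the
# source column count. GAF 2.0 carries the extension in 1-based column 16;
# GPAD carries it in 1-based column 11. GAF 1.0 (15 columns) is read with an
# empty extension, so the format is backwards compatible.

.gaf_cols <- c(
  "db", "db_object_id", "db_object_symbol", "qualifier", "go_id",
  "db_reference", "evidence_code", "with_from", "aspect", "db_object_name",
  "db_object_synonym", "db_object_type", "taxon", "date", "assigned_by",
  "annotation_extension", "gene_product_form_id"
)

.gpad_cols <- c(
  "db", "db_object_id", "qualifier", "go_id", "db_reference",
  "evidence_code", "with_from", "interacting_taxon", "date", "assigned_by",
  "annotation_extension", "annotation_properties"
)

# 1-based positions of the extension field in each dialect.
.GAF_EXT_COL <- 16L
.GPAD_EXT_COL <- 11L

# Parse an extension string, returning NULL on grammar failure (the raw
# string is retained in annotation_extension; validate_annotations() reports
# the grammar error).
parse_ext_or_null <- function(s) {
  tryCatch(parse_extension_field(s), goext_error = function(e) NULL)
}

finish_records <- function(tbl, comments, errors) {
  tbl <- tibble::as_tibble(tbl)
  tbl$extension <- lapply(tbl$annotation_extension, parse_ext_or_null)
  attr(tbl, "comments") <- comments
  attr(tbl, "row_errors") <- errors
  class(tbl) <- c("goext_annotations", class(tbl))
  tbl
}

empty_records <- function() {
  cols <- c(.gaf_cols, "interacting_taxon", "annotation_properties")
  tbl <- tibble::as_tibble(stats::setNames(
    rep(list(character(0)), length(cols)), cols))
  tbl$source_ncol <- integer(0)
  tbl
}

#' Construct a single annotation record
#'
#' Convenience constructor used in examples and tests: builds a one-row
#' annotation table in the same shape as [read_gaf()] output. Unspecified
#' columns are empty strings.
#'
#' @param db,db_object_id,db_object_symbol,qualifier,go_id,db_reference
#'   GAF columns 1-6.
#' @param evidence_code,with_from,aspect,db_object_name,db_object_synonym
#'   GAF columns 7-11.
#' @param db_object_type,taxon,date,assigned_by GAF columns 12-15.
#' @param annotation_extension extension text for GAF column 16 (parsed on
#'   construction).
#' @param gene_product_form_id GAF column 17.
#' @return a one-row annotation tibble.
#' @export
#' @examples
#' r <- gaf_record(db = "PomBase", db_object_id = "SPBC17D11.06",
#'                 go_id = "GO:0019784", evidence_code = "IMP", aspect = "F",
#'                 annotation_extension = "has_direct_input(PomBase:SPAC17G6.12)")
#' n_expressions(r$extension[[1]])
gaf_record <- function(db = "", db_object_id = "", db_object_symbol = "",
                       qualifier = "", go_id = "", db_reference = "",
                       evidence_code = "", with_from = "", aspect = "",
                       db_object_name = "", db_object_synonym = "",
                       db_object_type = "protein", taxon = "", date = "",
                       assigned_by = "", annotation_extension = "",
                       gene_product_form_id = "") {
  tbl <- tibble::tibble(
    db = db, db_object_id = db_object_id,
    db_object_symbol = db_object_symbol, qualifier = qualifier,
    go_id = curie_normalize(go_id), db_reference = db_reference,
    evidence_code = evidence_code, with_from = with_from, aspect = aspect,
    db_object_name = db_object_name, db_object_synonym = db_object_synonym,
    db_object_type = db_object_type, taxon = taxon, date = date,
    assigned_by = assigned_by, annotation_extension = annotation_extension,
    gene_product_form_id = gene_product_form_id,
    interacting_taxon = "", annotation_properties = "",
    source_ncol = 17L
  )
  finish_records(tbl, comments = NULL, errors = empty_row_errors())
}

empty_row_errors <- function() {
  tibble::tibble(line = integer(0), message = character(0))
}

#' Bind annotation records row-wise
#'
#' Concatenates annotation tibbles (e.g. single records from
#' [gaf_record()]) into one corpus, re-deriving the parsed extension
#' column.
#'
#' @param ... annotation tibbles, or a single list of them.
#' @return an annotation tibble.
#' @export
bind_records <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  cols <- c(.gaf_cols, "interacting_taxon", "annotation_properties",
            "source_ncol")
  df <- do.call(rbind, lapply(parts, function(p) {
    as.data.frame(p[, cols], stringsAsFactors = FALSE)
  }))
  finish_records(tibble::as_tibble(df), comments = NULL,
                 errors = empty_row_errors())
}

#' Row-level errors collected while reading an annotation file
#'
#' @param records output of [read_gaf()] or [read_gpad()].
#' @return a tibble with columns `line` and `message`.
#' @export
annotation_errors <- function(records) {
  attr(records, "row_errors") %||% empty_row_errors()
}

read_annotation_lines <- function(file, text) {
  if (!is.null(text)) {
    if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
      text <- strsplit(text, "\n", fixed = TRUE)[[1]]
    }
    return(text)
  }
  if (!file.exists(file)) {
    goext_error(sprintf("cannot read annotation file '%s'", file),
                "goext_io_error")
  }
  readLines(file, warn = FALSE)
}

read_tabular_annotations <- function(lines, min_cols, ext_col, cols) {
  is_comment <- startsWith(lines, "!")
  is_blank <- !nzchar(trimws(lines))
  keep <- !is_comment & !is_blank
  comments <- lines[is_comment]
  data_lines <- lines[keep]
  line_no <- which(keep)

  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  bad <- nc < min_cols
  errors <- tibble::tibble(
    line = line_no[bad],
    message = sprintf("expected at least %d tab-separated columns, found %d",
                      min_cols, nc[bad])
  )
  parts <- parts[!bad]
  nc <- nc[!bad]

  n <- length(parts)
  get_col <- function(j) {
    vapply(parts, function(p) if (length(p) >= j) p[j] else "", character(1))
  }
  tbl <- stats::setNames(lapply(seq_along(cols), get_col), cols)
  tbl <- tibble::as_tibble(tbl)
  if (n == 0L) tbl <- tbl[0, ]
  list(tbl = tbl, nc = nc, comments = comments, errors = errors)
}

#' Read a GAF annotation file
#'
#' Reads GAF 2.0 (17 columns, extension at column 16) and GAF 1.0 (15
#' columns, empty extension) rows. Lines starting with `!` are comments and
#' are retained so that [write_gaf()] can round-trip the file byte for byte.
#' Rows with fewer than 15 columns are collected as row-level errors (see
#' [annotation_errors()]) and parsing continues. Extension strings that fail
#' the grammar are kept verbatim with a `NULL` parsed extension;
#' [validate_annotations()] reports them.
#'
#' @param file path to a GAF file.
#' @param text alternatively, the file content as a character vector of
#'   lines (or one string with embedded newlines).
#' @return an annotation tibble; one row per data line.
#' @export
read_gaf <- function(file = NULL, text = NULL) {
  lines <- read_annotation_lines(file, text)
  parsed <- read_tabular_annotations(lines, min_cols = 15L,
                                     ext_col = .GAF_EXT_COL, cols = .gaf_cols)
  tbl <- parsed$tbl
  tbl$go_id <- curie_normalize(tbl$go_id)
  tbl$interacting_taxon <- rep("", nrow(tbl))
  tbl$annotation_properties <- rep("", nrow(tbl))
  tbl$source_ncol <- parsed$nc
  finish_records(tbl, parsed$comments, parsed$errors)
}

#' Write annotation records as GAF 2.0
#'
#' Emits 17 tab-separated columns with the serialized extension at 1-based
#' column 16. Comment lines captured by [read_gaf()] are re-emitted verbatim;
#' otherwise a `!gaf-version: 2.0` header is written. `read_gaf()` composed
#' with `write_gaf()` is the identity on records.
#'
#' @param records an annotation tibble.
#' @param file optional output path; when `NULL` the lines are returned.
#' @return the output lines, invisibly when `file` is given.
#' @export
write_gaf <- function(records, file = NULL) {
  header <- attr(records, "comments") %||% "!gaf-version: 2.0"
  ext <- extension_strings(records)
  body <- character(0)
  if (nrow(records) > 0) {
    m <- as.matrix(records[, .gaf_cols])
    m[, "annotation_extension"] <- ext
    body <- apply(m, 1L, paste, collapse = "\t")
  }
  lines <- c(header, body)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

# Canonical extension text per record: the serialized parsed field when the
# grammar parse succeeded, the raw string otherwise.
extension_strings <- function(records) {
  if (nrow(records) == 0) return(character(0))
  mapply(function(f, raw) {
    if (is.null(f)) raw else serialize_extension_field(f)
  }, records$extension, records$annotation_extension, USE.NAMES = FALSE)
}

#' Read a GPAD annotation file
#'
#' GPAD rows carry 12 tab-separated columns with the extension at 1-based
#' column 11. Records are returned in the same tibble shape as [read_gaf()];
#' GAF-only columns (symbol, aspect, taxon, ...) are empty, and the GPAD-only
#' columns `interacting_taxon` and `annotation_properties` are passed through
#' verbatim.
#'
#' @inheritParams read_gaf
#' @return an annotation tibble.
#' @export
read_gpad <- function(file = NULL, text = NULL) {
  lines <- read_annotation_lines(file, text)
  parsed <- read_tabular_annotations(lines, min_cols = 10L,
                                     ext_col = .GPAD_EXT_COL,
                                     cols = .gpad_cols)
  tbl <- parsed$tbl
  tbl$go_id <- curie_normalize(tbl$go_id)
  for (col in setdiff(.gaf_cols, .gpad_cols)) {
    tbl[[col]] <- rep("", nrow(tbl))
  }
  tbl <- tbl[, c(.gaf_cols, "interacting_taxon", "annotation_properties")]
  tbl$source_ncol <- parsed$nc
  finish_records(tbl, parsed$comments, parsed$errors)
}

#' Write annotation records as GPAD
#'
#' Emits the 12 GPAD columns with the serialized extension at 1-based column
#' 11; the extension text is identical to the GAF column 16 text, so
#' converting between the two formats preserves extensions verbatim.
#'
#' @inheritParams write_gaf
#' @return the output lines, invisibly when `file` is given.
#' @export
write_gpad <- function(records, file = NULL) {
  header <- attr(records, "comments") %||% "!gpad-version: 1.2"
  body <- character(0)
  if (nrow(records) > 0) {
    m <- as.matrix(records[, .gpad_cols])
    m[, "annotation_extension"] <- extension_strings(records)
    body <- apply(m, 1L, paste, collapse = "\t")
  }
  lines <- c(header, body)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Split disjunctive extensions into independent annotations
#'
#' A pipe-separated extension is equivalent to multiple independent
#' annotations, one per alternative. Records whose extension has more than
#' one conjunction are expanded to one record per conjunction with every
#' other column unchanged; records with an empty (or single-conjunction)
#' extension pass through as-is. The multiset of conjunctions across the
#' corpus is conserved.
#'
#' @param records an annotation tibble.
#' @return an annotation tibble with one conjunction per record.
#' @export
split_disjunction <- function(records) {
  n_conj <- vapply(records$extension, function(f) {
    if (ext_is_empty(f)) 1L else n_conjunctions(f)
  }, integer(1))
  if (all(n_conj <= 1L)) return(records)
  idx <- rep(seq_len(nrow(records)), n_conj)
  out <- records[idx, ]
  which_conj <- unlist(lapply(n_conj, seq_len))
  new_ext <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    f <- records$extension[[idx[k]]]
    if (ext_is_empty(f)) {
      new_ext[k] <- list(f)
    } else {
      new_ext[[k]] <- extension_field(f$conjunctions[which_conj[k]])
    }
  }
  out$extension <- new_ext
  out$annotation_extension <- vapply(new_ext, function(f) {
    if (is.null(f)) "" else serialize_extension_field(f)
  }, character(1))
  attr(out, "comments") <- attr(records, "comments")
  attr(out, "row_errors") <- attr(records, "row_errors")
  out
}

#' Percentage of extended annotations
#'
#' `100 * extended / total`, rounded half away from zero to one decimal --
#' the rounding used in published per-species extension statistics (e.g.
#' 1902 extended of 29049 total is 6.5%).
#'
#' @param total,extended numeric vectors of annotation counts.
#' @return numeric vector of percentages with one decimal.
#' @export
#' @examples
#' percent_extended(29049, 1902)  # 6.5
percent_extended <- function(total, extended) {
  ifelse(total > 0, round_half_up(100 * extended / total, 1L), NA_real_)
}

# round() in R rounds half to even; published annotation statistics round
# half away from zero.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-taxon extension statistics
#'
#' Counts, per taxon (GAF column 13; the first pipe-separated value), the
#' total number of records and the number of extended records (at least one
#' conjunction in the extension field), with the percentage extended as
#' computed by [percent_extended()]. Records without a taxon are bucketed
#' under `"unknown"`.
#'
#' @param records an annotation tibble.
#' @return a tibble with columns `taxon`, `total`, `extended`, `percent`,
#'   ordered by decreasing `extended` count, ties by taxon.
#' @export
compute_extension_stats <- function(records) {
  if (nrow(records) == 0L) {
    return(tibble::tibble(taxon = character(0), total = integer(0),
                          extended = integer(0), percent = numeric(0)))
  }
  taxon <- sub("\\|.*$", "", records$taxon)
  taxon[!nzchar(taxon)] <- "unknown"
  extended <- vapply(records$extension,
                     function(f) !ext_is_empty(f), logical(1))
  total_by <- table(taxon)
  ext_by <- tapply(extended, taxon, sum)
  taxa <- names(total_by)
  out <- tibble::tibble(
    taxon = taxa,
    total = as.integer(total_by[taxa]),
    extended = as.integer(ext_by[taxa]),
    percent = percent_extended(as.integer(total_by[taxa]),
                               as.integer(ext_by[taxa]))
  )
  out[order(-out$extended, out$taxon), ]
}
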