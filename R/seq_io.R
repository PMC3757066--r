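# Sequence containers and aligned-FASTA I/O.
#
# Coordinate convention (package-wide): all positions, columns and intervals
# are 0-based, half-open [start, end), BED-style. 1-based values appear only
# in rendered reports.

.GAP <- "-"
.BASES <- c("A", "C", "G", "T")
.BASES5 <- c("A", "C", "G", "T", "-")

#' Create an ungapped sequence record
#'
#' A minimal container for one ungapped DNA sequence: an id and a residue
#' string over `{A,C,G,T}`.
#'
#' @param id Non-empty character scalar, unique within any collection.
#' @param residues Character scalar over `A`,`C`,`G`,`T` (uppercase), length
#'   at least 1.
#' @param provenance Optional list of key=value metadata (written into FASTA
#'   headers by [write_fasta()]).
#' @return An object of class `sequence_record`.
#' @export
sequence_record <- function(id, residues, provenance = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty character scalar")
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("'residues' must be a non-empty character scalar")
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), .BASES)
  if (length(bad))
    stop("illegal characters in ungapped sequence: ", paste(bad, collapse = ", "))
  structure(list(id = id, residues = residues, provenance = provenance),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d bp)\n", x$id, nchar(x$residues)))
  invisible(x)
}

# Accept a sequence_record or a bare string; return list(id, seq).
.as_seq <- function(x, id = "seq") {
  if (inherits(x, "sequence_record")) list(id = x$id, seq = x$residues)
  else if (is.character(x) && length(x) == 1L) list(id = id, seq = x)
  else stop("expected a sequence_record or a character scalar")
}

#' Construct a gapped alignment
#'
#' Validates and wraps a set of equal-length rows over `{A,C,G,T,-}`.
#' `-` is the only accepted gap character; IUPAC ambiguity codes and `.` are
#' rejected rather than silently mapped.
#'
#' @param ids Character vector of unique, non-empty record ids.
#' @param rows Character vector of rows, same length as `ids`; all rows must
#'   have equal width and no column may be all-gap.
#' @return An object of class `gapped_alignment` with elements `ids`, `rows`
#'   (named by id) and `n_cols`.
#' @export
gapped_alignment <- function(ids, rows) {
  if (length(ids) != length(rows) || length(ids) == 0L)
    stop("'ids' and 'rows' must be non-empty and of equal length")
  if (anyDuplicated(ids) || any(!nzchar(ids)))
    stop("record ids must be unique and non-empty")
  w <- nchar(rows)
  if (length(unique(w)) != 1L)
    stop("alignment-length error: rows have unequal lengths (",
         paste(unique(w), collapse = ", "), ")")
  bad <- setdiff(unique(unlist(strsplit(rows, ""))), .BASES5)
  if (length(bad))
    stop("alphabet error: illegal characters in alignment: ",
         paste(bad, collapse = ", "),
         " (only A,C,G,T,'-' are accepted; IUPAC ambiguity codes are rejected)")
  m <- .rows_matrix(rows)
  if (any(colSums(m != .GAP) == 0L))
    stop("alignment contains an all-gap column")
  names(rows) <- ids
  structure(list(ids = ids, rows = rows, n_cols = unname(w[1L])),
            class = "gapped_alignment")
}

.rows_matrix <- function(rows) {
  matrix(unlist(strsplit(rows, "")), nrow = length(rows), byrow = TRUE)
}

# character matrix (rows = records, named) of an alignment
aln_matrix <- function(aln) {
  m <- .rows_matrix(aln$rows)
  rownames(m) <- aln$ids
  m
}

#' @export
print.gapped_alignment <- function(x, ...) {
  cat(sprintf("<gapped_alignment> %d records x %d columns\n",
              length(x$ids), x$n_cols))
  invisible(x)
}

.aln_row <- function(aln, id) {
  if (!id %in% aln$ids) stop("unknown record id: ", id)
  unname(aln$rows[[id]])
}

#' Remove gap characters from a row
#' @param x Character scalar (gapped row).
#' @return The ungapped string.
#' @export
degap <- function(x) gsub(.GAP, "", x, fixed = TRUE)

#' Read an aligned FASTA file
#'
#' Parses an aligned multi-FASTA where `-` is the only gap character.
#' Lowercase input is uppercased with a warning; ragged rows and characters
#' outside `{A,C,G,T,-}` are errors. Record order is preserved.
#'
#' @param path Path to an aligned FASTA file.
#' @return A [gapped_alignment()].
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  rows <- as.character(ss)
  ids <- sub("\\s.*$", "", names(ss))
  if (any(rows != toupper(rows))) {
    warning("lowercase characters uppercased on read")
    rows <- toupper(rows)
  }
  gapped_alignment(ids, unname(rows))
}

#' Write an alignment (or ungapped records) as FASTA
#'
#' @param aln A `gapped_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "gapped_alignment"))
  ss <- Biostrings::BStringSet(aln$rows)
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_alignment
#' @param records A list of [sequence_record()]s (or one record). Provenance
#'   metadata, when present, is appended to headers as `key=value` pairs.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "sequence_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$residues, character(1))
  hdr <- vapply(records, function(r) {
    if (is.null(r$provenance) || !length(r$provenance)) return(r$id)
    kv <- paste(names(r$provenance),
                vapply(r$provenance, function(v) paste(v, collapse = ","),
                       character(1)),
                sep = "=", collapse = " ")
    paste(r$id, kv)
  }, character(1))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Map an alignment column to an ungapped position
#'
#' The position is the number of non-gap characters strictly before `col` in
#' the record's row. If the row carries a gap at `col`, `NA_integer_` is
#' returned as the gap marker.
#'
#' @param aln A `gapped_alignment`.
#' @param id Record id.
#' @param col 0-based column index, `0 <= col < n_cols`.
#' @return 0-based ungapped position, or `NA_integer_` for a gap.
#' @export
column_to_position <- function(aln, id, col) {
  row <- .aln_row(aln, id)
  if (col < 0L || col >= aln$n_cols) stop("column out of range: ", col)
  ch <- strsplit(row, "")[[1]]
  if (ch[col + 1L] == .GAP) return(NA_integer_)
  as.integer(sum(ch[seq_len(col)] != .GAP))
}

#' Map an ungapped position to its alignment column
#'
#' Inverse of [column_to_position()] on non-gap columns.
#'
#' @inheritParams column_to_position
#' @param pos 0-based ungapped position in the record.
#' @return 0-based alignment column.
#' @export
position_to_column <- function(aln, id, pos) {
  cols <- nongap_columns(aln, id)
  if (pos < 0L || pos >= length(cols)) stop("position out of range: ", pos)
  cols[pos + 1L]
}

#' Non-gap columns of one record
#'
#' @inheritParams column_to_position
#' @return Integer vector of 0-based columns; element `p + 1` is the column
#'   holding ungapped position `p` (a full coordinate map).
#' @export
nongap_columns <- function(aln, id) {
  ch <- strsplit(.aln_row(aln, id), "")[[1]]
  which(ch != .GAP) - 1L
}

# number of non-gap characters of `row` (a char vector) in columns < col
.pos_before <- function(chars, col) as.integer(sum(chars[seq_len(col)] != .GAP))
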