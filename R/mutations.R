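# Derived-mutation calling between a reconstructed ancestor row and an
# allele row, event collapsing, labeling, and counting.
#
# Events are returned as a data.frame, one row per event, with 0-based
# half-open alignment-column spans plus ungapped anchor positions in both
# the ancestor frame (`anc_pos`, used to apply the event) and the allele
# frame (`allele_pos`).

#' Call derived mutation events between two aligned rows
#'
#' Compares an ancestor row to an allele row column by column. Maximal runs
#' of columns where exactly one side is gapped collapse to a single
#' insertion/deletion event; columns where both sides carry different bases
#' become one substitution each; runs of different kinds are never merged,
#' even when adjacent. Applying all returned events to the ungapped ancestor
#' (see [apply_events()]) reproduces the ungapped allele exactly.
#'
#' @param ancestor_row,allele_row Gapped rows of equal length over
#'   `{A,C,G,T,-}`.
#' @return A data.frame with columns `kind` (`substitution`, `insertion`,
#'   `deletion`), `col_start`, `col_end` (0-based half-open alignment span),
#'   `ancestral`, `derived` (possibly empty strings), `anc_pos`, `allele_pos`
#'   (0-based ungapped anchors), `label`, `region` (`NA` until
#'   [assign_labels()]). Sorted by `col_start`.
#' @export
call_mutations <- function(ancestor_row, allele_row) {
  if (nchar(ancestor_row) != nchar(allele_row))
    stop("rows have unequal lengths")
  a <- strsplit(ancestor_row, "")[[1]]
  b <- strsplit(allele_row, "")[[1]]
  cls <- rep("match", length(a))
  cls[a != .GAP & b == .GAP] <- "del"
  cls[a == .GAP & b != .GAP] <- "ins"
  cls[a == .GAP & b == .GAP] <- "bothgap"
  cls[a != .GAP & b != .GAP & a != b] <- "sub"

  ev <- list()
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (v %in% c("match", "bothgap")) next
    s <- starts[k]; e <- ends[k]
    if (v == "sub") {
      for (j in s:e) {
        ev[[length(ev) + 1L]] <- data.frame(
          kind = "substitution", col_start = j - 1L, col_end = j,
          ancestral = a[j], derived = b[j],
          anc_pos = .pos_before(a, j - 1L), allele_pos = .pos_before(b, j - 1L),
          stringsAsFactors = FALSE)
      }
    } else {
      anc <- if (v == "del") paste(a[s:e], collapse = "") else ""
      der <- if (v == "ins") paste(b[s:e], collapse = "") else ""
      ev[[length(ev) + 1L]] <- data.frame(
        kind = if (v == "del") "deletion" else "insertion",
        col_start = s - 1L, col_end = e,
        ancestral = anc, derived = der,
        anc_pos = .pos_before(a, s - 1L), allele_pos = .pos_before(b, s - 1L),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(kind = character(), col_start = integer(), col_end = integer(),
               ancestral = character(), derived = character(),
               anc_pos = integer(), allele_pos = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$col_start), , drop = FALSE]
  rownames(out) <- NULL
  out$label <- rep(NA_character_, nrow(out))
  out$region <- rep(NA_character_, nrow(out))
  out
}

# "A","B",...,"Z","AA","AB",... for arbitrarily many core events
.letter_labels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(n)]
}

#' Label mutation events by region
#'
#' Events whose start column falls inside the core interval are lettered
#' `A`, `B`, `C`, ... in column order; flank events are numbered `1`, `2`,
#' ... in column order. An indel keeps a single label regardless of length.
#'
#' @param events Event data.frame from [call_mutations()].
#' @param core Length-2 integer vector: the core interval in alignment
#'   columns, 0-based half-open.
#' @return The events with `label` and `region` filled in.
#' @export
assign_labels <- function(events, core) {
  stopifnot(length(core) == 2L, core[1] < core[2])
  if (nrow(events) == 0L) return(events)
  events <- events[order(events$col_start), , drop = FALSE]
  if (any(events$col_start[-1L] < events$col_end[-nrow(events)]))
    stop("overlapping events cannot be labeled")
  in_core <- events$col_start >= core[1] & events$col_start < core[2]
  events$region <- ifelse(in_core, "core", "flank")
  events$label[in_core] <- .letter_labels(sum(in_core))
  events$label[!in_core] <- as.character(seq_len(sum(!in_core)))
  rownames(events) <- NULL
  events
}

#' Count mutation events by kind
#'
#' Indel events are counted once regardless of length.
#'
#' @param events Event data.frame.
#' @return A list with `substitutions`, `indels`, `total`.
#' @export
count_mutations <- function(events) {
  subs <- sum(events$kind == "substitution")
  ind <- sum(events$kind %in% c("insertion", "deletion"))
  list(substitutions = subs, indels = ind, total = subs + ind)
}

#' Write a mutation catalogue as TSV
#'
#' One row per (allele, event), with both 0-based machine coordinates and the
#' 1-based rendered position.
#'
#' @param catalogues Named list of event data.frames (names = allele ids).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mutation_catalog <- function(catalogues, path) {
  rows <- lapply(names(catalogues), function(id) {
    ev <- catalogues[[id]]
    if (nrow(ev) == 0L) return(NULL)
    data.frame(allele_id = id, label = ev$label, kind = ev$kind,
               col_start = ev$col_start, col_end = ev$col_end,
               allele_pos = ev$allele_pos,
               ancestral = ev$ancestral, derived = ev$derived,
               region = ev$region, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(allele_id = character(), label = character(),
                      kind = character(), col_start = integer(),
                      col_end = integer(), allele_pos = integer(),
                      ancestral = character(), derived = character(),
                      region = character(), stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
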