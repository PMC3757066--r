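# In-silico construct design: chimeric region swaps, single-mutation
# substitutions into the ancestor, targeted transversion scrambles, and
# sub-deletions sliced out of a parent deletion event.

#' Build a chimeric sequence by swapping aligned regions
#'
#' Within each swap interval (alignment columns) the donor row replaces the
#' backbone row; outside, the backbone is retained. The output is the
#' ungapped chimera, with provenance (backbone, donor, intervals) recorded.
#'
#' @param aln A [gapped_alignment()].
#' @param backbone_id,donor_id Record ids.
#' @param intervals List of length-2 integer vectors, 0-based half-open
#'   column intervals; must be disjoint and within bounds. An empty list
#'   returns the ungapped backbone.
#' @param id Id for the resulting record.
#' @return A [sequence_record()].
#' @export
swap_region <- function(aln, backbone_id, donor_id, intervals,
                        id = paste0(backbone_id, "_chimera")) {
  bb <- strsplit(.aln_row(aln, backbone_id), "")[[1]]
  dn <- strsplit(.aln_row(aln, donor_id), "")[[1]]
  if (length(intervals)) {
    iv <- do.call(rbind, lapply(intervals, function(x) as.integer(x)))
    if (any(iv[, 1] < 0L) || any(iv[, 2] > aln$n_cols) || any(iv[, 1] >= iv[, 2]))
      stop("swap interval out of bounds")
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1L, 1] < iv[-nrow(iv), 2]))
      stop("swap intervals overlap")
    for (k in seq_len(nrow(iv))) {
      idx <- (iv[k, 1] + 1L):iv[k, 2]
      bb[idx] <- dn[idx]
    }
  }
  sequence_record(id, degap(paste(bb, collapse = "")),
                  provenance = list(backbone = backbone_id, donor = donor_id,
                                    swaps = vapply(intervals, function(x)
                                      sprintf("%d-%d", x[1], x[2]), character(1))))
}

#' Apply one mutation event to an ungapped sequence
#'
#' Substitutes, inserts, or deletes at the event's ungapped anchor position
#' (`anc_pos`). The event's ancestral string must match the sequence at that
#' position, otherwise the function refuses to apply it.
#'
#' @param seq A [sequence_record()] or character scalar (ungapped).
#' @param event A single-row event data.frame (one row of
#'   [call_mutations()] output).
#' @return The edited sequence, same type as the input (`sequence_record`
#'   inputs keep their id and gain provenance).
#' @export
apply_event <- function(seq, event) {
  sq <- .as_seq(seq)
  s <- sq$seq
  if (nrow(event) != 1L) stop("'event' must be a single event row")
  pos <- event$anc_pos
  anc <- event$ancestral
  der <- event$derived
  if (pos < 0L || pos + nchar(anc) > nchar(s))
    stop("event position out of range")
  have <- substr(s, pos + 1L, pos + nchar(anc))
  if (nchar(anc) && have != anc)
    stop(sprintf("ancestral-state mismatch at position %d: expected '%s', found '%s'",
                 pos, anc, have))
  out <- paste0(substr(s, 1L, pos), der,
                substr(s, pos + nchar(anc) + 1L, nchar(s)))
  if (inherits(seq, "sequence_record")) {
    prov <- c(seq$provenance,
              list(applied = sprintf("%s@%d:%s>%s", event$kind, pos,
                                     anc, der)))
    sequence_record(seq$id, out, provenance = prov)
  } else out
}

#' Apply a set of events to an ungapped sequence
#'
#' Events are applied in decreasing anchor order so earlier coordinates are
#' unaffected by length changes; for non-overlapping events (as produced by
#' [call_mutations()]) the result is order-independent and reproduces the
#' allele the events were called from.
#'
#' @inheritParams apply_event
#' @param events Event data.frame.
#' @return The edited sequence (same type as input).
#' @export
apply_events <- function(seq, events) {
  if (nrow(events) == 0L) return(seq)
  ord <- order(-events$anc_pos, -events$col_start)
  for (i in ord) seq <- apply_event(seq, events[i, , drop = FALSE])
  seq
}

#' Non-complementary transversion scramble
#'
#' Replaces the base at each selected position by its non-complementary
#' transversion (`A -> C`, `C -> A`, `G -> T`, `T -> G`), leaving every other
#' position untouched. The edited base is never equal to the original or to
#' its complement.
#'
#' @param seq A [sequence_record()] or character scalar (ungapped).
#' @param interval Length-2 integer vector, 0-based half-open window on the
#'   sequence the positions refer to; default the whole sequence.
#' @param positions Integer vector of 1-based base-pair offsets within
#'   `interval` (so `c(2, 4, 6, 8)` edits the 2nd, 4th, 6th and 8th base
#'   pairs of the window).
#' @return The scrambled sequence, same type as the input.
#' @export
scramble_transversions <- function(seq, interval = NULL, positions) {
  sq <- .as_seq(seq)
  s <- strsplit(sq$seq, "")[[1]]
  if (is.null(interval)) interval <- c(0L, length(s))
  stopifnot(length(interval) == 2L, interval[1] >= 0L,
            interval[2] <= length(s), interval[1] < interval[2])
  width <- interval[2] - interval[1]
  if (any(positions < 1L | positions > width))
    stop("position out of range of the interval")
  idx <- interval[1] + positions              # 1-based index into s
  map <- c(A = "C", C = "A", G = "T", T = "G")
  s[idx] <- unname(map[s[idx]])
  out <- paste(s, collapse = "")
  if (inherits(seq, "sequence_record"))
    sequence_record(seq$id, out,
                    provenance = c(seq$provenance,
                                   list(scrambled = paste(idx - 1L, collapse = ","))))
  else out
}

#' Slice a sub-deletion out of a parent deletion event
#'
#' Derives a new, shorter deletion event covering bases `from` (inclusive)
#' to `to` (exclusive) of the parent deletion's ancestral string — e.g. an
#' 8-bp deletion of the first eight bases of a 9-bp parent, or a 1-bp
#' deletion of only its last base.
#'
#' @param event A single-row deletion event.
#' @param from,to 0-based half-open range within the parent's ancestral
#'   string.
#' @return A single-row deletion event data.frame.
#' @export
slice_deletion <- function(event, from, to) {
  if (nrow(event) != 1L || event$kind != "deletion")
    stop("'event' must be a single deletion event")
  len <- nchar(event$ancestral)
  stopifnot(from >= 0L, to <= len, from < to)
  data.frame(kind = "deletion",
             col_start = event$col_start + from,
             col_end = event$col_start + to,
             ancestral = substr(event$ancestral, from + 1L, to),
             derived = "",
             anc_pos = event$anc_pos + from,
             allele_pos = event$allele_pos,
             label = NA_character_, region = NA_character_,
             stringsAsFactors = FALSE)
}
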