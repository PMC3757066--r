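# IUPAC consensus binding-site annotation: scanning, ancestor/allele site
# diffing, mutation-site overlap, and post-edit re-evaluation.
#
# Sites are consensus matches, not affinity-scored hits: a "lost" call means
# the mapped window no longer matches the consensus; reduced-affinity but
# still-consensus cases are conserved here and can be flagged with
# evaluate_site_after_edit().

.IUPAC <- Biostrings::IUPAC_CODE_MAP

#' Define an IUPAC consensus motif
#'
#' @param name Motif name (e.g. `"ABD-B"`).
#' @param consensus Non-empty IUPAC consensus string
#'   (codes `ACGTRYSWKMBDHVN`).
#' @return An object of class `motif`.
#' @export
motif <- function(name, consensus) {
  stopifnot(is.character(name), nzchar(name))
  consensus <- toupper(consensus)
  bad <- setdiff(unique(strsplit(consensus, "")[[1]]), names(.IUPAC))
  if (!nzchar(consensus) || length(bad))
    stop("invalid IUPAC code in consensus: ", paste(bad, collapse = ", "))
  structure(list(name = name, consensus = consensus), class = "motif")
}

#' Default motifs for the dimorphic element
#'
#' The empirically derived consensus motifs for the Hox factor ABD-B
#' (`TTTAY`) and the sex-determination factor DSX (`RNNACWAWGTNNY`).
#'
#' @return A named list of [motif()]s.
#' @export
default_motifs <- function() {
  list(`ABD-B` = motif("ABD-B", "TTTAY"),
       DSX = motif("DSX", "RNNACWAWGTNNY"))
}

#' Reverse complement of a DNA/IUPAC string
#' @param x Character scalar.
#' @return Reverse-complemented string (IUPAC-aware).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# does `window` (plain ACGT) match `consensus` (IUPAC) exactly, full length?
.matches_consensus <- function(window, consensus) {
  if (nchar(window) != nchar(consensus)) return(FALSE)
  w <- strsplit(window, "")[[1]]
  k <- strsplit(consensus, "")[[1]]
  all(mapply(function(a, b) grepl(a, .IUPAC[[b]], fixed = TRUE), w, k))
}

#' Scan a sequence for IUPAC consensus motif matches
#'
#' Reports every window matching the consensus, with IUPAC codes read as
#' character classes. Overlapping matches are allowed; minus-strand matches
#' are mapped to forward coordinates, and an interval matching on both
#' strands is reported once per strand.
#'
#' @param seq A [sequence_record()] or ungapped character scalar.
#' @param motif A [motif()].
#' @param strands `"both"` (default) or `"forward"`.
#' @return A data.frame of sites: `seq_id`, `start`, `end` (0-based
#'   half-open, forward coordinates), `strand`, `matched` (forward-strand
#'   slice), `motif_name`.
#' @export
scan_motif <- function(seq, motif, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  stopifnot(inherits(motif, "motif"))
  sq <- .as_seq(seq)
  subject <- Biostrings::DNAString(sq$seq)
  L <- nchar(motif$consensus)
  hit <- function(pattern, strand) {
    if (nchar(sq$seq) < L) return(NULL)
    m <- Biostrings::matchPattern(pattern, subject, fixed = FALSE)
    if (length(m) == 0L) return(NULL)
    st <- Biostrings::start(m) - 1L
    data.frame(seq_id = sq$id, start = st, end = st + L, strand = strand,
               matched = substring(sq$seq, st + 1L, st + L),
               motif_name = motif$name, stringsAsFactors = FALSE)
  }
  out <- hit(motif$consensus, "+")
  if (strands == "both")
    out <- rbind(out, hit(revcomp(motif$consensus), "-"))
  if (is.null(out))
    out <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      strand = character(), matched = character(),
                      motif_name = character(), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# check a window against consensus on the given strand
.window_matches <- function(window, consensus, strand) {
  if (strand == "-") consensus <- revcomp(consensus)
  .matches_consensus(window, consensus)
}

#' Call binding-site conservation, loss and gain between ancestor and allele
#'
#' Every ancestor site is mapped through the alignment columns onto the
#' allele; it is `conserved` if the allele's ungapped window still matches
#' the consensus (on the site's strand), `lost` otherwise. Allele windows
#' that match where the corresponding ancestor window does not are reported
#' as `gained` (allele-frame coordinates).
#'
#' @param recon An [fitch_reconstruct()] result (supplies the ancestor row).
#' @param aln The `gapped_alignment` the reconstruction was computed from.
#' @param allele_id Allele record id.
#' @param motifs List of [motif()]s (default [default_motifs()]).
#' @param strands Passed to [scan_motif()].
#' @return A data.frame: `motif_name`, `status`
#'   (`conserved`/`lost`/`gained`), `allele_id`, `frame` (`ancestor` for
#'   conserved/lost, `allele` for gained), `start`, `end`, `strand`,
#'   `matched`.
#' @export
diff_sites <- function(recon, aln, allele_id, motifs = default_motifs(),
                       strands = "both") {
  stopifnot(inherits(recon, "ancestral_reconstruction"))
  anc_row <- strsplit(recon$consensus, "")[[1]]
  all_row <- strsplit(.aln_row(aln, allele_id), "")[[1]]
  if (length(anc_row) != length(all_row))
    stop("reconstruction and alignment disagree on column count")
  anc_seq <- degap(recon$consensus)
  all_seq <- degap(paste(all_row, collapse = ""))
  anc_cols <- which(anc_row != .GAP)          # 1-based cols of ancestor pos p = anc_cols[p+1]
  all_cols <- which(all_row != .GAP)

  # cumulative ungapped-position maps, per column
  all_ungap_before <- cumsum(all_row != .GAP)
  anc_ungap_before <- cumsum(anc_row != .GAP)

  res <- list()
  for (m in motifs) {
    anc_sites <- scan_motif(sequence_record("ancestor", anc_seq), m, strands)
    all_sites <- scan_motif(sequence_record(allele_id, all_seq), m, strands)
    # ancestor -> allele: conserved / lost
    for (i in seq_len(nrow(anc_sites))) {
      s <- anc_sites$start[i]; e <- anc_sites$end[i]
      c0 <- anc_cols[s + 1L]; c1 <- anc_cols[e]
      a0 <- if (c0 > 1L) all_ungap_before[c0 - 1L] else 0L
      a1 <- all_ungap_before[c1]
      win <- substr(all_seq, a0 + 1L, a1)
      ok <- .window_matches(win, m$consensus, anc_sites$strand[i])
      res[[length(res) + 1L]] <- data.frame(
        motif_name = m$name, status = if (ok) "conserved" else "lost",
        allele_id = allele_id, frame = "ancestor",
        start = s, end = e, strand = anc_sites$strand[i],
        matched = anc_sites$matched[i], stringsAsFactors = FALSE)
    }
    # allele -> ancestor: gained
    for (i in seq_len(nrow(all_sites))) {
      s <- all_sites$start[i]; e <- all_sites$end[i]
      c0 <- all_cols[s + 1L]; c1 <- all_cols[e]
      a0 <- if (c0 > 1L) anc_ungap_before[c0 - 1L] else 0L
      a1 <- anc_ungap_before[c1]
      win <- substr(anc_seq, a0 + 1L, a1)
      if (!.window_matches(win, m$consensus, all_sites$strand[i]))
        res[[length(res) + 1L]] <- data.frame(
          motif_name = m$name, status = "gained",
          allele_id = allele_id, frame = "allele",
          start = s, end = e, strand = all_sites$strand[i],
          matched = all_sites$matched[i], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(motif_name = character(), status = character(),
               allele_id = character(), frame = character(),
               start = integer(), end = integer(), strand = character(),
               matched = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Intersect mutation events with binding sites
#'
#' Events and sites must be in the same ungapped sequence frame: events are
#' placed at `[anc_pos, anc_pos + nchar(ancestral))` (so insertions, which
#' occupy no ancestral bases, never overlap). Every pair with a nonempty
#' intersection is reported with its length in bp.
#'
#' @param events Event data.frame (ancestor-frame anchors).
#' @param sites Site data.frame from [scan_motif()] on the ungapped ancestor.
#' @return A data.frame: `label`, `kind`, `event_start`, `event_end`,
#'   `motif_name`, `site_start`, `site_end`, `overlap_bp`.
#' @export
overlap_events_sites <- function(events, sites) {
  res <- list()
  for (i in seq_len(nrow(events))) {
    e0 <- events$anc_pos[i]
    e1 <- e0 + nchar(events$ancestral[i])
    for (j in seq_len(nrow(sites))) {
      s0 <- sites$start[j]; s1 <- sites$end[j]
      ov <- min(e1, s1) - max(e0, s0)
      if (ov > 0L)
        res[[length(res) + 1L]] <- data.frame(
          label = events$label[i], kind = events$kind[i],
          event_start = e0, event_end = e1,
          motif_name = sites$motif_name[j],
          site_start = s0, site_end = s1,
          overlap_bp = ov, stringsAsFactors = FALSE)
    }
  }
  if (length(res)) {
    out <- do.call(rbind, res); rownames(out) <- NULL; out
  } else
    data.frame(label = character(), kind = character(),
               event_start = integer(), event_end = integer(),
               motif_name = character(), site_start = integer(),
               site_end = integer(), overlap_bp = integer(),
               stringsAsFactors = FALSE)
}

#' Does a binding site still match its consensus after an edit?
#'
#' Applies the event to the sequence and re-evaluates the consensus at the
#' site's shifted window. When the event starts before the site, the window
#' is anchored at the site's (shifted) end — so a deletion clipping the
#' site's first bases recruits the surviving upstream sequence, the geometry
#' under which a deletion ending one bp into a site can leave a window that
#' still matches. Events starting at or after the site's start leave the
#' window anchored at the site's start.
#'
#' @param seq Ungapped ancestor sequence ([sequence_record()] or string).
#' @param event Single-row event data.frame (must apply cleanly to `seq`).
#' @param site Single site row (from [scan_motif()] on `seq`).
#' @param motif The site's [motif()].
#' @return `TRUE` if the shifted window still matches the consensus.
#' @export
evaluate_site_after_edit <- function(seq, event, site, motif) {
  sq <- .as_seq(seq)
  edited <- apply_event(sq$seq, event)
  L <- nchar(motif$consensus)
  d0 <- event$anc_pos
  d1 <- d0 + nchar(event$ancestral)
  net <- nchar(event$derived) - nchar(event$ancestral)
  mapfwd <- function(p) if (p <= d0) p else if (p >= d1) p + net else d0
  if (d0 < site$start) {
    new_end <- mapfwd(site$end)
    new_start <- new_end - L
  } else {
    new_start <- site$start
    new_end <- new_start + L
  }
  if (new_start < 0L || new_end > nchar(edited)) return(FALSE)
  win <- substr(edited, new_start + 1L, new_end)
  .window_matches(win, motif$consensus, site$strand)
}

#' Write motif sites as BED6
#'
#' 0-based half-open intervals, `name` = motif name, `score` = 0.
#'
#' @param sites Site data.frame from [scan_motif()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$seq_id, start = sites$start,
                    end = sites$end, name = sites$motif_name,
                    score = rep(0L, nrow(sites)),
                    strand = sites$strand, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
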