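# In-silico restriction digestion, RFLP marker discovery, genotype calling
# from fragment patterns, and Mendelian segregation testing.
#
# Fragment lengths follow the gel convention: cuts are placed at the
# top-strand cut coordinate only; sticky-end overhangs are not modeled.

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param recognition IUPAC recognition sequence.
#' @param cut_offset_top 0-based offset of the top-strand cut within the
#'   recognition site, `0 <= offset <= nchar(recognition)`.
#' @return An object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset_top) {
  stopifnot(is.character(name), nzchar(name))
  recognition <- toupper(recognition)
  bad <- setdiff(unique(strsplit(recognition, "")[[1]]), names(.IUPAC))
  if (length(bad)) stop("invalid IUPAC code in recognition site: ",
                        paste(bad, collapse = ", "))
  cut_offset_top <- as.integer(cut_offset_top)
  if (cut_offset_top < 0L || cut_offset_top > nchar(recognition))
    stop("cut offset outside the recognition site")
  structure(list(name = name, recognition = recognition,
                 cut_offset_top = cut_offset_top),
            class = "restriction_enzyme")
}

#' BstXI (CCANNNNNN^TGG, top-strand cut after position 8)
#' @return A [restriction_enzyme()].
#' @export
bstxi <- function() restriction_enzyme("BstXI", "CCANNNNNNTGG", 8L)

#' Find restriction-enzyme recognition sites
#'
#' Scans the forward strand for IUPAC matches of the recognition sequence;
#' when the recognition is not its own reverse complement, the minus strand
#' is scanned too and mapped to forward coordinates.
#'
#' @param seq A [sequence_record()] or ungapped character scalar.
#' @param enzyme A [restriction_enzyme()].
#' @return A data.frame with `start` (0-based site start) and `strand`,
#'   sorted by start.
#' @export
find_enzyme_sites <- function(seq, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  sq <- .as_seq(seq)
  m <- scan_motif(sequence_record(sq$id, sq$seq),
                  motif(enzyme$name, enzyme$recognition),
                  strands = if (revcomp(enzyme$recognition) ==
                                enzyme$recognition) "forward" else "both")
  data.frame(start = m$start, strand = m$strand, stringsAsFactors = FALSE)
}

#' Digest a sequence with a restriction enzyme
#'
#' Cuts the top strand at `site start + cut_offset_top` for every forward
#' site (and at the mirrored offset for minus-strand sites). Coincident cuts
#' from overlapping sites are applied once. A site-free sequence yields one
#' fragment equal to the whole input.
#'
#' @inheritParams find_enzyme_sites
#' @return An object of class `digest_result`: `lengths` (ordered 5' to 3')
#'   and `fragments` (character vector). Lengths always sum to the input
#'   length, and the fragments concatenate to the input.
#' @export
digest <- function(seq, enzyme) {
  sq <- .as_seq(seq)
  n <- nchar(sq$seq)
  sites <- find_enzyme_sites(sq$seq, enzyme)
  L <- nchar(enzyme$recognition)
  cuts <- ifelse(sites$strand == "+",
                 sites$start + enzyme$cut_offset_top,
                 sites$start + (L - enzyme$cut_offset_top))
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  bounds <- c(0L, cuts, n)
  frags <- substring(sq$seq, bounds[-length(bounds)] + 1L, bounds[-1L])
  structure(list(lengths = as.integer(diff(bounds)), fragments = frags,
                 enzyme = enzyme$name, seq_id = sq$id),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest_result> %s on %s: fragments [%s]\n",
              x$enzyme, x$seq_id, paste(x$lengths, collapse = ", ")))
  invisible(x)
}

#' Discover RFLP markers between two alleles
#'
#' Digests the amplicon interval of both alleles with each enzyme and
#' reports the enzymes whose fragment-length multisets differ.
#'
#' @param alleleA,alleleB [sequence_record()]s or ungapped strings.
#' @param enzymes A [restriction_enzyme()] or list of them.
#' @param amplicon_interval Optional length-2 integer vector, 0-based
#'   half-open interval on both alleles; `NULL` digests the full sequences.
#' @return A list of `rflp_marker` objects, each with `enzyme`, `interval`,
#'   `allele_ids`, and `patterns` (sorted fragment-length multisets `A`, `B`).
#' @export
rflp_discover <- function(alleleA, alleleB, enzymes, amplicon_interval = NULL) {
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  a <- .as_seq(alleleA, "alleleA"); b <- .as_seq(alleleB, "alleleB")
  clip <- function(s) {
    if (is.null(amplicon_interval)) return(s)
    iv <- as.integer(amplicon_interval)
    if (iv[1] < 0L || iv[2] > nchar(s) || iv[1] >= iv[2])
      stop("amplicon interval out of range")
    substr(s, iv[1] + 1L, iv[2])
  }
  sa <- clip(a$seq); sb <- clip(b$seq)
  out <- list()
  for (enz in enzymes) {
    pa <- sort(digest(sa, enz)$lengths)
    pb <- sort(digest(sb, enz)$lengths)
    if (!identical(pa, pb))
      out[[length(out) + 1L]] <- structure(
        list(enzyme = enz, interval = amplicon_interval,
             allele_ids = c(A = a$id, B = b$id),
             patterns = list(A = pa, B = pb)),
        class = "rflp_marker")
  }
  out
}

#' Call a genotype from an observed fragment pattern
#'
#' Exact multiset matching against the marker's two homozygous patterns and
#' their union (the heterozygote); anything else is a no-call.
#'
#' @param observed_fragments Integer vector of observed fragment lengths.
#' @param marker An `rflp_marker`.
#' @return One of `"homozygous_A"`, `"homozygous_B"`, `"heterozygous"`,
#'   `"no_call"`.
#' @export
call_genotype <- function(observed_fragments, marker) {
  stopifnot(inherits(marker, "rflp_marker"))
  obs <- sort(as.integer(observed_fragments))
  pa <- marker$patterns$A
  pb <- marker$patterns$B
  if (identical(obs, pa)) return("homozygous_A")
  if (identical(obs, pb)) return("homozygous_B")
  if (identical(obs, sort(c(pa, pb)))) return("heterozygous")
  "no_call"
}

#' Chi-square test of a Mendelian segregation ratio
#'
#' Pearson goodness-of-fit of observed class counts against an expected
#' integer ratio (no continuity correction), with `classes - 1` degrees of
#' freedom and an upper-tail p-value.
#'
#' @param counts Integer vector of observed counts per class (>= 2 classes,
#'   positive total).
#' @param ratio Expected integer ratio, same length (e.g. `c(1, 2, 1)`).
#' @return An object of class `segregation_result`: `observed`, `expected`,
#'   `ratio`, `statistic`, `df`, `p_value`.
#' @export
segregation_test <- function(counts, ratio) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("need at least 2 classes")
  if (length(ratio) != length(counts)) stop("ratio/counts length mismatch")
  if (sum(counts) <= 0) stop("total count must be positive")
  if (any(ratio <= 0)) stop("zero expected class")
  p <- ratio / sum(ratio)
  ht <- suppressWarnings(stats::chisq.test(counts, p = p))
  structure(list(observed = counts, expected = sum(counts) * p,
                 ratio = ratio,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value)),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("<segregation_result> observed [%s] vs ratio %s: chi-square = %.3f, df = %d, p = %.3g\n",
              paste(x$observed, collapse = ", "),
              paste(x$ratio, collapse = ":"),
              x$statistic, as.integer(x$df), x$p_value))
  invisible(x)
}
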