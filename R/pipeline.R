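# End-to-end orchestration: reconstruct -> mutations -> motifs, with
# optional RFLP, segregation and activity stages, writing deterministic
# TSV/BED/FASTA/JSON outputs.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes reconstruction, mutation cataloguing and binding-site diffing
#' (plus optional RFLP, segregation and activity stages) over one
#' configuration, writing all outputs under `out_dir`. Outputs carry no
#' timestamps, so a rerun with the same config is byte-identical. Any stage
#' failure raises an error tagged `[stage:<name>]`.
#'
#' @param config A named list with elements:
#'   \describe{
#'     \item{alignment}{path to an aligned FASTA, or a `gapped_alignment`.}
#'     \item{tree}{path to a Newick file, or a `phylo`.}
#'     \item{ingroup}{character vector of ingroup tip labels.}
#'     \item{core_interval}{optional `c(start, end)` columns (0-based
#'       half-open) for core/flank labeling; default: whole alignment.}
#'     \item{motifs}{optional list of [motif()]s; default [default_motifs()].}
#'     \item{enzymes}{optional list of [restriction_enzyme()]s.}
#'     \item{counts, ratio}{optional observed class counts and expected
#'       ratio for a segregation test.}
#'     \item{measurements, reference_id}{optional measurements TSV (see
#'       [read_measurements()]) and the reference construct id.}
#'     \item{out_dir}{output directory (created if absent).}
#'     \item{seed}{optional integer, recorded in the summary.}
#'   }
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("[stage:config] 'out_dir' is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  aln <- .stage("load", {
    a <- config$alignment
    if (inherits(a, "gapped_alignment")) a else read_alignment(a)
  })
  tree <- .stage("reconstruct", {
    tr <- config$tree
    if (is.null(tr)) stop("no tree supplied")
    if (!inherits(tr, "phylo")) {
      if (!file.exists(tr)) stop("tree file not found: ", tr)
      tr <- ape::read.tree(tr)
    }
    tr
  })
  recon <- .stage("reconstruct", fitch_reconstruct(aln, tree, config$ingroup))

  .stage("reconstruct", {
    paths$consensus_gapped <- file.path(out_dir, "consensus_gapped.fasta")
    gp <- Biostrings::BStringSet(recon$consensus)
    names(gp) <- "concestor"
    Biostrings::writeXStringSet(gp, paths$consensus_gapped)
    paths$consensus <- file.path(out_dir, "concestor.fasta")
    write_fasta(sequence_record("concestor", degap(recon$consensus)),
                paths$consensus)
    paths$ambiguity <- file.path(out_dir, "ambiguity.tsv")
    utils::write.table(recon$tie_breaks, paths$ambiguity, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  core <- if (!is.null(config$core_interval)) config$core_interval
          else c(0L, aln$n_cols)
  catalogues <- .stage("mutations", {
    ev <- lapply(config$ingroup, function(id)
      assign_labels(call_mutations(recon$consensus, .aln_row(aln, id)), core))
    names(ev) <- config$ingroup
    ev
  })
  .stage("mutations", {
    paths$mutations <- file.path(out_dir, "mutations.tsv")
    write_mutation_catalog(catalogues, paths$mutations)
  })

  motifs <- if (!is.null(config$motifs)) config$motifs else default_motifs()
  anc_seq <- sequence_record("concestor", degap(recon$consensus))
  sites <- .stage("motifs",
    do.call(rbind, lapply(motifs, function(m) scan_motif(anc_seq, m))))
  diffs <- .stage("motifs", {
    d <- do.call(rbind, lapply(config$ingroup, function(id)
      diff_sites(recon, aln, id, motifs)))
    rownames(d) <- NULL
    d
  })
  .stage("motifs", {
    paths$sites_bed <- file.path(out_dir, "motif_sites.bed")
    write_sites_bed(sites, paths$sites_bed)
    paths$site_diffs <- file.path(out_dir, "site_diffs.tsv")
    utils::write.table(diffs, paths$site_diffs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  enzyme_sites <- NULL
  if (!is.null(config$enzymes)) {
    enzyme_sites <- .stage("rflp", {
      do.call(rbind, lapply(config$enzymes, function(enz) {
        s <- find_enzyme_sites(anc_seq, enz)
        if (nrow(s) == 0L) return(NULL)
        data.frame(seq_id = anc_seq$id, start = s$start,
                   end = s$start + nchar(enz$recognition),
                   motif_name = enz$name, strand = s$strand,
                   stringsAsFactors = FALSE)
      }))
    })
    .stage("rflp", {
      paths$enzyme_bed <- file.path(out_dir, "enzyme_sites.bed")
      write_sites_bed(if (is.null(enzyme_sites))
        data.frame(seq_id = character(), start = integer(), end = integer(),
                   motif_name = character(), strand = character())
        else enzyme_sites, paths$enzyme_bed)
    })
  }

  segres <- NULL
  if (!is.null(config$counts)) {
    segres <- .stage("segtest",
      segregation_test(config$counts, config$ratio))
    .stage("segtest", {
      paths$segregation <- file.path(out_dir, "segregation.tsv")
      utils::write.table(
        data.frame(class = seq_along(segres$observed) - 1L,
                   observed = segres$observed, expected = segres$expected,
                   chi_square = segres$statistic, df = segres$df,
                   p_value = segres$p_value),
        paths$segregation, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  activity <- NULL
  if (!is.null(config$measurements)) {
    activity <- .stage("activity", {
      meas <- read_measurements(config$measurements)
      ref_id <- config$reference_id
      if (is.null(ref_id) || !ref_id %in% names(meas))
        stop("reference construct not found in measurements")
      rows <- lapply(meas, function(m) {
        na <- normalize_activity(m, meas[[ref_id]])
        data.frame(construct_id = na$construct_id,
                   percent = na$percent, sem_percent = na$sem_percent,
                   n = na$n,
                   report = sprintf("%.0f +/- %.0f%% (n=%d)", na$percent,
                                    na$sem_percent, na$n),
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      rownames(tab) <- NULL
      tab
    })
    .stage("activity", {
      paths$activity <- file.path(out_dir, "activity.tsv")
      utils::write.table(activity, paths$activity, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("concestor")),
    seed = config$seed,
    n_records = length(aln$ids), n_cols = aln$n_cols,
    n_ingroup = length(config$ingroup),
    n_polymorphic_cols = length(recon$polymorphic_cols),
    n_ambiguous_cols = length(recon$ambiguous_cols),
    parsimony_score = recon$score,
    n_mutation_rows = sum(vapply(catalogues, nrow, integer(1))),
    n_motif_sites = nrow(sites),
    n_site_diffs = nrow(diffs),
    config_hash = sum(utf8ToInt(paste(deparse(config[intersect(names(config),
      c("ingroup", "core_interval", "motifs", "enzymes", "counts", "ratio",
        "reference_id", "seed"))]), collapse = ""))))
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(reconstruction = recon, catalogues = catalogues,
                 sites = sites, diffs = diffs, enzyme_sites = enzyme_sites,
                 segregation = segres, activity = activity, paths = paths))
}
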