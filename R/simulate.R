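# Ground-truth synthetic data: an ancestor with planted binding sites
# evolved down a rooted tree by a per-branch substitution/indel process that
# owns its own true alignment (no realignment), plus F2 crosses and noisy
# replicate reporter intensities.
#
# All randomness flows from one seeded stream consumed in a fixed preorder
# edge traversal, so identical config + seed gives byte-identical datasets.

# run `f` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, f) {
  if (is.null(seed)) stop("a seed is mandatory")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  f()
}

# Fixed paper-scale genealogy: one realized coalescent-shaped ingroup tree
# (frozen topology and branch lengths, rescaled so the mean pairwise path
# length is 2 units) below a ladder of 7 outgroups. The tree is part of the
# study design; user seeds randomize mutations only.
.paper_scale_tree <- function() {
  ing <- .with_seed(191L, function()
    ape::rcoal(31L, tip.label = sprintf("mel.%02d.1", 1:31)))
  d <- ape::cophenetic.phylo(ing)
  ing$edge.length <- ing$edge.length * 2 / mean(d[lower.tri(d)])
  h <- max(ape::node.depth.edgelength(ing))
  og <- c("mau.5", "sec.38", "sim.33", "yak.25", "luc.41", "eug.20", "fuy.9")
  nwk <- sub(";$", "", ape::write.tree(ing))
  for (nm in og) {
    h <- h + 1.2
    nwk <- sprintf("(%s:1.2,%s:%.6f)", nwk, nm, h)
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

#' Simulation configuration
#'
#' Bundles the generative conditions the analysis assumes: a rooted tree
#' (default: the fixed paper-scale genealogy of 31 population alleles below
#' a 7-species outgroup ladder), ancestor length and GC content, per-branch
#' substitution and indel rates, planted binding-site motifs, and a
#' mandatory seed.
#'
#' @param seed Integer seed (mandatory).
#' @param tree A rooted `phylo`; `NULL` uses the fixed paper-scale tree.
#' @param ingroup Ingroup tip labels; `NULL` takes the tips matching
#'   `^mel\\.`.
#' @param length Ancestor length in bp (default 700).
#' @param gc GC fraction of background sequence (default 0.4).
#' @param sub_rate Substitutions per site per unit branch length
#'   (default 0.0115; with the default tree this calibrates the ingroup to
#'   ~98% mean pairwise identity and ~50 polymorphic columns).
#' @param indel_rate Indel events per site per unit branch length, split
#'   evenly between insertions and deletions (default `sub_rate / 10`).
#' @param indel_mean_len Mean of the geometric indel length distribution
#'   (default 2).
#' @param planted_motifs List of `list(motif =, count =)` entries; default
#'   14 ABD-B (`TTTAY`) and 2 DSX (`RNNACWAWGTNNY`) instances.
#' @param protect_motifs If `TRUE` (default), planted windows are shielded
#'   from mutation so leaves retain their sites.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed, tree = NULL, ingroup = NULL,
                              length = 700L, gc = 0.4,
                              sub_rate = 0.0115, indel_rate = sub_rate / 10,
                              indel_mean_len = 2,
                              planted_motifs = list(
                                list(motif = default_motifs()[["ABD-B"]], count = 14L),
                                list(motif = default_motifs()[["DSX"]], count = 2L)),
                              protect_motifs = TRUE) {
  stopifnot(length >= 1L, gc >= 0, gc <= 1, sub_rate >= 0, sub_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, indel_mean_len >= 1)
  if (is.null(seed)) stop("a seed is mandatory")
  if (is.null(tree)) tree <- .paper_scale_tree()
  stopifnot(inherits(tree, "phylo"))
  if (is.null(ingroup)) ingroup <- grep("^mel\\.", tree$tip.label, value = TRUE)
  if (!length(ingroup)) stop("no ingroup tips")
  need <- sum(vapply(planted_motifs, function(p)
    p$count * nchar(p$motif$consensus), numeric(1)))
  if (need > length) stop("infeasible packing: planted motifs exceed length")
  structure(list(seed = as.integer(seed), tree = tree, ingroup = ingroup,
                 length = as.integer(length), gc = gc, sub_rate = sub_rate,
                 indel_rate = indel_rate, indel_mean_len = indel_mean_len,
                 planted_motifs = planted_motifs,
                 protect_motifs = protect_motifs),
            class = "simulation_config")
}

# unseeded core used by both generate_ancestor and simulate_evolution
.gen_ancestor_core <- function(config) {
  L <- config$length
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  bases <- sample(names(p), L, replace = TRUE, prob = p)
  occupied <- logical(L)
  coords <- list()
  for (pm in config$planted_motifs) {
    cons <- strsplit(pm$motif$consensus, "")[[1]]
    w <- length(cons)
    for (k in seq_len(pm$count)) {
      placed <- FALSE
      for (try in seq_len(10000L)) {
        s <- sample.int(L - w + 1L, 1L) - 1L    # 0-based start
        if (!any(occupied[(s + 1L):(s + w)])) { placed <- TRUE; break }
      }
      if (!placed) stop("infeasible packing: could not place motif ",
                        pm$motif$name)
      inst <- vapply(cons, function(cc) {
        opts <- strsplit(.IUPAC[[cc]], "")[[1]]
        opts[sample.int(length(opts), 1L)]
      }, character(1))
      bases[(s + 1L):(s + w)] <- inst
      occupied[(s + 1L):(s + w)] <- TRUE
      coords[[length(coords) + 1L]] <- data.frame(
        motif_name = pm$motif$name, start = s, end = s + w, strand = "+",
        stringsAsFactors = FALSE)
    }
  }
  motifs <- if (length(coords)) do.call(rbind, coords) else
    data.frame(motif_name = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  motifs <- motifs[order(motifs$start), , drop = FALSE]
  rownames(motifs) <- NULL
  list(record = sequence_record("concestor_true", paste(bases, collapse = "")),
       motifs = motifs, protected = occupied & config$protect_motifs)
}

#' Generate a ground-truth ancestral element with planted binding sites
#'
#' Background bases are i.i.d. at the configured GC fraction; each planted
#' motif instance is sampled uniformly from its consensus-compatible strings
#' and placed uniformly without overlap (forward strand).
#'
#' @param config A [simulation_config()].
#' @return A list: `record` (a [sequence_record()]) and `motifs`
#'   (data.frame of planted coordinates, 0-based half-open).
#' @export
generate_ancestor <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  out <- .with_seed(config$seed, function() .gen_ancestor_core(config))
  out[c("record", "motifs")]
}

#' Evolve the ancestor down the tree with a true alignment
#'
#' Substitutions are drawn per eligible site with probability
#' `1 - exp(-sub_rate * branch_length)` (uniform over the three alternative
#' bases); insertion and deletion events each arise at half the analogous
#' indel probability, with geometric lengths. The generator owns the true
#' alignment: insertions splice new columns into every materialized row, so
#' no realignment step ever runs. Protected (planted-motif) columns are
#' exempt from mutation when `protect_motifs` is set.
#'
#' @param config A [simulation_config()].
#' @return An object of class `simulated_dataset`: `alignment` (leaves only,
#'   ingroup rows first), `ancestor_row` (gapped, same column frame),
#'   `ancestor` (ungapped [sequence_record()]), `motifs` (planted
#'   coordinates, ancestor ungapped frame), `tree`, `ingroup`, `outgroup`,
#'   `events_by_leaf` (named list of [call_mutations()] catalogues vs the
#'   true ancestor), and `config`.
#' @export
simulate_evolution <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, function() .simulate_evolution_core(config))
}

.simulate_evolution_core <- function(config) {
  anc <- .gen_ancestor_core(config)
  tree <- config$tree
  tips <- tree$tip.label
  n_tip <- length(tips)
  root <- n_tip + 1L
  tr <- ape::reorder.phylo(tree, "cladewise")   # preorder: parents first
  edges <- tr$edge
  elen <- tr$edge.length
  if (is.null(elen)) elen <- rep(1, nrow(edges))

  rows <- vector("list", n_tip + tree$Nnode)
  rows[[root]] <- strsplit(anc$record$residues, "")[[1]]
  protected <- anc$protected
  col_id <- seq_along(rows[[root]])   # original root column of each column

  for (e in seq_len(nrow(edges))) {          # preorder: parent done first
    p <- edges[e, 1L]; v <- edges[e, 2L]; bl <- elen[e]
    row <- rows[[p]]
    elig <- which(row != .GAP & !protected)
    p_sub <- -expm1(-config$sub_rate * bl)
    p_ind <- -expm1(-config$indel_rate * bl) / 2   # each of ins / del
    # substitutions
    hit <- elig[stats::runif(length(elig)) < p_sub]
    for (j in hit) row[j] <- sample(setdiff(.BASES, row[j]), 1L)
    # deletions: anchored at an eligible site, extending right over non-gap,
    # unprotected columns
    ndel <- stats::rbinom(1L, length(elig), p_ind)
    for (k in seq_len(ndel)) {
      len <- stats::rgeom(1L, 1 / config$indel_mean_len) + 1L
      s <- elig[sample.int(length(elig), 1L)]
      j <- s
      while (j <= length(row) && len > 0L) {
        if (row[j] != .GAP) {
          if (protected[j]) break
          row[j] <- .GAP
          len <- len - 1L
        }
        j <- j + 1L
      }
    }
    # insertions: new columns spliced into every materialized row
    nins <- stats::rbinom(1L, length(elig), p_ind)
    for (k in seq_len(nins)) {
      len <- stats::rgeom(1L, 1 / config$indel_mean_len) + 1L
      q <- sample.int(length(row) + 1L, 1L) - 1L   # insert after column q
      # do not split a protected window
      if (q > 0L && q < length(row) && protected[q] && protected[q + 1L]) next
      pgc <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
               (1 - config$gc) / 2)
      new <- sample(.BASES, len, replace = TRUE, prob = pgc)
      for (i in seq_along(rows)) {
        if (is.null(rows[[i]])) next
        rows[[i]] <- append(rows[[i]], rep(.GAP, len), after = q)
      }
      row <- append(row, new, after = q)
      protected <- append(protected, rep(FALSE, len), after = q)
      col_id <- append(col_id, rep(NA_integer_, len), after = q)
    }
    rows[[v]] <- row
  }

  leaf_rows <- vapply(seq_len(n_tip), function(i)
    paste(rows[[i]], collapse = ""), character(1))
  names(leaf_rows) <- tips
  ingroup <- intersect(tips, config$ingroup)
  outgroup <- setdiff(tips, ingroup)

  # the reconstruction target is the sequence at the ingroup MRCA node, not
  # the root: root-to-MRCA spine mutations are outgroup history
  mrca <- if (length(ingroup) == 1L) match(ingroup, tips)
          else ape::getMRCA(tree, ingroup)
  anc_chars <- rows[[mrca]]
  anc_row <- paste(anc_chars, collapse = "")

  # planted-motif coordinates projected into the MRCA's ungapped frame
  motifs <- anc$motifs
  if (nrow(motifs)) {
    ungap_before <- cumsum(anc_chars != .GAP)
    for (i in seq_len(nrow(motifs))) {
      cols <- which(!is.na(col_id) & col_id > motifs$start[i] &
                    col_id <= motifs$end[i])
      if (!length(cols)) { motifs$start[i] <- motifs$end[i] <- 0L; next }
      c0 <- min(cols); c1 <- max(cols)
      motifs$start[i] <- if (c0 > 1L) ungap_before[c0 - 1L] else 0L
      motifs$end[i] <- ungap_before[c1]
    }
  }

  # drop columns gapped in every leaf (an ancestral base deleted everywhere
  # is unobservable; vanishingly rare at default rates)
  m <- .rows_matrix(leaf_rows)
  allgap <- colSums(m != .GAP) == 0L
  if (any(allgap)) {
    keep <- which(!allgap)
    leaf_rows <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
    names(leaf_rows) <- tips
    anc_row <- paste(strsplit(anc_row, "")[[1]][keep], collapse = "")
  }
  ord <- c(ingroup, outgroup)
  aln <- gapped_alignment(ord, unname(leaf_rows[ord]))
  events <- lapply(ord, function(id) call_mutations(anc_row, leaf_rows[[id]]))
  names(events) <- ord

  structure(list(alignment = aln, ancestor_row = anc_row,
                 ancestor = sequence_record("concestor_true", degap(anc_row)),
                 motifs = motifs, tree = tree,
                 ingroup = ingroup, outgroup = outgroup,
                 events_by_leaf = events, config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d leaves (%d ingroup) x %d columns, seed %d\n",
              length(x$alignment$ids), length(x$ingroup),
              x$alignment$n_cols, x$config$seed))
  invisible(x)
}

#' Simulate an F2 cross under a single semi-dominant locus
#'
#' Genotypes are drawn multinomially at (1/4, 1/2, 1/4); with full
#' penetrance and semi-dominance the phenotype class equals the genotype.
#'
#' @param n Number of F2 individuals (>= 1).
#' @param seed Integer seed.
#' @return A list with `genotypes` and `phenotypes`, each a named count
#'   vector over `AA`, `AB`, `BB` (phenotypically: the two parental classes
#'   and the intermediate).
#' @export
simulate_f2_cross <- function(n, seed) {
  if (n < 1L) stop("'n' must be >= 1")
  counts <- .with_seed(seed, function()
    as.vector(stats::rmultinom(1L, n, c(0.25, 0.5, 0.25))))
  names(counts) <- c("AA", "AB", "BB")
  list(genotypes = counts, phenotypes = counts)
}

#' Simulate replicate reporter intensities for a test/reference pair
#'
#' Reference replicates are Normal(`mu_ref`, `noise_sd`); test replicates
#' are Normal(`mu_ref * true_percent / 100`, `noise_sd`); both truncated to
#' positive values by rejection.
#'
#' @param true_percent True activity as percent of the reference (> 0).
#' @param noise_sd Replicate standard deviation, same units as `mu_ref`.
#' @param n_reps Replicates per construct (>= 2).
#' @param seed Integer seed.
#' @param mu_ref Reference mean intensity (default 100).
#' @return A list of two [activity_measurements()]: `test` and `reference`.
#' @export
simulate_reporter <- function(true_percent, noise_sd = 15, n_reps = 6L,
                              seed, mu_ref = 100) {
  stopifnot(true_percent > 0, n_reps >= 2L, noise_sd >= 0)
  draw <- function(mu) {
    x <- numeric(n_reps)
    for (i in seq_len(n_reps)) {
      repeat { v <- stats::rnorm(1L, mu, noise_sd); if (v > 0) break }
      x[i] <- v
    }
    x
  }
  .with_seed(seed, function() {
    test <- draw(mu_ref * true_percent / 100)
    ref <- draw(mu_ref)
    list(test = activity_measurements("test", test),
         reference = activity_measurements("reference", ref))
  })
}
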