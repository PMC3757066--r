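# Independent oracles and shared fixtures for the test suite. The oracles
# deliberately share no code with the implementation paths they check.

BASES5 <- c("A", "C", "G", "T", "-")

# Brute-force minimum-change oracle: enumerate every labeling of the
# internal nodes over the 5-state alphabet, score each by counting edges
# whose endpoints differ, and collect the states the `node` takes among the
# minimal labelings.
brute_force_mpr <- function(tree, tipstates, node) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  tipcode <- match(tipstates[tree$tip.label], BASES5)
  G <- as.matrix(expand.grid(rep(list(1:5), n_int)))  # labelings x internals
  state_of <- function(v) {
    if (v <= n_tip) matrix(tipcode[v], nrow(G), 1L) else G[, v - n_tip, drop = FALSE]
  }
  cost <- numeric(nrow(G))
  for (e in seq_len(nrow(tree$edge)))
    cost <- cost + (state_of(tree$edge[e, 1L]) != state_of(tree$edge[e, 2L]))
  best <- which(cost == min(cost))
  ns <- as.vector(if (node <= n_tip) rep(tipcode[node], nrow(G))
                  else G[, node - n_tip])
  cost_by_state <- vapply(1:5, function(s) {
    idx <- ns == s
    if (!any(idx)) Inf else min(cost[idx])
  }, numeric(1))
  names(cost_by_state) <- BASES5
  list(score = min(cost), set = BASES5[sort(unique(ns[best]))],
       cost_by_state = cost_by_state)
}

# Naive window-by-window IUPAC scanner on both strands, via regex.
iupac_regex <- function(consensus) {
  map <- Biostrings::IUPAC_CODE_MAP
  paste0(vapply(strsplit(consensus, "")[[1]],
                function(cc) paste0("[", map[[cc]], "]"), character(1)),
         collapse = "")
}
rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
naive_scan <- function(seq, consensus, strands = "both") {
  L <- nchar(consensus)
  n <- nchar(seq)
  if (n < L) return(data.frame(start = integer(), strand = character()))
  wins <- substring(seq, 1:(n - L + 1L), L:n)
  f <- which(grepl(paste0("^", iupac_regex(consensus), "$"), wins)) - 1L
  out <- data.frame(start = f, strand = rep("+", length(f)),
                    stringsAsFactors = FALSE)
  if (strands == "both") {
    m <- which(grepl(paste0("^", iupac_regex(rc(consensus)), "$"), wins)) - 1L
    out <- rbind(out, data.frame(start = m, strand = rep("-", length(m)),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# random rooted tree whose first `n_in` tips form a monophyletic ingroup
# below a ladder of `n_out` outgroups
make_ingroup_tree <- function(n_in, n_out) {
  ing <- ape::rtree(n_in, tip.label = sprintf("P%d", seq_len(n_in)))
  nwk <- sub(";$", "", ape::write.tree(ing))
  for (i in seq_len(n_out))
    nwk <- sprintf("(%s:1,O%d:1)", nwk, i)
  ape::read.tree(text = paste0(nwk, ";"))
}

# memoized paper-scale synthetic dataset (shared across test files)
.fixture_env <- new.env(parent = emptyenv())
get_paper_ds <- function(seed = 1L) {
  key <- paste0("ds", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_evolution(simulation_config(seed = seed))
  .fixture_env[[key]]
}
get_paper_recon <- function(seed = 1L) {
  key <- paste0("rec", seed)
  if (is.null(.fixture_env[[key]])) {
    ds <- get_paper_ds(seed)
    .fixture_env[[key]] <- fitch_reconstruct(ds$alignment, ds$tree, ds$ingroup)
  }
  .fixture_env[[key]]
}

# random gapped row pair of equal length (no all-gap columns guaranteed by
# never gapping both rows at one column)
random_row_pair <- function(n) {
  a <- character(n); b <- character(n)
  for (j in seq_len(n)) {
    kind <- sample(c("match", "sub", "del", "ins"), 1L,
                   prob = c(0.7, 0.1, 0.1, 0.1))
    if (kind == "match") { x <- sample(c("A", "C", "G", "T"), 1L); a[j] <- x; b[j] <- x }
    else if (kind == "sub") { x <- sample(c("A", "C", "G", "T"), 2L); a[j] <- x[1]; b[j] <- x[2] }
    else if (kind == "del") { a[j] <- sample(c("A", "C", "G", "T"), 1L); b[j] <- "-" }
    else { a[j] <- "-"; b[j] <- sample(c("A", "C", "G", "T"), 1L) }
  }
  c(paste(a, collapse = ""), paste(b, collapse = ""))
}

write_tmp_fasta <- function(ids, rows) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), rows)), path)
  path
}
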