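---
title: "Reconstructing and dissecting a dimorphic cis-regulatory element"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and dissecting a dimorphic cis-regulatory element}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concestor)
```

## The problem

Cis-regulatory elements (CREs) diverge quickly between populations, and a
handful of derived mutations can reshape a CRE's output. This package
implements the analysis pipeline for one well-studied case: the "dimorphic
element" of the *Drosophila melanogaster* *bab* locus, whose alleles drive
female abdominal pigmentation phenotypes ranging from Light to Dark. The
strategy is to (i) infer the element carried by the most recent common
ancestor (MRCA) of the surveyed population alleles — the "concestor" — by
parsimony over a rooted tree with outgroup species, (ii) catalogue each
allele's derived mutations against that ancestor, (iii) ask which mutations
create or destroy transcription-factor binding sites (ABD-B and DSX
consensus motifs), and (iv) connect genotype to phenotype through RFLP
genotyping with Mendelian segregation tests and through reporter-activity
and binding-titration statistics.

Raw study sequences are not distributed in machine-readable form, so the
package ships a first-class synthetic-data generator that reproduces the
statistical structure the analysis assumes; every stage is tested against
it and against independent oracles.

## Ancestral reconstruction

`fitch_reconstruct()` performs exact unit-cost parsimony per alignment
column over the five-state alphabet `{A,C,G,T,-}`. Gaps are an ordinary
fifth character state at this stage; indel *event* semantics (collapsing a
gap run into one mutation) are applied downstream by `call_mutations()`.
This matches the column-granular bookkeeping used for polymorphic and
ambiguous site counts.

Rather than the classical two-pass Fitch procedure on a binarised tree, the
implementation runs an up/down dynamic program over per-node state costs
(Sankoff-style with unit costs). Two consequences:

* **Multifurcations are handled natively.** The minimum mutation count of a
  multifurcating node equals that of any binary resolution under unit
  costs, so no arbitrary caterpillar resolution is needed and the result
  cannot depend on input order.
* **The full MPR set is returned.** For every column the reconstruction
  reports *all* states the ingroup MRCA takes in at least one
  minimum-change labeling, computed exactly (`up + down` cost equals the
  global minimum). The test suite verifies this against brute-force
  enumeration of every internal labeling on trees of up to 8 leaves.

Columns with more than one MPR state are flagged ambiguous, and a single
consensus is resolved deterministically: the state carried by the plurality
of outgroup leaves, then the ingroup plurality, then alphabetically with
`-` last. The rule is recorded per column in the ambiguity report, and
`enumerate_alternates()` expands the Cartesian product of ambiguous state
sets (consensus first, deterministic lexicographic order) so alternate
ancestors can be synthesised and tested, mirroring the study's robustness
analysis of its eight ambiguous sites.

One property worth stating because it is *not* true: outgroup removal can
shrink an MRCA state set. Outgroup context can admit a state whose
ingroup-subtree cost is one above the ingroup-only optimum (the extra
mutation is paid on the edge above the MRCA). The test suite pins down the
correct relationship: the ingroup-only set is exactly the set of
conditional-cost minimizers, and every full-tree MPR state lies within one
mutation of that optimum.

## Mutation catalogue and constructs

`call_mutations()` compares the resolved ancestor row to an allele row
column by column. Maximal runs where exactly one side is gapped collapse to
a single insertion or deletion event; differing base pairs become
one substitution each; runs of different kinds never merge, so a gap run
flanked by substitutions yields separate events. The hard guarantee, tested
on thousands of random row pairs, is the round trip: applying the called
events to the ungapped ancestor reproduces the allele exactly.

`assign_labels()` letters core-region events (`A`, `B`, `C`, ...) and
numbers flank events, in column order — the labeling convention of the
study, under which, e.g., a 9-bp deletion is one lettered mutation.
Reproducing the study's specific letters would require its full allele
panel; the rule here only promises deterministic, order-respecting labels
per catalogue. Homopolymer-tract length changes are ordinary left-aligned
indel events; the catalogue exposes both column-level counts (via
`fitch_reconstruct()$polymorphic_cols`) and event-level counts (via
`count_mutations()`), because tract variation makes the two genuinely
different quantities and the source material does not fix one convention.

`construct_design` functions build the in-silico reagents: `swap_region()`
for core/flank chimeras (with provenance recorded in FASTA headers),
`apply_event()` for single-mutation substitutions into the ancestor (which
refuses to apply an event whose ancestral state does not match — a cheap
but effective guard against frame errors), `scramble_transversions()` for
non-complementary transversion scrambles (`A<->C`, `G<->T`; the edited base
is never the original nor its complement, and the map is an involution),
and `slice_deletion()` for sub-deletions of a parent deletion such as
an 8-bp prefix deletion or a 1-bp final-base deletion. Cloning adapters are
out of scope: constructs are endogenous sequence only.

## Binding-site annotation

Sites are IUPAC consensus matches (`TTTAY` for ABD-B, `RNNACWAWGTNNY` for
DSX by default), scanned on both strands with minus-strand hits mapped to
forward coordinates. There is deliberately no PWM or energy model: the
source analysis defines sites by consensus match plus prior in-vitro
binding, and graded affinity lives in the titration statistic instead.
The scanner is verified against a naive window-by-window regex oracle on
random sequences and motifs.

`diff_sites()` maps each ancestral site through alignment columns onto an
allele and calls it conserved if the mapped window still matches the
consensus, lost otherwise; allele-only matches are gained. A mutation that
*reduces* a site's quality while still matching the consensus is therefore
"conserved" here — that distinction is handled by
`evaluate_site_after_edit()`, which applies an event and re-tests the
consensus at the shifted window. The window anchors at the site's end when
the event starts before the site (so a deletion clipping a site's first
base recruits the surviving upstream base — the geometry by which a 9-bp
deletion ending one bp inside a DSX site can leave a still-matching,
lower-affinity site), and at the site's start otherwise.

## RFLP genotyping and segregation

`digest()` cuts at the top-strand cut coordinate of every recognition-site
match (BstXI: `CCANNNNNN^TGG`, offset 8); fragment lengths are the gel
convention, overhangs are not modelled, and fragments always concatenate to
the input. `rflp_discover()` reports enzymes whose fragment-length
multisets differ between two alleles; `call_genotype()` calls homozygotes
by exact multiset match and heterozygotes by the union multiset, with
anything else a no-call. `segregation_test()` is a plain Pearson
goodness-of-fit chi-square (no continuity correction) against an integer
ratio; for F2 counts of 25/54/23 against 1:2:1 it gives chi-square 0.431,
p = 0.806. The study prints p = 0.787 for the same counts; the exact
variant behind that number is unstated, so the package documents the plain
Pearson value and does not chase the printed one.

## Activity and titration statistics

`normalize_activity()` reports a construct as a percent of a reference
mean, with the test sample's SEM (n-1 standard deviation over sqrt(n))
scaled the same way and reference uncertainty deliberately not propagated —
that is the "mean ± SEM, % of reference" convention of the source reports.
The estimate is scale-invariant in the common intensity units.
`fold_range()` is the max/min ratio of allele means (the printed extremes
182% and 9% give a 20-fold range). `additivity()` compares a combined
construct against `100 + sum(single - 100)`; the printed F (160%), L
(215%) and F+L (241%) means give an expectation of 275% and a deviation of
-34. `relative_affinity()` reduces two detection-threshold titrations to
`100 * ref_threshold / variant_threshold`; its granularity is the titration
step (two-fold in the study design) and no interpolation is attempted,
which is exactly how a threshold of 16 ng versus 32 ng becomes "about 50%
affinity". Detection calls are validated to be monotone once positive;
violations are input errors, not smoothed over.

## The synthetic-data generator

`simulation_config()` fixes the study conditions; its defaults are the
paper-scale preset:

| parameter | default | why |
|---|---|---|
| tree | fixed 31-allele coalescent-shaped ingroup + 7-outgroup ladder | one realized genealogy, as in the study; user seeds vary mutations only |
| `length` | 700 bp | element scale |
| `gc` | 0.40 | typical non-coding *Drosophila* composition |
| `sub_rate` | 0.0115 /site/unit length | calibrates ingroup identity to ~98% given that planted windows are protected |
| `indel_rate` | `sub_rate/10`, geometric mean length 2 | preserves the observed excess of substitutions over indels |
| planted motifs | 14 ABD-B + 2 DSX | the ancestral site content |

The ingroup genealogy is one frozen coalescent draw rescaled so the mean
pairwise path length is 2 units; with the rates above the preset yields
~98% mean ingroup pairwise identity and roughly 40–65 polymorphic columns
across seeds — the scale of the study's 52 — while the outgroup ladder
provides enough signal that the reconstructed consensus recovers the true
MRCA sequence at more than 99% of columns. Branch mutation probabilities
are `1 - exp(-rate * branch_length)`, substitutions are uniform over the
three alternatives, and insertions splice new columns into every
materialized row so the generator owns a true alignment and no aligner ever
runs. All randomness is one seeded stream consumed in a fixed preorder edge
traversal: identical config and seed give byte-identical datasets.

The truth the generator stores is the sequence at the **ingroup MRCA
node**, not the root: mutations on the root-to-MRCA spine are outgroup
history and are invisible to (and not a failure of) the reconstruction.

What the generator does *not* emulate: selection, recombination,
migration/admixture, alignment error (the true alignment is given),
mutation-rate heterogeneity along the sequence (outside protected windows),
and saturation corrections for the deep outgroups. Passing tests therefore
demonstrate correctness of the algorithms under a clean tree-structured
mutation process, not robustness to misalignment or to non-treelike
population history.

`simulate_f2_cross()` draws genotypes multinomially at 1:2:1 with full
penetrance (semi-dominance makes phenotype equal genotype);
`simulate_reporter()` makes Gaussian replicate intensities truncated to
positive values.

## Numerical choices and degenerate inputs

* All machine coordinates are 0-based, half-open (BED convention); 1-based
  values appear only in rendered reports.
* `-` is the only gap character; `.` and IUPAC codes in alignments are
  loud errors, and lowercase input is uppercased with a warning.
* Consensus tie-breaks, alternate-reconstruction order, and event labels
  are all deterministic; pipeline outputs carry no timestamps, so reruns
  are byte-identical.
* Identity over a pair with no gap-free column is an error, not NaN; a
  titration with no detected lane is an "undetectable affinity" error; a
  zero-count segregation table and a zero expected class are errors.
* An ancestral base deleted in every leaf is unobservable; the generator
  drops such columns (vanishingly rare at default rates) rather than
  emitting an all-gap column.

## Problem sizes used by the test suite

The suite runs the full paper-scale preset (38 leaves x ~740 columns) for
recovery and calibration checks; 1000-case oracle comparisons for the
parsimony DP (trees of 3–8 leaves against exhaustive labeling enumeration)
and the motif scanner (sequences up to 500 bp); 1000 random row pairs for
the mutation round trip; 2000 simulated F2 cohorts of 102 individuals for
the type-I error and p-value-uniformity checks; and 500 seeded replicates
for reporter-percent recovery. These sizes were chosen to exercise each
statistical claim at the scale the study itself used.

## Known limitations

* Parsimony, not likelihood: no branch lengths in the reconstruction, no
  posterior support; deep outgroups are used as plurality tie-breakers
  rather than probabilistically weighted evidence.
* Site calls are binary consensus matches; affinity changes that keep the
  consensus require the titration route.
* The RFLP model assumes complete digestion and exact primer matches.
* Event labels restart per catalogue; cross-allele label identity (the
  study's shared letters) requires cataloguing against the same ancestor
  with the same core interval, and is not otherwise guaranteed.
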