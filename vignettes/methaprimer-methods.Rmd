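---
title: "Designing and validating degenerate primers for methanogenesis marker genes"
author: "methaprimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating degenerate primers for methanogenesis marker genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methaprimer)
```

## The problem

Methanogenic archaea are surveyed with marker-gene amplicon sequencing.
Beyond 16S rRNA and the classic *mcrA* marker, genes of the
methyl-coenzyme M reductase cluster (*mcrB*, *mcrG*) and the
methyltransferases of methylotrophic methanogenesis (*mtaB*, *mtbA*) make
informative markers — but each requires degenerate PCR primers designed
against conserved regions of a diverse gene family, and each primer set
must be validated: how many of the reads it amplifies actually come from
the target protein family?

`methaprimer` implements that whole workflow as reusable, deterministic
components: IUPAC degenerate-sequence algebra, conserved-window primer
design on an alignment, phylogenetic partitioning of hypervariable
families, in-silico PCR, a read-merging + translated-search validation
pipeline culminating in the primer-sensitivity statistic, and a simplified
phylogenetic placement of the inferred peptides. A seeded synthetic-data
generator provides gene families, amplicon libraries and reference sets
with known ground truth, so every stage is testable offline.

## Degenerate oligo algebra

A degenerate primer is a string over the 15-letter IUPAC alphabet; its
*degeneracy* is the number of concrete oligos in the pool, the product of
per-position code sizes. Degeneracy is always computed multiplicatively —
enumeration (capped at $10^6$) exists for oracle checks and pool export.
Complementation maps each ambiguity code to the code of the complemented
base set, so reverse complementation is an involution that commutes with
expansion.

Primer/template matching needs a convention for ambiguity codes *in the
template* (draft genomes contain `N`s): the default rule is non-empty
intersection of the two base sets, so a template `N` never costs a
mismatch; a strict mode requires the template set to be contained in the
primer set.

```{r algebra}
oligo_degeneracy("TWYCARGGHYTVAAYGC")   # mcrB forward primer: 288
revcomp_oligo("CCDCCDCCDCCRTARAT")
```

## Primer design on an alignment

A *conserved window* is a gap-free window (configurable gap tolerance)
whose per-column minimal covering IUPAC consensus stays under a degeneracy
cap. "Minimal covering" is greedy: bases are added in order of how many
additional sequences they cover until a fraction `min_coverage` of the
sequences is covered; with the default `min_coverage = 1` the consensus
covers every observed base, and lowering it lets rare variants be ignored
(the greedy order makes the consensus monotone in `min_coverage`).

Candidate pairs take the upstream consensus as the forward primer and the
reverse complement of the downstream consensus as the reverse primer.
Because indels make product length ill-defined on an alignment, the
expected product is the *median ungapped span* (primer-inclusive, the
standard amplicon convention) across the aligned sequences. Pairs are
ranked by pair degeneracy ascending — reproducing "lowest degeneracy"
selection as an optimization — with ties broken by product length
descending (longer amplicons carry more phylogenetic signal) and leftmost
start, so output is deterministic. Defaults: primer length 16–25 nt,
product ≤ 500 bp (so both 454 and short-read platforms can sequence the
amplicon), per-primer degeneracy ≤ 1024.

Pair enumeration thins the window list before forming combinations, and
the thinning is positional: the few lowest-degeneracy windows are kept per
50-column stretch. Keeping only the globally best windows would be wrong —
they often pile up in a single conserved patch, which can never yield a
forward/reverse pair.

## Partitioning hypervariable families

Some families are too variable for any single pair (the *mcrG* case,
where two sequence groups had to be distinguished before design).
`partition_by_tree()` builds a neighbor-joining guide tree from pairwise
p-distances (an approximation of a full ML tree, adequate for deep-split
recovery) and bisects at the longest internal branch until every group
admits at least one pair under the design constraints or `max_groups` is
reached. Designability is probed by actually running the design on each
group. For partitioning runs we recommend a strict degeneracy cap (the
benchmarks use 16): the point of splitting is to obtain near-specific
per-group primers, and under the permissive default cap even strongly
diverged families can formally admit a highly degenerate pair, which
would stop the split.

## In-silico PCR

Binding sites are scanned with positional Hamming counting (no indels),
the semantics of iPCRess-style scanners: a site is every window, on either
strand, with at most `max_mismatch_per_primer` base-match failures
(IUPAC-compatible positions cost nothing). Amplicons pair a forward site
with an opposite-orientation reverse site downstream on the same template,
require both primers to match, reject products shorter than the two
primers combined, and keep products within ±50 bp (default) of the pair's
expected length. Defaults follow the published screen: 2 mismatches per
primer, raised to 4 for the longer *mcrG* primers (stored in the shipped
primer table). There is no 3′-end constraint by default; an optional
clamp requires 0 mismatches in the last *N* primer bases.

## The validation pipeline and primer sensitivity

Paired reads are merged at the overlap (≥ 10 nt) with the best matched
minus mismatched bases; ties go to the shorter overlap, which has the
lower mismatch fraction. The mismatch penalty matters: a long spurious
overlap matches about 25% of its bases by chance, so a match-only
objective would prefer it to a shorter perfect overlap and the pair would
then fail the mismatch cap. Pairs with no positive-scoring overlap, or
whose best overlap exceeds a 25% mismatch fraction, stay unmerged;
overlap conflicts resolve to the higher-quality base. This objective
approximates (but is not identical to) FLASH's mismatch-ratio rule.

Merged reads are translated in all six frames and aligned locally
(Smith–Waterman, BLOSUM62, gap open 11 / extend 1) against the reference
peptide set; the best HSP gets a Karlin–Altschul E-value
$E = K m n e^{-\lambda S}$ with the standard gapped BLOSUM62 constants
$\lambda = 0.267$, $K = 0.041$ and $n$ the reference residue count
(configurable), and hits with $E > 10^{-3}$ count as no-hits — the
E-value cut is applied before any other filter. Reads with no hit, an HSP
peptide containing a stop codon (a frameshift symptom), or an HSP shorter
than 30 aa (exactly 30 is kept) are discarded; survivors are the
*inferred peptides*. The statistic of interest is

$$\text{sensitivity} = \left\lfloor 100 \cdot
  \frac{\#\text{inferred peptides}}{\#\text{merged reads}} \right\rfloor$$

truncated (not rounded) to an integer percent — truncation reproduces the
published validation percentages from their own read counts (one printed
row does not follow from its counts under either convention and ships
flagged as inconsistent). The discard classes partition the merged reads,
an invariant the tests enforce.

The generic nucleotide QC used for 16S-style reads (drop reads < 50 nt,
\> 2% ambiguous bases, or > 2% of bases inside homopolymer runs) is also
provided; "2% homopolymers" is not a precisely defined notion, so it is
operationalized as the fraction of bases inside runs of ≥ 8 nt
(configurable).

## Simplified phylogenetic placement

Full evolutionary placement (ML insertion of each query into each tree
edge) is deliberately not re-implemented. `place()` keeps the same
interface — query in, tree node plus mass out — so an ML backend can be
swapped in later: the query is aligned to each reference row, leaves
within 2 percentage points identity of the best (the near-tie margin,
sized to absorb alignment noise without collapsing distinct genera in the
synthetic benchmarks) form the candidate set, and the placement goes to
the single candidate leaf or to the candidates' last common ancestor with
mass 1. A multi-placement mode spreads mass score-proportionally over the
top *k* leaves. Queries aligning fewer than 10 columns are unalignable
and counted unclassified.

Downstream: per-node masses below 1% of total are trimmed (a node exactly
at the threshold is retained; this flat per-node rule simplifies the
leaf-to-root mass semantics of pplacer-style trimming and is
configurable); the composite score `(identity + coverage)/2 > 93`
separates classified from unclassified queries; a PhyloXML "fat tree" is
exported with branch widths proportional to subtree read mass and
root-to-placement paths in red; and placements aggregate to an abundance
table at a requested rank, with a placement at an internal node counted
at the deepest rank shared by its subtree's leaves (mass that cannot be
attributed at the requested rank is reported at the shared shallower
rank). Classified plus unclassified fractions sum to one.

## The synthetic-data generator

`simulate_family()` evolves a random (stop-free, codon-aware by default)
ancestor down a random tree under per-site substitution; designated
conserved blocks mutate at a reduced rate, emulating the conserved
regions that degenerate marker-gene primers target. Defaults — 20 leaves,
900 nt, mean root-to-tip divergence 0.10 substitutions/site, three 30-nt
blocks at 11%/33%/55% of the length with rate multiplier 0.05 — give
realistic marker-gene-like families whose best primer pairs (product
roughly 230–430 bp) fall inside the planted blocks (block positions scale
with the ancestor length: 11%, 33% and 55%). There are no indels in the
default model, so the simulated sequences are simultaneously their own
alignment and positional Hamming in-silico PCR is exact; indel realism is
intentionally out of scope.

The two-clade mode joins two such clades by stem branches that evolve at
full rate *including inside the conserved blocks* and saturate by default
(1.5 substitutions/site on the stem path): the clades become distinct
sequence clusters sharing no conserved windows, which is the regime in
which a hypervariable family defeats single-pair design and must be
partitioned phylogenetically — mild between-clade divergence (say, a
realized p-distance of 0.3) leaves plenty of family-wide low-degeneracy
windows and is *not* that regime.

`simulate_amplicon_library()` draws on-target read pairs from predicted
amplicons of random family members (2 × 250 nt reads, the MiSeq setting
the markers were validated with; constant Phred 35 qualities keep merging
deterministic; substitution errors at 0.2% per base) and off-target pairs
from random fragments of the same length — contaminants that merge
cleanly but match no reference, so the pipeline's sensitivity estimates
the planted on-target fraction. A truth table records every read's
origin. `simulate_reference_set()` translates the family in frame 1,
reuses the true tree, and assigns a synthetic ranked taxonomy (orders
from the root split, genera from average-linkage clusters of tree
distances).

What passing the synthetic benchmarks does *not* show: robustness to
indels, chimeras, realistic Illumina error profiles, abundance skew, or
reference sets with uncurated false positives — real libraries have all
of these.

## Benchmark problem sizes and numerical choices

The shipped test suite and acceptance script use: 2,000 read pairs per
library at on-target fractions 0.3/0.6/0.9 (recovery within 5 percentage
points), with the library's primer pair designed under a 450 bp product
cap so that 2 × 250 nt read pairs always overlap by at least 50 nt and
merge; 20 replicate families for designability (≥ 90% of members
amplified at the 2-mismatch budget) and for two-clade partition recovery;
200 placement queries at ≤ 10% amino-acid divergence (≥ 85% placed at the
source leaf or an ancestor); 200 random in-silico PCR instances checked
site-for-site against a brute-force expand-and-Hamming oracle; and 1,000
random oligos checked against brute-force expansion counting.

Numerical conventions worth knowing: coordinates are 0-based half-open
internally and in TSV output (a flag emits 1-based inclusive for
cross-checking against other scanners); degeneracy is a double (it
overflows integers for N-rich oligos); sensitivity uses `floor`;
window/pair ranking and all generators are deterministic under a seed;
and empty inputs (empty FASTA, empty family, zero placements) return
empty results rather than errors, except where a statistic would be
undefined (sensitivity with zero merged reads errors; an empty family
reports coverage 0 with a warning).

## Known limitations

Melting temperature and thermodynamics are out of scope (annealing
conditions are determined empirically); mismatch counting ignores indels
in the binding site; the placement scorer is similarity-based, not ML,
and reports no uncertainty; the merge objective is a documented
approximation of FLASH; and the NJ guide tree is an approximation of the
ML trees one would use for a publication-grade partition.
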