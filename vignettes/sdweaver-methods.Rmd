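---
title: "Targeted assembly of collapsed segmental duplications: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted assembly of collapsed segmental duplications: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Segmental duplications (SDs) are genomic segments present in several copies at
high sequence identity (often above 99%). In whole-genome assemblies built
from error-prone long reads, the copies collapse: reads from every copy pile
onto a single representation because the per-read error rate (10–15% for
PacBio CLR or older Nanopore chemistry) dwarfs the 0.1–1% divergence between
copies. sdweaver resolves such regions by *targeted, iterative* assembly: the
user supplies an initial anchor sequence from unique sequence flanking one
copy, and the assembler grows a contig one window at a time, at each step
keeping only the reads that belong to the copy being walked.

Each iteration has four phases:

1. **Mapping.** Reads similar to the current anchor are recruited from an
   in-memory minimizer index (canonical k-mers, `k = 15`, window `w = 10`).
   A read is retained when its chained minimizer hits span at least half the
   anchor length (`min_cov_frac = 0.5`), mirroring the behaviour of a
   PAF-emitting mapper whose alignment block covers the anchor.
2. **Clustering.** Reads and anchor are homopolymer-compressed (HPC), which
   absorbs the dominant indel error mode of long reads. Reads spanning the
   full HPC anchor are genotyped at *cis-morphisms* — single-nucleotide
   differences between SD copies visible as pileup columns whose second most
   frequent state exceeds a threshold. A similarity graph connects reads with
   near-identical genotypes; its connected components are partitioned by
   randomized recursive splitting, and the cluster continuing the previous
   iteration's selection is chosen.
3. **Assembling.** The selected cluster's reads, truncated to the anchor
   window plus a flank, are assembled into a consensus contig: a backbone
   seeded by the anchor plus a representative read tail, then several rounds
   of banded realignment and per-column majority voting (bases, deletions,
   and pooled insertion votes).
4. **Extending.** The anchor is located in the contig by infix alignment
   (free end gaps, minimal Levenshtein distance). The contig slice covering
   the anchor replaces the tail of the growing assembly and the novel suffix,
   capped at `step_cap` bases, is appended; the last `anchor_len` bases
   become the next anchor.

Iteration ends when no reads span the anchor, when the contig stops growing,
when the anchor can no longer be located at 90% identity (the run has lost
track of its locus), or at a configured length/iteration cap.

## Cis-morphisms in homopolymer-compressed space

A single-base substitution between two SD copies survives homopolymer
compression as a *substitution column* only when neither the original nor the
substituted base matches a neighbouring base. At uniform base composition
this is only roughly a quarter of sites; the rest merge with or split an
adjacent run and become single-base HPC indels. The minority copy then shows
a systematic *deletion* against the anchor at that column. sdweaver therefore
genotypes five states per column — `A, C, G, T` and deletion — and treats
insertion evidence as unusable (an inserted base has no column of its own).
Without deletion genotypes roughly 60% of the usable signal would be lost,
which at desk scale (1–2 kb anchor windows) starves the clustering.

Pileup columns are noisy in state-specific ways: substitutions spread the
9%-per-base substitution error over three alternative bases plus alignment
wobble (~4% per column at 15% read error), while HPC deletions arise mostly
from lost single-base runs (~6.5%). The default thresholds derive from these
rates (`pileup_state_rates()`), scaling linearly with the configured error
rate. A locus is called when its second state exceeds its noise expectation
(z > 2) *and* a copy-fraction floor (a quarter of one copy's expected share
of the pileup); candidate loci are thinned so that any 3-column neighbourhood
contributes only its strongest locus, because alignment wobble around
homopolymer boundaries produces correlated artifact columns in small
neighbourhoods.

The deliberately permissive call gate matters for deep stacks: with ten
copies piled up, a site private to one copy has a second-state frequency
around 0.08 — at or below the top-level noise floor. Such loci only become
decisive *within* partition nodes after other copies have been split off,
which is why the recursive partition re-tests every locus against the noise
expected at its own node depth, and why whole blocks are recursively
re-called and re-partitioned (`refine_block`) while any child remains larger
than about 1.7 copies' worth of reads.

## Randomized clustering and its guards

Within a block, each of `n_sim = 100` simulations (the benchmark driver uses
52) recursively splits the
reads on a uniformly chosen informative locus (reads grouped by their state;
missing and sub-threshold states join the majority branch). Two guards keep
the recursion honest:

* **Cluster-size floor.** A split is accepted only when every constructed
  child, *after* reads are re-assigned to their nearest child consensus,
  holds at least `min_frac = 0.8` times the expected number of
  anchor-spanning reads per copy. The driver estimates that expectation
  analytically from the configured coverage and read-length distribution,
  bounds it by the observed count at the first (unique-anchor) window, and
  passes a lower confidence bound (`lambda - 2*sqrt(lambda)`) so that
  binomial fluctuation of a true copy's read count does not forbid its own
  split. At 18 kb reads and a few-kb anchor the spanning count approaches the
  fold coverage and the floor reduces to the familiar `0.8 x coverage`.
* **Complexity penalty.** The best clustering minimizes the summed Hamming
  distance of every read to its nearest cluster consensus. Because that sum
  always improves with finer partitions, clusterings are compared with a
  per-cluster penalty equal to one copy's expected read count: an extra
  cluster must explain at least one copy's worth of distance. A split on a
  single artifact locus saves far less; a true copy's split saves much more.

After the best clustering is chosen, reads are assigned to their nearest
cluster consensus. This matters for the parameter-recovery property (ARI 1.0
against truth labels): without re-assignment, every read with a miscall at
the split locus would be misrouted.

Selection follows the paper's continuity rule — the cluster sharing the most
reads with the previous selection (first iteration: the cluster whose
consensus genotype is closest to the anchor's own bases). Two pragmatic
safeguards address desk-scale failure modes: an oversized selected cluster
(> 1.4 copies) is trimmed to reads whose genotypes agree with the *carriers*
(reads shared with the previous selection) and then re-refined at a relaxed
floor and penalty (half a copy each) to strip lingering sibling copies; a
run whose selected consensus disagrees with its own anchor at more than 30%
of comparable loci terminates as lost-track. The consensus template tail
is seeded with the *medoid* of the longest read tails, so that where a
duplication boundary splits the cluster's tails into incompatible camps
(each copy exits into its own flanking sequence) the majority camp polishes
coherently.

## Consensus accuracy

The polisher is a windowed majority voter over banded realignments. Exact
insertion strings fragment under read errors, so insertion votes at a
junction are pooled and the plurality string is emitted once pooled support
clears 40% of the local depth. With independent per-base errors (the
simulator's model), measured consensus accuracy on fully covering reads is
about 1.4 errors/kb at 20x, 0.7/kb at 30x and 0.3/kb at 40x. Two geometric
choices keep the *final* consensus of every base at full depth: the per-step
extension (`step_cap`) never exceeds the anchor length, so every appended
base is re-polished inside a later anchor window at full spanning coverage;
and the driver trims the final, once-polished tail (`trim_tail`, default
`step_cap`) from the reported contig. Clustering uses only anchor-spanning
reads, but consensus additionally uses *partial* reads: recruited reads that
cover part of the window are genotyped over the loci they reach and join the
polish set when their genotype matches the selected cluster's consensus and
no other cluster better.

## The simulator

`evolve_units()` assigns a root sequence to a tree (star, balanced binary,
caterpillar, or random binary; `topology_tree()`) and generates every child
by copying its parent and substituting each base independently at a fixed
per-edge rate, to a uniformly chosen different base. The benchmark maps the
"SD sequence identity" parameter to that per-edge rate (`rate = 1 -
identity`), so leaves of deeper topologies accumulate proportionally more
divergence from the root — the natural reading of a fixed per-edge process.

`build_collapsed_contig()` concatenates the leaf units with i.i.d. random
flanks at both ends and optional random spacers between units; every
flank/spacer is regenerated until it shares no 21-mer with any unit, which
guarantees an unambiguous initial anchor. The benchmark suite sets
`spacer_len = flank_len`, giving every leaf its own unique preceding flank to
anchor from. `sample_reads()` draws read starts uniformly, lengths from a
truncated normal, reverse-complements half the reads, and applies
independent per-base errors split 60/25/15 across
substitution/insertion/deletion — a fixed mix approximating CLR behaviour.
Truth labels follow the read midpoint.

What the simulator does *not* emulate: chemistry-specific error profiles
(homopolymer-biased indels, quality ramps), tandem repeats or mobile
elements inside units, structural events other than substitution, and
coverage biases. Consensus accuracy on real CLR data will therefore be
somewhat worse than on simulated reads at the same nominal error rate, and
regions dominated by tandem repeats remain out of reach — consistent with
the failure modes reported for real SD-rich clones.

## Benchmark design and evaluation

The desk-scale benchmark (`sd_benchmark()`, `benchmark_preset("desk")`) runs
ten evolutionary scenarios — flat with 2, 4 and 8 leaves; three bifurcating
shapes (balanced 8, asymmetric 8, balanced 12); cascading with 4 and 8
leaves; two random trees with 10 leaves — at 20 kb units, 99.5% identity,
8 kb unique flanks, 40x coverage, 15% error and 5 kb ± 1 kb reads. Each leaf
is assembled once from the last 2 kb of its preceding flank with a length cap
of one anchor plus one unit plus about 2 kb, so a correct run traverses its
entire SD copy and stops inside its following flank. Desk geometry:
`anchor_len = 2000`, `step_cap = 1900`, truncation `flank = 2400`; these keep
roughly 24
anchor-spanning reads per copy for clustering while partial reads restore
full depth for consensus. A `paper_scale` preset (0.45 Mb flanked units,
18 kb ± 3 kb reads) mirrors the original experiment scale and is provided
for completeness; it is slow and not exercised by the tests.

Evaluation follows the validation protocol: per contig, the best
minimizer-seeded alignment against each truth unit; a contig is assigned to a
unit when the alignment covers at least 95% of the contig and its Phred score
`Q = -10 log10(1 - identity)` is the highest among all units (ties: lower
edit distance, then unit order, flagged ambiguous). A unit is resolved when
some contig is assigned to it. Truth units carry their unique flanking
context (`flanked_units()`), since a per-leaf targeted run legitimately
reconstructs flank–unit–flank; runs that never left their starting window are
excluded as failed assemblies rather than scored as stubs. The BAC-style
rule (`bac_style_resolution()`) instead requires 99.5% coverage of the
reference clone. Perfect identity is reported at the conventional FASTQ cap
of Q60. Identity is computed as one minus edits over alignment columns
(matches + mismatches + indels), on the full aligned region.

## Numerical and degenerate-input choices

* Alignment is unit-cost Levenshtein with a banded dynamic program; the band
  doubles until the distance is provably optimal (distance < band) or a cap
  is reached. Ties prefer diagonal moves, giving canonical alignments.
* Consensus tie-breaks are lexicographic; deletions must exceed half the
  local depth; all-gap columns drop.
* An anchor region with no cis-morphisms behaves as a plain targeted
  assembler: one cluster holding every spanning read.
* Empty inputs error early (`edit_align`, `build_pileup`, `random_partition`);
  an unrecruitable initial anchor is a hard error with a diagnostic, while
  downstream read exhaustion terminates the run with a status.
* All randomness flows from the single configured seed; per-block clustering
  seeds derive deterministically from (seed, iteration, block).

## Known limitations

* Sibling copies at the low end of the divergence range (about 1% pairwise,
  i.e. two tree edges at the default rate) can fail to separate in windows
  where too few of their distinguishing sites are callable; the run then
  either exits through the wrong copy's flank (contig unassigned) or drags a
  residual two-copy mixture through a few windows, depressing consensus
  quality to the low twenties (Phred) instead of about thirty. At desk scale
  this affects on the order of one leaf per dense scenario; longer reads
  (paper scale) enlarge the window and the margin.
* The evaluation's 95%-coverage rule makes contigs that wrongly exit into a
  different copy's flank unassignable rather than misassigned — resolution
  percentages degrade gracefully, but no rescue is attempted.
* Runtime is dominated by banded alignments in the pileup and polishing
  phases; the ten-scenario desk benchmark runs in roughly a quarter of an
  hour on one CPU.
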