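---
title: "Combinatorial pooling and k-mer deconvolution: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial pooling and k-mer deconvolution: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolkit)
```

## The problem

Clone-by-clone sequencing of a large insert library — say the minimum tiling
path (MTP) of a BAC physical map, a few thousand clones of roughly 100–150 kb
each — needs a way to assign short reads back to the clone they came from.
Barcoding every clone is expensive; `poolkit` implements the combinatorial
alternative. Clones are mixed into pools following a *shifted transversal
design* (STD): each clone is present in a unique, small set of pools (its
*signature*), and any DNA that belongs to a clone necessarily shows up in the
sequencing output of exactly those pools. Deconvolution then reduces to a
set-matching problem between observed pool occupancy patterns and unions of
clone signatures.

## The pooling design

An STD(P, L, Γ) has L layers, each a partition of the clones into P pools
(P prime, L ≤ P). Clone i, written in base P as digits
$(i_0, \ldots, i_\Gamma)$, joins in layer $j$ the pool

$$ jP + \Big( \textstyle\sum_{c=0}^{\Gamma} i_c\, j^c \bmod P \Big), \qquad j = 0, \ldots, L-1 . $$

The layer polynomial is the whole trick: two distinct clones agree in a layer
only where the difference polynomial has a root, and a nonzero polynomial of
degree ≤ Γ over GF(P) has at most Γ roots, so **two signatures share at most
Γ pools**. Consequently unions of up to $d = \lfloor (L-1)/\Gamma \rfloor$
signatures are pairwise distinct (`decodability()`), and the minimum symmetric
difference between signatures is at least $2(L-\Gamma)$
(`min_signature_distance()`).

Conventions fixed by the package: layer shifts are $j = 0 \ldots L-1$ in
order, items are 0-based, and pool numbering is layer-major (layer $j$ owns
pools $[jP, (j+1)P)$). The optional extra "special" layer of the general STD
construction is not implemented; `layers <= p` is enforced, which is the
regime a pooled-sequencing experiment uses in practice.

The package's running example is STD(13, 7, 2) filled to its capacity of
$13^3 = 2197$ clones: 91 pools, 169 clones per pool, 7 pools per clone,
three-decodable, and pairwise sharing percentages 57.9 / 30.6 / 11.5 for
0 / 1 / 2 shared pools.

**The triple-sharing statistic.** For a triple of clones the package reports
the *union deficit* $3L - |sig(a) \cup sig(b) \cup sig(c)|$ — the total
number of pool collisions inside the triple. The alternative reading,
"pools common to all three signatures", maxes out at Γ; the union deficit
maxes out at 3Γ, which is the range over which a three-decodable design needs
to be characterised (at Γ = 2 a triple can collide in up to six pools), so
the union deficit is the statistic `triple_sharing()` computes. Sampling is
without replacement and driven by R's RNG, so a fixed seed reproduces the
histogram exactly.

## Read simulation

`sim_genome()` + `sim_clone_layout()` + `sim_pool_reads()` emulate the
pooled sequencing of a tiled clone set:

* clones tile the genome left to right with Normal lengths and Normal
  consecutive overlaps (both truncated); no base may be covered by more than
  three clones, matching what a three-decodable design can resolve;
* each pool's reads are drawn only from its member clones, in proportion to
  clone length; insert lengths are Normal(`insert_mean`, `insert_sd`) clamped
  to `[read_length, clone length]`, and fragments never run past clone ends
  (a BAC read contains only clone sequence);
* sequencing error is i.i.d. per-base substitution — no indels, constant
  (Q40) base qualities — applied at `error_rate`;
* optionally a fraction of read pairs is drawn from a contaminant sequence
  (the role *E. coli* carrier DNA plays in real BAC pools) and flagged;
* every read name carries `id|clone|pool|fragment start|fragment end|contam`
  with `|` reserved, and a truth TSV maps each mate to its source, so
  evaluation never has to re-align anything.

Defaults mirror a typical short-read pooled-BAC experiment: 104-base mates,
327-base mean insert, 1% error. The insert-length standard deviation is not
something a mean alone determines; the package defaults to 10% of the mean
and exposes it.

What the simulator deliberately does **not** model: indels, position-
dependent quality, PCR/amplification bias, chimeric fragments, and the
repeat landscape of real plant genomes (repeat families are available but are
mutated copies of a single unit, far tamer than LTR retrotransposon nests).
Passing simulation tests therefore demonstrates the correctness of the
*combinatorial machinery* — design, counting, classification, accounting —
not that any particular real genome will deconvolute at the simulated rates;
on repeat-rich genomes a substantially larger fraction of k-mers ends in the
`repeat_discard`/`unmatched` bins.

## The k-mer count table

All ACGT windows of length k are counted per pool under canonicalisation
(the lexicographic minimum of the k-mer and its reverse complement — 2-bit
base coding makes numeric and lexicographic order coincide). Windows touching
a non-ACGT symbol are skipped; upstream trimming drops reads containing `N`
anyway. Counts saturate at 65,535 (documented cap): classification only uses
positivity and relative magnitude, never absolute depth. No low-count
pre-threshold is applied before classification — the decision tree's
`w < L` band already absorbs sporadic error k-mers, and thresholding would
silently change the support sizes the tree reasons about.

**Why k = 26.** The deconvolution should notice that two reads of length
104 overlap by at least 75% (78 bases) even if the overlap carries two
sequencing errors. By pigeonhole, `max_mismatches` errors in an
`overlap_length` window always leave an exact run of at least
$\lceil (78-2)/3 \rceil = 26$ bases (`guaranteed_match_length()`, verified
against enumeration of every mismatch placement), so a 26-mer from the
overlap is guaranteed to be seen intact. `k` stays exposed — shorter k-mers
gain sensitivity and lose specificity.

## Classification and read assignment

For a k-mer observed in a read from pool $s$, let $w$ be the number of pools
with a positive count. With $U_1 = L$, $U_2 = [2L-2\Gamma,\, 2L]$ and
$U_3 = [3L-3\Gamma,\, 3L]$:

1. $w < L$: discard (`error_discard`) — some pool of the source clone is
   missing, so the k-mer likely contains an error (or depth failed locally).
2. $w = L$: assign iff the support equals one clone signature.
3. $L < w < 2L-2\Gamma$: drop the $w-L$ smallest counts and re-test as (2).
4. $w \in U_2$: assign iff the support equals the union of two signatures.
5. $2L < w < 3L-3\Gamma$: drop down to $2L$, re-test as (4).
6. $w \in U_3$: assign iff the support equals a union of three signatures.
7. $w > 3L$: discard (`repeat_discard`) — the k-mer is ubiquitous.

Numerical choices the bands do not pin down by themselves:

* **Bands are tried strictly in this order, no fall-through.** For small L
  and large Γ the two- and three-union bands can touch (e.g. $w = 2L$ when
  $3L - 3\Gamma \le 2L$); the first applicable band decides which single
  match is attempted, and a failed equality test is final (`unmatched`).
* **The drop rule never removes the source pool's entry** — the pool the
  read came from genuinely contains the k-mer; among equal smallest counts
  the lower pool index is dropped first, making the reduction deterministic.
* **Union searches scan candidates in ascending clone order** (candidates =
  clones whose full signature is inside the support), so on the rare designs
  where a union admits several representations the lexicographically first
  one wins, deterministically. At full capacity and within the design's
  decodability the representation is unique.

The implementation (candidate pruning, bitset unions, per-pool memoisation)
is tested for exact agreement with an independent brute-force search over
*all* 1-, 2- and 3-clone unions on every support of a small design.

A read is then assigned to the union $B$ of its assigned k-mers' clone sets
iff $1 \le |B| \le 3$ — its *read signature*, the union of those clones'
signatures, then automatically matches a 1-, 2- or 3-clone signature union.
Reads with no assigned k-mer, or mixing more than three clones, are
non-deconvolutable and kept in a separate file. Mates are deconvoluted
independently as single-end reads; mate agreement is an *evaluation* metric,
not an input to assignment.

Planning guidance surfaced by the documentation but deliberately not
enforced anywhere: post-deconvolution per-clone depth of at least ~50x gives
good clone assemblies, which with depth amplification in mind suggests
150–200x pre-deconvolution pool coverage.

## Evaluation metrics

* `deconvolution_rate`: deconvoluted reads / input reads.
* `correctness_rate`: among deconvoluted reads, the fraction whose clone set
  contains the source clone *or a clone overlapping it* in the layout —
  sequence in an overlap belongs to both clones, so either assignment is
  right. Correctness is defined over deconvoluted reads only.
* `mate_concordance`: pairs with both mates non-deconvolutable are excluded;
  among pairs with at least one assigned mate, a pair is concordant iff both
  mates are assigned and one clone set contains the other. Counting
  one-assigned pairs as eligible-but-discordant is the stricter of the two
  readings of an ambiguous convention; it is documented rather than assumed
  to be the only one.
* `per_clone_depth`: a read assigned to several clones contributes its bases
  to each of them (depth amplification); sizes come either from the layout
  or from fingerprint band counts via `calibrate_band_multiplier()` — a
  library of mean clone length 106 kb with a mean band count near 90 gives
  the canonical ~1175 bases/band multiplier.

## Marker decoding

Pool-level binary marker calls (a GoldenGate assay run on the pools) are
decoded per marker: with $S$ the positive-pool set, choose the clone set $T$
($1 \le |T| \le 3$) minimising $E(T) = |P(T) \setminus S| + |S \setminus
P(T)|$, and call the marker non-decodable when the minimum exceeds 3 errors
(`error_cap`, exposed). The search is restricted to clones sharing at least
$L - \mathrm{error\_cap}$ pools with $S$: a clone below that bound already
contributes more than `error_cap` missing observations on its own, so the
restriction cannot change a decodable argmin; for non-decodable markers the
reported error count is the candidate-space minimum (still > cap). Ties are
broken by smaller $|T|$, then clone order — the tie-break is a determinism
choice, not a claim about biology. Note the interaction with flipped-off
*shared* pools: removing a private pool of one clone from a two-clone union
can leave a one-clone explanation with the same error count, which then wins
the smaller-set tie-break; simulations of planted markers show this costs a
small percentage of exact recoveries at realistic noise.

## Preprocessing

`quality_trim()` scans each read with a sliding window (default 4 bases,
configurable) and cuts at the start of the first window whose *mean* Phred
quality drops below 23; reads shorter than 36 bases after trimming, or
containing `N`, are dropped. The window length and mean-comparison are the
package's own defaults — a single-base threshold is noisier, a long window
too forgiving; both knobs are exposed. Adapter and contaminant removal
(alignment against vector/host) are left to upstream tools.

## Robustness to a missing pool

The package treats "losing a pool" as re-running deconvolution without that
pool's *reads* while keeping the already-built count table — the realistic
failure mode (a pool dropped from sequencing after the table exists, or
reprocessing with one input removed). In that regime the remaining reads
classify identically and the overall rate barely moves. Rebuilding the table
without the pool is a different and much harsher experiment: every member
clone of that pool then presents $w = L-1$ supports and band (1) discards
its unique k-mers, so roughly a fraction $P^\Gamma/n$ of reads would be lost
by construction. The strict decision tree is intentionally kept strict; an
error-tolerant re-match of near-miss supports (and iterative error
correction generally) is out of scope.

## Problem sizes and degenerate inputs

The test and acceptance suites run, on one CPU in a few minutes: the full
design combinatorics at n = 2197 (exact, all 2.4M pairs; 10⁶ sampled
triples); simulations on STD(5, 4, 1) fully loaded with 25 clones of 30 kb
at 30x per pool — disjoint/error-free for the no-noise round trip, 10 kb
overlaps with 1% error for the realistic case; exhaustive
classification-vs-oracle checks on STD(3, 3, 1, 9); and marker decoding
against an exhaustive oracle on 25 clones plus planted-set recovery at
n = 2197. These sizes are the package's chosen trade-off between runtime and
statistical resolution; all of them scale up by changing arguments only.

Degenerate inputs are defined, not accidental: designs with n = 1 have empty
pair statistics and no distance; pools with no usable clone yield empty
FASTQ files with a warning; clones shorter than the mean insert are skipped
with a warning; reads shorter than k contribute no k-mers and come out
non-deconvolutable with reason `no_assigned_kmers`; an empty marker call set
is non-decodable with an `NA` error count.

## Known limitations

* The count table lives in memory for the R session (an external pointer);
  the TSV export is for small tables, not a database format. Genome-scale
  tables need tens of GB, as hash-table k-mer counting always does.
* Substitution-only error model; no indel handling anywhere downstream.
* No iterative error-correction/deconvolution loop, and non-deconvoluted
  pool leftovers are not assembled or rescued.
* `layers <= p` only (no special layer), and sampled triple statistics
  support at most 2^21 items.
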