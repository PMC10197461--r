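---
title: "Minimizer-digested r-index classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimizer-digested r-index classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minidex)
```

## The problem

Read classification — deciding whether a sequencing read originates from a
reference collection, and if so from which class of genomes — underlies host
depletion, contamination screening, metagenomic assignment, and adaptive
sampling on nanopore devices, where the decision must be made from the first
few hundred bases while the molecule is still in the pore. Pangenome
references (hundreds of strains per species) make alignment-based approaches
expensive; `minidex` instead combines two compression ideas:

1. **Minimizer digestion.** A window of `w` consecutive bases is slid one
   base at a time; in each window the constituent `k`-mer with minimal hash
   is the *minimizer*, and the digest is the concatenation of the selected
   minimizers with runs of equal values collapsed to one symbol. The digest
   is several-fold shorter than the input, and, optionally, each possible
   `k`-mer becomes one symbol of a *minimizer alphabet* (`4^k` symbols; 256
   for `k = 4`, fitting one byte).

2. **Run-length BWT indexing.** The digest collection is concatenated (one
   sentinel per document) and indexed by its Burrows–Wheeler transform,
   stored run-length encoded. For repetitive collections the number of runs
   `r` grows with the *distinct* sequence content, not the total length `n`,
   so near-identical strains cost almost nothing. The package reports `n`,
   `r` and `n/r` for every build.

## Matching statistics and pseudomatching lengths

For a pattern `P[1..m]` and text `T`, the matching statistic `MS[i]` is the
length of the longest prefix of `P[i..]` occurring anywhere in `T`.
Backward search over the BWT computes these right-to-left: at each step the
LF mapping prepends one character to the current match. When the current
row's BWT character mismatches the next pattern character, the algorithm
jumps to the nearest run of the needed character either above or below; a
per-gap *threshold* — the row of the minimum LCP value between two
consecutive runs of the same character — decides the direction that
preserves the longer match.

*Pseudomatching lengths* (PMLs) are the one-pass approximation: a length
counter increments on every successful LF extension and resets to 0 on
every threshold jump, and the emitted counter values are the PMLs. They are
position-wise bounded above by the matching statistics and retain their
discriminating power — reads from the reference produce long PML runs,
foreign reads do not. Computing exact MS additionally requires suffix-array
samples at run boundaries plus random access to the text (kept only when an
index is built with `msSupport = TRUE`): the first pass records a candidate
text offset per position, the second pass measures each match length by
direct comparison.

The sampled *document array* stores, for each of the `r` runs, the class
label of the suffix at the run's first and last row (`2r` labels, packed in
`ceil(log2 c)` bits each). Every threshold jump lands exactly on a run
boundary, so the label there is read off ("case 2") and carried through
subsequent extensions ("case 1"), yielding one class label per read
position. Aggregating these labels over the read gives a multi-class call.

## Classification rules

* **Null threshold.** Substrings are drawn from the original reference,
  character-reversed (not reverse-complemented, so base composition is
  preserved while genuine matches are destroyed), digested exactly like
  reads, and their PMLs pooled. The classification threshold is the largest
  null PML occurring at least `minCount = 5` times; 0 if none qualifies.
* **Windowed majority.** A read's PML vector is cut into non-overlapping
  windows of 150 symbols from the left end; a trailing short window merges
  into its predecessor, and a read shorter than 150 symbols is one window.
  A window is "above" iff its maximum PML strictly exceeds the threshold;
  the read is *present* iff strictly more than half its windows are above.
  Ties therefore resolve to *absent*.
* **Contamination scan.** Each assembly contig is streamed as one read; the
  contig is flagged *suspicious* iff the 25th percentile of its PML
  distribution is at or above 2 (inclusive). The percentile uses the
  inverse-ECDF quantile (`type = 1`), so it is always an observed integer.
* **Adaptive batches.** Bases arrive in batches of 180; after each
  accumulated prefix (up to 4 batches) the windowed rule runs, and the
  first *present* verdict ejects the read. Because batches extend the read
  on the side the right-to-left pass consumes last, the driver recomputes
  PMLs on the accumulated prefix at each batch; the exact pause/resume
  machinery (`resumePmls`) is exposed for callers that can deliver chunks
  right-to-left, where chunked output is identical to single-shot output.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 4 | minimizer length (bases); fixes the minimizer alphabet at `4^k = 256` symbols |
| `w` | 11 | window length (bases); larger `w` = sparser digest, smaller index, shorter matches |
| `seed` | 42 | k-mer hash seed, recorded in the index header for reproducibility |
| `nullReads`, `nullReadLength` | 500, 2000 | reversed substrings drawn for the null PML distribution |
| `nullMinCount` | 5 | occurrence floor of the threshold rule |
| `window` | 150 | classification window, in processed symbols (digest symbols for digested indexes, bases otherwise) |
| `batchBases`, `maxBatches` | 180, 4 | adaptive-sampling batch protocol |
| percentile, cutoff | 25, 2 | contamination rule (inclusive cutoff) |

## Numerical and design choices

* **Hashing.** k-mers are packed 2 bits/base and mixed with the seed by
  splitmix64; values are truncated to 53 bits so they are exact doubles in
  R. Ties in a window break to the leftmost k-mer. Digest collapsing is by
  *value*: a minimizer is appended only when it differs from the previously
  appended one, so adjacent distinct occurrences of the same k-mer also
  collapse. Windows containing non-ACGT characters are skipped, which
  equals digesting ACGT segments independently.
* **Sentinels.** One per document, all ranking below the data alphabet and
  among themselves by document order — suffix order, and hence every
  downstream structure, is fully deterministic. Sentinel codes are negative,
  so they can never collide with data symbols.
* **Thresholds.** For each gap between consecutive runs of a character, the
  threshold is the row of the *leftmost* minimum LCP in the gap; rows
  strictly above it jump up (to the earlier run's last row), rows at or
  below jump down (to the later run's first row). The convention is pinned
  by a brute-force property test: every directed jump preserves a common
  prefix at least as long as the rejected direction, exhaustively over
  random texts.
* **Initial state.** Matching starts at BWT row 0 with length 0; the first
  read symbol is processed as an ordinary step (usually a jump). Any start
  row yields valid PMLs since the first mismatch resets the state; row 0 is
  chosen for determinism. On a jump the emitted PML at that position is 0
  (the reset itself); the matched character contributes to the *next*
  position's increment. A read symbol absent from the index alphabet emits
  0 and leaves the row unchanged.
* **Class labels.** Positions before the first case 2 have no label (`NA`)
  and are excluded from aggregation; multi-class ties break to the smallest
  class id and are flagged. Label aggregation is unweighted by default.
* **Reverse complements** are added at build time as extra documents of the
  same class, so reads are queried in their given orientation only.
* **Construction.** Suffix arrays are built by prefix doubling and LCPs by
  Kasai's algorithm — O(n log² n) and O(n), ample at desk scale; the index
  targets correctness and `O(r)`-sized *storage* of the query structures,
  not `O(r)`-space construction.

## What the synthetic generator emulates — and what it does not

`simulatePangenome` mutates a random ancestor into class bases
(inter-class divergence, default 10%) and strains (intra-class divergence,
default 1%), substitution-only. `simulateReads` draws substrings from
either strand, injects substitution errors (default 5%, the error regime
of long nanopore reads; 1 kb reads stand in for them at desk scale), or
emits i.i.d. random reads as negatives. The generator does **not** emulate
indels, ONT homopolymer error structure, read-length distributions,
base-composition bias, or genome rearrangements. Passing tests therefore
demonstrate the correctness of the index and the discriminating behaviour
of PML-based classification under substitution noise — not calibrated
accuracy on real instrument data.

Default study sizes (used by the test suite and the acceptance script):
binary recovery indexes 5 strains of 5 kb at 1% divergence (both strands,
`k = 4`, `w = 11`, minimizer alphabet) and classifies 200 true 1 kb reads
at 95% identity plus 200 random reads; multi-class recovery uses 3 classes
× 2 strains (10% inter, 1% intra) with 100 reads per class; the
contamination scan plants 2 genome-length (5 kb) copies mutated at 1%
among 20 random 5 kb contigs. Oracle checks run on 1000 random
text/pattern pairs (≤ 2000/≤ 100 symbols) and 100 random texts (≤ 200
symbols) with exhaustive per-state verification. These sizes keep every
experiment within seconds while leaving all statistics far from their
decision margins — with one caveat below.

## Known limitations

* The planted-contaminant quartile sits intrinsically near the inclusive
  cutoff: at 1% mutation under (4, 11) digestion roughly a quarter of
  digest symbols carry PML ≤ 1, so the 25th percentile of a mutated copy
  lands in 1–5 while clean contigs sit at 0. The *gap* is unambiguous, but
  at some seeds a planted contig can fall one unit below the fixed cutoff.
  Longer contigs and less divergent contamination (the realistic case)
  move the statistic safely above it.
* PML resets on every jump, including jumps that happen to preserve the
  full match; PMLs therefore under-estimate MS most when the index holds
  few near-duplicates of the matching region.
* The sampled document array records one class per run boundary; when a
  match occurs in many classes, only one is reported per step, and short
  reads aggregate few labels. Label fractions are a plurality signal, not
  a posterior.
* One sentinel per document makes the suffix sort deterministic but adds
  `D` symbols and up to `D` extra runs for a `D`-document collection —
  negligible beyond toy scale.
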