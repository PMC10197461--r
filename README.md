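# minidex

Compressed pangenome indexing and streaming read classification in R.

`minidex` is for analyses that must decide, quickly and in small memory,
whether a sequencing read comes from a (possibly very large) reference
collection — host-read depletion, nanopore adaptive sampling, assembly
contamination screening, and coarse multi-class assignment against strain
pangenomes. It combines **minimizer digestion** with a **run-length
compressed BWT index** and classifies reads from **pseudomatching
lengths**, so the index grows with the *distinct* sequence in the
pangenome rather than its total size.

## The method in brief

* A minimizer scheme `(k, w)` slides a `w`-base window one base at a time
  and keeps, per window, the `k`-mer with minimal hash (leftmost on ties);
  collapsing runs of equal minimizers yields the *digest*, optionally
  re-encoded over the *minimizer alphabet* in which every possible `k`-mer
  is one symbol (`4^k = 256` symbols for `k = 4`).
* The digested documents (plus their reverse complements), one sentinel
  each, are indexed by the run-length encoded Burrows–Wheeler transform.
  With `r` the number of maximal BWT runs and `n` the text length, the
  index costs `O(r)` words and `n/r` measures how repetitive the
  collection is.
* For a read `P[1..m]`, the matching statistic `MS[i]` is the length of
  the longest prefix of `P[i..]` occurring in the reference. The one-pass
  approximation computed by default — the *pseudomatching length* `PML[i]
  ≤ MS[i]` — increments along successful LF extensions and resets to 0 on
  each threshold-guided jump between BWT runs. Exact `MS` is available via
  a second pass when the index retains suffix-array samples
  (`msSupport = TRUE`).
* A *sampled document array* (two class labels per BWT run, `ceil(log2 c)`
  bits each) lets every jump report the class of the run boundary it lands
  on; aggregating the per-position labels over a read gives a multi-class
  call.
* A read is called **present** iff a strict majority of its 150-symbol
  windows has a maximum PML strictly above the *null threshold* — the
  largest PML occurring at least 5 times among reversed reference
  substrings. Contigs are flagged **suspicious** iff the 25th percentile
  of their PML distribution is ≥ 2. Adaptive-sampling decisions re-apply
  the windowed rule after each accumulated 180-base batch (up to 4).

## Worked example

```r
library(minidex)

pg  <- simulatePangenome(nClasses = 2, strainsPerClass = 3,
                         genomeLength = 5000, intraDivergence = 0.01,
                         interDivergence = 0.10, seed = 1)
idx <- buildIndex(pg$sequences, pg$labels,
                  scheme = MinimizerScheme(k = 4, w = 11))
idx
#> PangenomeIndex
#>   alphabet: minimizer (digested, k = 4, w = 11, seed = 42)
#>   documents: 12 in 2 class(es): class1, class2
#>   n = 13229, r = 5854, n/r = 2.26
#>   doc array: TRUE; MS support: FALSE; null PML threshold: 2
```

Six strains and their reverse complements digest to `n = 13229` symbols in
`r = 5854` runs; the null PML threshold 2 was derived at build time from
500 reversed reference substrings. Classify four 95%-identity reads drawn
from the strains and two random reads:

```r
sim     <- simulateReads(pg$sequences, pg$labels, nReads = 4,
                         readLength = 1000, errorRate = 0.05, seed = 2)
foreign <- simulateReads(nReads = 2, readLength = 1000,
                         origin = "random", seed = 3)
classifyReads(idx, c(sim$reads, foreign$reads), multiclass = TRUE)
#>   read_id verdict windows_above windows_total max_pml called_class class_fraction
#> 1   read1 present             1             1       9       class2          0.752
#> 2   read2 present             1             1      18       class2          0.855
#> 3   read3 present             1             1      29       class2          0.833
#> 4   read4 present             1             1      14       class1          0.726
#> 5   rand1  absent             0             1       1       class2          0.584
#> 6   rand2  absent             0             1       1       class1          0.613
```

All four genuine reads are present with max PML 9–29 (well above the
threshold) and the document-array plurality recovers each read's true
class (`class2, class2, class2, class1`); the random reads never exceed
PML 1 and are absent — their `called_class` is the plurality among the few
labels a non-matching read still touches, which is why the verdict, not
the class call, carries the presence decision. A ~1000-base read digests
to ~230 symbols, hence a single classification window here.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/minidex.R build -r refs.fa -o idx -k 4 -w 11
Rscript inst/cli/minidex.R classify -i idx -q reads.fq -o report.tsv --multiclass
Rscript inst/cli/minidex.R scan -i idx -a assembly.fa -o contigs.tsv
```

## Index directory layout

`saveIndex()` writes a directory holding `header.txt` (key=value metadata:
magic, version, `k`, `w`, seed, alphabet, `n`, `r`, flags, null
threshold), `classes.txt` / `doclabels.txt`, little-endian int32 arrays
(`runStarts`, `runChars`, `runLengths`, `occBefore`, symbol table,
per-symbol run directory, `thrRows` thresholds, optional SA samples and
text), and `docarray.bin` with the `2r` boundary labels bit-packed. Writes
are deterministic: identical inputs produce byte-identical directories.

See the vignette (`vignettes/minimizer-rindex-classification.Rmd`) for the
full model description, parameter table, numerical conventions, and known
limitations.
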