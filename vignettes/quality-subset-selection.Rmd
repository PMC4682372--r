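---
title: "Quality-based subset selection: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-based subset selection: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqsubset)
```

## The selection problem

High-depth short-read datasets carry strong redundancy: a bacterial
genome sequenced at 2500x, or a large genome at 110x, contains many more
reads than an assembler needs to reach a given contiguity. At the same
time, each read's FASTQ record carries a per-base Phred score $Q$ that
encodes the base-calling error probability

$$p = 10^{-Q/10}, \qquad P_c = 1 - p .$$

`seqsubset` uses these scores to rank reads and keep a subset of a
chosen size. Three single-read statistics and one pair statistic are
implemented:

* **MQV** $= \min_i Q_i$. The rationale is that a read's weakest base is
  the most likely cause of a failed overlap or a broken k-mer; a read
  with 299 excellent bases and one Q2 call is, for overlap purposes,
  damaged goods.
* **ProductQ** $= \prod_{i=1}^{L} (1 - 10^{-Q_i/10})$, the probability
  that the read contains *no* wrong base; appropriate when the assembler
  consumes whole reads (overlap/string-graph assemblers). Reported to
  users as the correctness score, ProductQ × 100.
* **k-mer ProductQ** $= \min_{j=1..L-k+1} \prod_{i=j}^{j+k-1}
  (1 - 10^{-Q_i/10})$: de Bruijn-graph assemblers consume k-mers, so the
  read is judged by its weakest window.
* **PE-MQV** $= \min(\mathrm{MQV}_1, \mathrm{MQV}_2)$ for a pair: mates
  must be kept or dropped together to preserve pairing, and a pair is
  only as reliable as its worse mate.

Selection keeps items with score $\ge$ threshold (inclusive everywhere;
see *Tie-breaks and conventions*). The threshold is not guessed: it is
read off the cumulative score distribution at the target subset size, or
derived from a target coverage depth.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `offset` | all I/O and scoring | 33 | quality encoding; Phred+33 ("Sanger", all modern Illumina). 64 supported for legacy data. |
| `k` | `kmer_min_product_q`, `filter_productq` | none (whole-read) | k-mer window in bp; choose the assembler's k. The package forces an explicit choice rather than defaulting, because whole-read and windowed scores answer different questions. |
| `threshold` | `filter_minq`, `filter_pe` | — | integer MQV in [0, 93] |
| `threshold_product` | `filter_productq` | — | raw product in [0, 1]; a "correctness score 95" rule is `0.95` |
| `target_fraction` | `threshold_for_fraction` | — | desired kept fraction in (0, 1] |
| `target_depth`, `genome_size` | `fraction_for_depth` | — | x-fold depth target; converts to a fraction via `depth × G / total_bases` |
| `k` | `estimate_coverage` | 25 | spectrum k-mer size; small enough for in-memory hashing, standard for depth spectra |
| `canonical` | k-mer counting | `TRUE` | pool each k-mer with its reverse complement (reads come from both strands) |
| `chunk_size`, `workers` | `chunked_stats` | 10⁴, 1 | partitioning of the deterministic chunk-merge computation; never affects results |
| `q30_strict` | `summarize_reads` | `FALSE` | Q30 percentage counts `>= 30` (Illumina convention) or `> 30` |
| `strict` | `filter_pe` | `FALSE` | paired keep rule `>` instead of `>=` |

## Numerical choices

**Log-space window products.** ProductQ over hundreds of bases
underflows no time soon in double precision, but window minima over all
$L-k+1$ windows are found in O($L$) by accumulating $\log(1-p)$ in a
prefix sum and minimising the difference of two prefix values; `exp` is
applied once. This is order-independent and agrees with the brute-force
per-window product to well under the contractual 1e-9 relative error
(observed ~1e-15; the acceptance suite checks 1000 random reads with
random $L \le 400$ and $k$).

**Q = 0 bases.** $P_c = 0$ makes $\log$ infinite. Any window containing
such a base has product exactly 0, and every base lies in at least one
window, so the read score is returned as an exact 0 without non-finite
arithmetic.

**Reads shorter than k** are scored as their whole-read product (one
short window), with a warning. The alternative — refusing to score
them — would silently change subset counts; degrading gracefully keeps
every read scoreable.

**Correctness-score binning** uses `floor(product × 100)` so that bin
$b$ means "score in $[b, b+1)$", matching the semantics of a threshold
`0.yy`; an epsilon of 1e-9 is added before flooring so products such as
0.29, whose double representation lands infinitesimally below 29 after
scaling, bin where a human expects. A product of exactly 1 bins to 100.

**Exact chunk merging.** Every summary statistic is a ratio of
integer-valued accumulators (counts, summed integer scores, GC counts),
and histogram merging is bin-wise integer addition — a commutative
monoid with the empty histogram as identity. Chunked computation is
therefore *bit-identical* to the serial run for any chunk size and
worker count, which is the package's deterministic stand-in for a
map-reduce aggregation and is asserted, not assumed, in the tests.

## Threshold determination

`threshold_for_fraction` returns the **largest** integer threshold whose
kept fraction still meets the target; when the target falls between
occupied bins it over-keeps rather than under-keeps. The choice is
deliberate: fraction targets usually encode a minimum coverage depth,
and erring toward more data is the safe direction. The round-trip
property (kept fraction ≥ target, and no larger integer threshold
achieves it) is tested exactly.

With no reference genome, `estimate_coverage` supplies the genome size:
total k-mer count divided by the k-mer coverage depth, then depth =
total bases / genome size.

**Locating the k-mer depth.** The multiplicity spectrum of a real
dataset has a steep error tail at low multiplicity and a genomic peak
around the true depth. The peak is searched at or after the spectrum's
first local minimum (the valley past the error tail). On desk-scale
spectra (~10³ distinct k-mers) the raw argmax jitters by ±2–3
multiplicities from Poisson noise — enough to move a genome-size
estimate by 5–8%. The implementation therefore locates the peak on a
3-bin moving average and refines it to the rounded count-weighted
centroid within ±3√peak multiplicities (≈ three Poisson standard
deviations), i.e. a windowed Poisson mean. On clean unimodal spectra
this coincides with the argmax; on noisy ones it recovers a 1000 bp toy
genome within 5% for 99 of 100 seeds where the argmax fails for about
half. A spectrum with no interior peak (monotone decreasing) yields
depth 1 with an explicit low-confidence warning.

## What the synthetic generator emulates — and what it does not

`generate_reads` draws bases i.i.d. uniform over A/C/G/T and qualities
i.i.d. per base from a chosen model. The default `low_spike_mixture`
(`q_low = 0.02`, low range Q2–Q9, high range Q30–Q40) reproduces the
defining tension of high-depth Illumina data: ~98% of bases at or above
Q30, yet the majority of 300 bp reads contain at least one sub-Q10 base,
so the MQV distribution peaks low while base-level statistics look
excellent. Because qualities are i.i.d., the MQV law
$P(\mathrm{MQV} \ge t) = P(Q \ge t)^L$ holds analytically, which the
tests exploit as an independent oracle.

`generate_from_genome` samples reads from a random **circular** toy
genome (start positions uniform over all positions; reads wrap past the
end, as on a bacterial chromosome). Circularity matters: with linear
sampling, genome ends are under-covered and the interior k-mer depth is
$n(L-k+1)/(G-L+1)$ rather than $n(L-k+1)/G$, biasing the genome-size
estimate ~9% low at the test geometry. Pairs are forward /
reverse-complement mates spanning a Gaussian fragment length, with
start positions and fragment sizes returned as ground truth.

Deliberately **not** modelled: position-dependent quality decay along
the read, correlated error bursts, platform-specific substitution
profiles, GC-coverage bias, repeats (the toy genome is random sequence,
so k-mers are effectively unique), heterozygosity, and adapter
contamination. A green test therefore establishes the correctness of
the scoring, counting and selection machinery under the stated
stochastic model — not that any particular threshold is optimal for a
real library, which remains dataset-dependent and is explicitly an
iterate-and-assemble decision for the user.

## Tie-breaks and conventions

* **Keep rule**: inclusive `>=` for single-end *and* paired-end
  filtering. The single-end definition ("no smaller than the
  threshold") and the paired-end wording ("larger than") are
  inconsistent in common usage; the package standardises on the
  single-end rule so that a pair is kept iff both mates would be kept by
  the single-end filter at the same threshold — an exact identity the
  tests assert. `strict = TRUE` restores `>` for paired data.
* **Q30 percentage**: `>= 30` by default (the Illumina "Q30"
  convention), `> 30` behind `q30_strict`.
* **Peak ties** in the k-mer spectrum resolve to the multiplicity with
  the larger raw count, then the smaller multiplicity.
* **Random baseline**: per-item Bernoulli keep (single streaming pass)
  rather than exact-count sampling; the seed is recorded in the
  selection report and the RNG state is isolated from the caller's.
* **Mate identity**: a trailing `/1`–`/2` tag is stripped; otherwise the
  first whitespace token is compared (CASAVA 1.8 headers).

## Known limitations

* In-memory only: k-mer counting and read sets live in RAM; the
  distributed-computation scale of the original map-reduce setting is
  out of scope, and only its determinism contract is kept.
* The depth estimator assumes a unimodal genomic peak; heterozygous or
  highly repetitive genomes (mixture spectra) need dedicated
  spectrum-fitting tools.
* Quality scores are taken at face value; no recalibration, trimming or
  error correction is performed (those belong upstream).
* FASTA output wraps at 80 columns and FASTQ is strictly 4-line;
  multi-line FASTQ input is not supported.
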