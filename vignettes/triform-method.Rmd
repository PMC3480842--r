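---
title: "Model-free peak detection for transcription-factor ChIP-Seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free peak detection for transcription-factor ChIP-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triformr)
```

## The problem

ChIP-Seq for a transcription factor produces sequencing reads that pile up
near the factor's binding sites. Because only the ends of ~200 bp fragments
are sequenced, forward-strand reads accumulate upstream of a site and
reverse-strand reads downstream of it — the strand-shift property. A peak
caller must separate genuine, sharply localized binding events from two
kinds of noise: random fluctuations of background coverage, and *noisy
plateaus*, wide blocks of elevated coverage with no distinctive core and no
strand shift. Callers that simply test for elevated coverage accept
plateaus; triformr implements the Triform approach, which defines a peak
through the local *shape* of the coverage profile and therefore rejects
them.

## The coverage model and the Hoel statistics

At each position $x$ on one strand, the coverage $C_x$ (after reads are
extended to a fixed width $w$) is regarded as a Poisson variate with
unspecified mean $\lambda_x$. Nothing else is assumed: no background model,
no fitted parameters. With a fixed flank spacing $\delta > w$, the three
coverage values $C_{x-\delta}, C_x, C_{x+\delta}$ are treated as
independently measured Poisson counts, and three peak-shape alternatives are
tested with normalized linear contrasts (Hoel's nonparametric comparison of
Poisson counts):

$$
z_1 = \frac{2C_x - C_{x-\delta} - C_{x+\delta}}
           {\sqrt{2\,(C_{x-\delta}+C_x+C_{x+\delta})}},\qquad
z_2 = \frac{C_x - C_{x-\delta}}{\sqrt{C_{x-\delta}+C_x}},\qquad
z_3 = \frac{C_x - C_{x+\delta}}{\sqrt{C_{x+\delta}+C_x}}.
$$

Form 1 (center above both flanks — equivalently, a significantly negative
local second derivative of coverage), Form 2 (above the left flank only)
and Form 3 (above the right flank only). Each denominator is the square
root of an unbiased estimate of the contrast's variance under the matching
null (e.g. $\mathrm{Var}(2C-L-R) = 6\lambda = \mathbb{E}[2(L+C+R)]$ under
the Form-1 null), so each statistic is approximately standard normal even
at low counts. All-zero counts give $z = 0$ by convention — zero evidence,
never `NaN` — and a strictly positive cut-off then correctly fails.

Enrichment over the control sample (coverage $B_x$, Poisson mean $\mu_x$,
library-size ratio $r$ = control reads / ChIP reads) is tested the same
way, and a pseudo-count-stabilized enrichment ratio is recorded:

$$
z_4 = \frac{rC_x - B_x}{\sqrt{r\,(C_x+B_x)}},\qquad
\mathrm{ER}_x = \frac{1 + rC_x}{1 + B_x}.
$$

`nlp_from_z()` converts any of these to $-\log_{10} P(Z > z)$ through the
log-scale normal survival function, so extreme z-values (say $z = 40$)
yield large finite scores rather than overflowing.

```{r stats}
hoel_z1(0, 10, 0)
hoel_z4(10, 2, ratio = 1)
nlp_from_z(hoel_z1(0, 10, 0))
```

## The detection procedure

For each chromosome, strand and form, `detect_form_regions()` finds every
maximal run of positions with $z_f > \texttt{min\_z}$ **and**
$z_4 > \texttt{min\_z}$ whose width strictly exceeds `min_n`. Then:

1. **min.er filter.** The cut-off is data-derived: per strand, the
   `min_er_quantile` (default 3/8) quantile of the center enrichment ratios
   of all detected Form-1 regions. Regions of every form must strictly
   exceed their strand's cut-off. In real data the lower quantiles are
   populated by weak noise regions, so this removes the least enriched
   regions without touching strong sites.
2. **Replicate filter.** With $\ge 2$ ChIP replicates, every position of a
   region must have $z_f > 0$ and $z_4 > 0$ in every replicate (each with
   its own library ratio against the shared control). The pooled sample
   always drives the main statistics.
3. **Strand pairing.** A region is accepted only if it overlaps *exactly
   one* region of the same form on the opposite strand; ambiguous or
   unpaired regions are discarded.
4. **Lag test.** For each pair, the inter-strand lag is the lag maximizing
   the raw cross-correlation (sliding dot product) of the two strand
   profiles over the pair's span extended by $\delta$ on each side; lags up
   to the range width minus one, capped at $2\delta$, are searched, ties
   broken toward the smaller lag. The pair is kept only when the lag
   strictly exceeds `min_lag`. This is what rejects coincident-profile
   artifacts such as plateau edges.
5. **Scoring and form resolution.** A kept pair becomes a peak spanning the
   union of its two regions, located at the span midpoint, scored by
   `PEAK.NLP` — the sum of the two strand NLPs, each taken at the region's
   summit (the position of maximal form z, leftmost on ties). The sum is a
   Fisher combination: $2\ln(10)\sum \mathrm{NLP}$ is the $\chi^2$
   statistic of the combined null. Form 2/3 peaks overlapping a Form 1 peak
   are redundant and removed; surviving overlapping Form 2 + Form 3 peaks
   merge into one Form 1 peak (union span, summed NLP, larger lag). Any
   residual overlap is resolved by keeping the higher-NLP peak, so the
   final list is non-overlapping per chromosome.

Detection is entirely deterministic: identical inputs and parameters give
byte-identical peak tables.

## Parameters

| parameter         | default | units | meaning |
|-------------------|---------|-------|---------|
| `read_width` (w)  | 100     | bp    | fixed width to which each read is extended from its 5' end |
| `delta`           | 150     | bp    | flank spacing; > w, comparable to the DNA around one nucleosome |
| `min_z`           | 1.2816  | z     | cut-off for all tests; default is the upper-tail z for p = 0.1 |
| `min_n`           | 10      | bp    | minimum region width (strict) |
| `min_er_quantile` | 3/8     | —     | quantile of Form-1 enrichment ratios defining min.er |
| `min_lag`         | 10      | bp    | minimum inter-strand lag (strict) |
| `ratio` (r)       | data    | —     | control/ChIP library-size ratio, computed from read counts |

The parameters are deliberately fixed rather than fitted, which is the
method's defense against overfitting. The min.er choice is not critical:
nearby quantiles give almost identical cut-offs because the low quantiles
sit in a mass of near-tied weak-region ratios.

## Numerical and design choices

* **Coordinates.** Input BED is 0-based half-open; everything internal is
  1-based inclusive, converted exactly once at parse time.
* **Extension anchor.** Reads are extended to `read_width` from their 5'
  end, in the read's direction. This mimics the sequenced fragment reaching
  w bp inward from each end and draws the two strand profiles of a site
  toward each other — their separation becomes roughly (fragment length −
  w) and their peak regions overlap, which the strand-pairing criterion
  requires. Midpoint-anchored extension was evaluated and rejected: it
  leaves the strand profiles (fragment length − read length) apart, the
  per-strand regions then rarely overlap for ~200 bp fragments, and
  pairing — and with it most true sites — is lost. A consequence worth
  remembering is that reported lags estimate (fragment length − w), not
  (fragment length − read length).
* **min.er quantile.** Type-7 (linear interpolation between order
  statistics), the most common empirical-quantile convention; recorded in
  the run metadata. A strand with no Form-1 regions gets min.er = 0.
* **Strict inequalities** everywhere a threshold is "exceeded": `z >
  min_z`, width `> min_n`, `ER > min.er`, `lag > min_lag`. Combined with
  the heavy ties among weak-region enrichment ratios, strictness does real
  work: the quantile value itself is always excluded.
* **Cross-correlation** is an unnormalized dot product; the argmax is
  invariant to positive scaling and mean-centering can create spurious
  optima on short sparse ranges. Ties break toward the smallest lag, so
  identical profiles give lag 0 and are rejected.
* **Degenerate inputs.** Empty files are empty results, not errors. A pair
  whose strand profile is all zero over the lag range has no defined lag
  and is dropped. Merged Form 1 peaks are not re-tested against the
  per-strand conditions (their constituents already passed).
* **Same-form pairing.** Opposite-strand overlap counting is restricted to
  regions of the same form. Counting across forms would triple-count the
  same physical bump (each bump is typically detected in several forms) and
  make "exactly one overlap" unsatisfiable everywhere.
* **Pooling.** Replicates are pooled for the main statistics; the
  replicate sign filter is the only place individual replicates are
  consulted.

## The synthetic data generator

`simulate_chipseq()` emulates exactly the structure the detector assumes:
point binding sites whose forward/reverse read centers are Gaussian-jittered
around positions $p \mp (\text{fragment\_length} - \text{read\_length})/2$,
Poisson per-site read counts, uniform Poisson background on both strands,
and a matched site-free control. Defaults — a 2 Mb chromosome, 50 sites, 200
bp fragments, 36 bp reads, 40 reads per site and strand, 20 bp jitter,
0.005 background and control reads/bp/strand — describe a realistically
deep transcription-factor experiment at small genome scale, and are the
conditions under which the package's end-to-end tests run. Sites are placed
at least two fragment lengths apart so each is a distinct, resolvable event;
overlapping binding events are a real phenomenon the generator deliberately
does not model. Also not modeled: sequence content, mappability gaps,
duplicate-read artifacts, copy-number variation and the broad non-uniform
background of real chromatin. Passing the end-to-end tests therefore
demonstrates the machinery is correct under the model's own assumptions,
not that real-data performance equals the simulated numbers.

```{r sim}
sim <- simulate_chipseq(genome_length = 3e5, n_sites = 8, seed = 7)
calls <- call_peaks(sim$chip, sim$control)
glance(calls)
glance(evaluate_calls(calls, sim$truth, tol = 100))
```

`evaluate_calls()` matches peaks to planted sites greedily, best score
first, one-to-one within a tolerance, reporting recall, the
false-discovery proportion and positional errors.

## Known limitations

* At background rates around 0.005 reads/bp/strand, chance pileups (a >10
  bp run of coverage 2–4 over a control gap) occasionally satisfy every
  condition including the lag test; expect on the order of one such call
  per megabase in background-only data. They carry low `PEAK.NLP` and sit
  at the bottom of the ranked list, and they are diluted to a small
  false-discovery proportion whenever true sites are present, but a
  *guaranteed* near-zero absolute false-positive count in signal-free data
  is not a property of the procedure.
* The min.er rule is self-referential: with very few Form-1 regions (e.g. a
  nearly noise-free experiment with a handful of sites) the quantile lands
  on a true site's own enrichment ratio and the strict comparison removes
  it. The rule presumes a realistic mixture of weak and strong regions.
* Peaks closer together than roughly a region width cannot both survive
  the "exactly one overlap" pairing rule.
* Problem sizes in the test suite (2 Mb genomes, tens of sites, 100,000
  Monte-Carlo draws for calibration) were chosen as the smallest scales at
  which the stochastic properties are stable; the implementation itself is
  run-length based and handles real chromosome lengths.
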