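---
title: "Alignment-free dN/dS from FracMinHash containment: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free dN/dS from FracMinHash containment: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmhdnds)
```

## The problem

The ratio of non-synonymous to synonymous substitution rates, dN/dS (ω),
is the workhorse statistic for inferring selection on protein-coding
sequence: ω > 1 indicates adaptive (positive) selection, ω < 1 purifying
(negative) selection. Conventional estimators — counting methods such as
Nei–Gojobori (NG86) or maximum-likelihood codon models — require codon
alignments, which becomes the bottleneck when the comparison set is tens of
thousands of genomes. This package implements a closed-form dN/dS estimator
that needs no alignment at all: it works from FracMinHash containment
indices of DNA and protein k-mer sketches, so a pairwise estimate costs two
set intersections.

## Sketches and containment

A FracMinHash sketch of a k-mer set $A$ keeps every k-mer whose 64-bit hash
falls below $2^{64}/\mathrm{scaled}$ — a uniform subsample retaining an
expected fraction $1/\mathrm{scaled}$ of $A$. We hash with MurmurHash3
x64_128 (low 64 bits, seed 42, the convention of the sourmash family of
tools), canonicalizing DNA k-mers (minimum of k-mer and reverse complement)
so sketches are strand-robust; protein k-mers are hashed as-is, and k-mers
containing characters outside the alphabet (`N`, `X`, the stop symbol `*`)
are skipped.

The debiased fractional containment of $A$ in $B$ estimated from sketches is

$$\hat C(A,B) = \frac{|\mathrm{sk}(A)\cap \mathrm{sk}(B)|}
{|\mathrm{sk}(A)|\,\bigl(1-(1-s)^{|A|}\bigr)},\qquad s = 1/\mathrm{scaled},$$

where the denominator's second factor corrects for the event that a
non-empty set leaves an empty sketch. The true cardinality $|A|$ is not
available from a sketch, so we plug in $|\mathrm{sk}(A)|\cdot\mathrm{scaled}$;
the factor is computed in log space and is numerically 1 whenever
$|A| s \gg 1$, which holds for any genome-scale input, so the choice of
plug-in estimator is inert in practice. At `scaled = 1` the sketch is the
full k-mer set and containment is exact.

## From containment to dN/dS

Model mutation as independent per-position Bernoulli events at rate $p$.
A DNA k-mer survives with probability $(1-p)^{k_{nt}}$, so the containment
of the original sequence's k-mer set in the mutated one satisfies
$C_{nt} \approx (1-p)^{k_{nt}}$, giving the nucleotide mutation rate
$p = 1 - C_{nt}^{1/k_{nt}}$ (this is the familiar containment→ANI
relationship; the protein-level analogue with $k_{aa}$-mers gives the
amino-acid rate $p_{AA} = 1 - C_{aa}^{1/k_{aa}}$, i.e. 1 − AAI). We always
derive $k_{nt} = 3k_{aa}$ so the DNA window covers exactly the codons of
the protein window.

Per codon, condition on "at least one nucleotide mutated", which has
probability $1-(1-p)^3$. The non-synonymous part of that event has
probability $p_N = p_{AA}$ (the amino acid changed); the synonymous
remainder is $p_S = \bigl(1-(1-p)^3\bigr) - p_{AA}
= C_{aa}^{1/k_{aa}} - C_{nt}^{3/k_{nt}}$. Note the conservation property
$p_N + p_S = 1-(1-p)^3$: the two branches partition the codon mutation
event.

Counting methods weight mutation counts by site counts. Averaged over
codons, NG86-style counting assigns 0.77 synonymous and 2.23 non-synonymous
sites per codon, so the site ratio $S/N = 0.77/2.23 = 0.345$ is a constant
here (never recomputed per sequence). The estimator is

$$\widehat{dN/dS} \;=\; \frac{1 - C_{aa}^{1/k_{aa}}}
{C_{aa}^{1/k_{aa}} - C_{nt}^{3/k_{nt}}} \times 0.345 .$$

`fmh_dnds()` evaluates this and reports all intermediate quantities; the
identity between this form and the conditional-probability route is tested
to machine precision.

### Direction of the containment

Containment is asymmetric. The derivation above mutates a sequence $W$
into $W'$ and uses the containment of $W$'s k-mers in $W'$'s set, so
`fmh_dnds_pair(ref, query)` puts the *reference* on the denominator side.
The reverse direction is biased in the presence of in-frame stop codons in
the derived sequence: stops shrink the derived protein k-mer set (stop
k-mers are not hashable), which inflates the reverse containment and hence
the apparent synonymous signal. All-vs-all comparisons (`multisearch()`,
`pairwise_dnds()`) report both ordered directions, labelled by `query` and
`target`.

### Degenerate regions of the estimator

The estimator has well-defined failure modes, reported as status codes
rather than errors:

* `undefined_identical` — both containments are 1 (0/0);
* `undefined_zero_containment` — the protein containment is 0, so the AAI
  root is 0 and $p_S \le 0$; this is the regime of mutation rates around
  0.1 and above, where containment of long k-mers collapses;
* `undefined_nonpositive_pS` — the observed protein divergence exceeds
  what the nucleotide divergence permits under the model
  ($C_{aa}^{1/k_{aa}} \le C_{nt}^{3/k_{nt}}$); sampling noise near
  $p_S \approx 0$ lands here.

Conversely at rates around 0.001 both containments approach 1 and the
estimate, while defined, rests on a handful of k-mer differences.

## Ground truth: NG86 with Jukes–Cantor correction

For benchmarking, `ng86_dnds()` implements the Nei–Gojobori counting
method on positionally comparable sequences (equal length, same frame — the
module never aligns): fractional synonymous site counts per codon
enumerated from the standard code (changes to stop codons excluded, with
the per-position fractions renormalized), pathway-averaged synonymous /
non-synonymous difference counts for multi-hit codons (orderings passing
through a stop are discarded; in the rare case every ordering is blocked,
all are used with stop-crossing steps counted as non-synonymous), and the
Jukes–Cantor correction $d = -\tfrac34\ln(1-\tfrac43 p)$ applied to the raw
proportions. Codon pairs containing `N` or a stop in either sequence are
skipped pairwise and counted. The suite checks this implementation against
an independently written enumerator on hundreds of random codon pairs and
whole sequences.

A note on the site constants: exact enumeration over the 61 sense codons
puts most synonymous sites at third codon positions and almost none at
second positions. This package never uses per-position constants — sites
are always counted from the code table — and the estimator's $S/N$ uses
only the position-order-invariant total 0.77/2.23.

## The selection simulator

`simulate_cohort()` generates the benchmark inputs. A reference is drawn
uniformly over the 61 sense codons (stop-free by construction), then each
query mutates the reference with independent Bernoulli($p$) draws at
targeted positions, replacing the base uniformly with one of the other
three:

* `negative` targets the third position of each codon — mostly synonymous
  changes, a purifying-selection proxy;
* `positive` targets the first and second positions (one draw each) —
  mostly non-synonymous changes, an adaptive-selection proxy;
* `uniform` targets every position.

Mutated queries may acquire in-frame stop codons; that is deliberate, since
both downstream consumers have defined behaviour for stops (protein
sketching skips `*` k-mers; NG86 skips the codon pair). Determinism: the
reference uses `seed`, query $i$ uses `seed + i`, so any single query can
be regenerated in isolation; simulator calls save and restore the caller's
RNG state.

The default study conditions follow the simulation design the estimator
was characterized under: reference lengths 5,001 / 10,002 / 20,001 nt,
mutation rates 0.1 / 0.01 / 0.001 (of which 0.01 is the informative regime
— 0.1 collapses containment toward 0, 0.001 leaves too little signal),
100 queries per scheme, $k_{aa} \in \{5,7,15,21\}$, scale factor 1 for
desk-scale benchmarking and 500 for genome collections.

What the simulator does *not* emulate: codon-usage bias, indels,
recombination, transition/transversion asymmetry, and heterogeneous rates
along the sequence. Tests passing on these cohorts therefore validate the
estimator's arithmetic and its selection-direction behaviour under the
idealized mutation model, not its calibration on real genomes, where the
characterization showed systematic overestimation relative to
alignment-based methods.

## Benchmark behaviour and a known limitation

`selection_benchmark()` reproduces the NG86-vs-FracMinHash comparison:
per (length, $k_{aa}$) it simulates both cohorts from one shared
reference, computes both estimators per query, and reports the pooled
Pearson correlation over defined pairs (pairs where either estimator is
undefined — NG86 with zero synonymous differences, or the estimator's
status codes — are dropped; fewer than ten usable pairs set a `low_n`
flag).

Two robust findings at 20,001 nt, $p = 0.01$, $k_{aa} = 7$, scale 1: every
positive-scheme query estimates above 1 and every negative-scheme query
below 1 across all seeds we examined, with positive-cohort medians well
above 1. The pooled *Pearson correlation*, by contrast, is fragile: both
estimators put a rare-event count in a denominator (synonymous signal in
the positive scheme is a few events per 6,667 codons), so a single query
whose synonymous signal collapses to one k-mer quantum produces an extreme
ratio and can move the pooled R from ~0.93 to ~0.5 between seeds.
Rank correlations and log-scale correlations are ~0.94–0.99 and stable.
Users comparing the two estimators should treat the raw-scale pooled R at
these conditions as a draw-dependent summary; at shorter lengths (5,001 nt)
it degrades further because the synonymous event counts shrink
proportionally.

## Filtering and aggregation

For genome-collection work the estimator exposes the two screening
thresholds used downstream of containment: keep pairs with
$p_S \ge$ `min_pS` (default 0.05; enough synonymous signal for a stable
denominator) and $p_N \le$ `max_pN` (default 0.23; beyond that the
containment→identity relation is out of its regime). The direction of each
inequality is a package choice — discard weak-synonymous-signal and
implausibly-diverged pairs — and both thresholds are exposed as options.
`aggregate_median()` reduces pair estimates to group (e.g. genus) medians
over status-ok pairs, requiring both pair members to share the group label;
even-sized groups use the mean of the two central values, and cross-group
pairs are returned separately rather than silently dropped.

## Numerical and interface choices

* Hashes cross the C++/R boundary as fixed-width 16-character lowercase
  hex strings: R has no unsigned 64-bit integer, hex preserves exactness,
  and lexicographic order equals numeric order. Sketch JSON stores hashes
  the same way (sorted), keeping serialization deterministic and exact —
  64-bit values are not exactly representable as JSON numbers.
* The retention threshold $2^{64}/\mathrm{scaled}$ is computed and compared
  on native `uint64` in C++, never in double precision in R.
* The debias factor $1-(1-s)^{\hat A}$ is evaluated as
  `-expm1(A_hat * log1p(-s))` to avoid underflow/overflow at genome scale.
* Containment estimates slightly above 1 (debiasing can overshoot) are
  clamped to 1 with a warning before rate conversion.
* Sequence lengths used by the test suite and the bundled benchmark script
  are the characterization's own: 20,001-nt references with 100 queries
  per scheme for the headline comparison, 30-codon pairs for exhaustive
  oracle checks, and 50-kb pairs over 200 replicates for the sketch
  debiasing property.
* Undefined values serialize as `NA` alongside a populated `status`
  column; numeric CSV output from the command-line tool is written at 6
  significant digits.

## Scope and limitations

The package estimates pairwise dN/dS from sketches; it does not align, call
ORFs, or model transitions/transversions, recombination, or codon
frequencies — inputs are assumed to be in-frame coding sequences. Estimates
are most informative in the divergence window where containments are
bounded away from both 0 and 1 for the chosen k; outside it, expect status
codes rather than numbers. On real genome collections the estimator's
characterization reports systematic overestimation of dN/dS magnitude while
preserving the inference of selection direction, so group-level medians and
relative comparisons are the intended use, not absolute rate estimates.
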