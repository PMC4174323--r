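---
title: "Detecting artificial selection with windowed Tajima's D: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting artificial selection with windowed Tajima's D: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The statistical model

`sweepscan` detects genomic windows shaped by artificial selection in a
cohort partitioned into one wild group and several cultivated subgroups.
The core signal is the site-frequency-spectrum distortion a selective
sweep leaves behind: locally reduced diversity and an excess of
low-frequency variants, which drives Tajima's D negative (balancing or
diversifying regimes push it positive).

For a window of effective length $L$ with $S$ segregating sites among
$n$ sampled haplotypes, the package computes nucleotide diversity
$\pi = \sum_{\text{sites}} 2\hat p(1-\hat p)\,\tfrac{n}{n-1} / L$,
Watterson's $\theta_w = S/(a_1 L)$ with $a_1 = \sum_{i=1}^{n-1} 1/i$,
and

$$D = \frac{\pi_{\text{total}} - S/a_1}{\sqrt{e_1 S + e_2 S(S-1)}},$$

with the full 1989 constant set $(a_1, a_2, b_1, b_2, c_1, c_2, e_1,
e_2)$ — see `tajima_constants()`. The frequency-based $\pi$ estimator is
exactly the mean difference over all haplotype pairs (including the two
haplotypes within one diploid), which is what the test suite's
pair-enumeration oracles exploit.

### The neutral range and its beta approximation

$D$ is bounded. Every site a singleton gives the minimum; every site at
the most even attainable frequency gives the maximum. The per-site
diversity maximum depends on the parity of $n$: $n/(2(n-1))$ for even
$n$, but $(n+1)/(2n)$ for odd $n$, because the derived count must sit at
$\lfloor n/2 \rfloor$. `d_bounds()` implements the parity-aware form;
with the even-only form the odd-$n$ confidence limits are visibly wrong
(the $n=7$ upper limit moves by 0.05, far beyond the package's 0.02
reproduction tolerance).

Under neutrality $D$ is approximated by a beta density rescaled to
$[D_{\min}, D_{\max}]$ with mean 0 and variance 1. Writing
$u = (D - D_{\min})/(D_{\max} - D_{\min})$, $u \sim \mathrm{Beta}(\beta,
\alpha)$ with

$$\alpha = -\frac{(1 + D_{\min} D_{\max})\,D_{\max}}{D_{\max}-D_{\min}},
\qquad
\beta = \frac{(1 + D_{\min} D_{\max})\,D_{\min}}{D_{\max}-D_{\min}}.$$

`d_confidence_limits()` takes equal-tail quantiles of this density
numerically (via `qbeta`), for any $n \ge 4$ and any level — no lookup
table. The limits for $n = 6..9$:

```{r}
neutral_range_table(6:9)
```

### Whose $n$? Accessions versus haplotypes

$\pi$ and $\theta_w$ use $n_\text{hap} = 2\times$ accessions, as diploid
dosages demand. For the *confidence limits* of the scan the package
defaults to the accession count (`ci_sample_size = "accessions"`),
because the published per-subgroup ranges are exactly the beta limits at
the printed accession counts (6–9), not at their doubled haplotype
counts. This is also defensible on substance: these orchard species
self, so the effective number of independent haplotypes per subgroup is
much closer to the accession count than to twice it. The haplotype
convention remains available as a configuration switch.

### Intensity and the candidate rule

A window's intensity is its percent distance from the midpoint $m$ of
the neutral range, normalized **asymmetrically** so that each limit is
exactly 100%: $100\,(D-m)/(\text{upper}-m)$ above the midpoint,
$100\,(m-D)/(m-\text{lower})$ below. The asymmetry is forced by the
requirement that "intensity > 100%" coincide with "outside the
range" — a symmetric scale cannot put both limits at 100% because the
beta density is skewed. Candidates are windows with intensity strictly
above 100; windows with undefined $D$ are never judged.

### Subgroup set logic

On a shared window grid (windows are compared by identity, not interval
intersection), the default rules are:

* edible-selected: candidate in **all** of C, D, E, F and **not** in A;
* ornamental-selected: candidate in A and in **none** of C, D, E, F;
* subgroup B (an admixed intermediate in the emulated design) is
  excluded via `ignore_subgroups`.

The two labels are provably disjoint; the implementation asserts this on
every run. Only after labeling are windows merged into maximal
contiguous regions and annotated with genes (≥ 1 bp span overlap,
deduplicated).

### Corroboration: ROD and Hudson-type $F_{ST}$

Per window, $\mathrm{ROD} = 1 - \pi_{\text{cul}}/\pi_{\text{wild}}$
(undefined where $\pi_{\text{wild}} = 0$) and
$F_{ST} = (\pi_B - \pi_W)/\pi_B$, where $\pi_B$ is the mean pairwise
difference between haplotypes from different groups and $\pi_W$ the
average of the two within-group diversities. Both are computed from
dosage-derived allele frequencies, which equals explicit haplotype-pair
enumeration (the within-group estimator carries the $n/(n-1)$
correction; for two identical groups this gives exactly
$F_{ST} = -1/(n_\text{hap}-1)$, a useful sanity fixture).

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `window_size`, `step` | 10000, = window | bp | disjoint 10 kb tiling; the scan counts windows as discrete units |
| `s_min` | 3 | sites | below this the variance term of $D$ is degenerate; window reported as undefined |
| `min_called_fraction` | 0.5 | fraction | genotype-level proxy for the original read-depth/mapping filters |
| `maf_min` (filter) | 0 | frequency | scans keep rare variants — they carry the sweep signal |
| `level` | 0.95 | — | two-sided equal-tail split of the neutral range |
| `ci_sample_size` | accessions | — | see above |
| LD: `maf_min`, `max_dist`, `bin_width` | 0.1, 1000 kb, 1 kb | — | the conventional pairwise-LD settings for this kind of cohort |

Coordinates are 1-based inclusive at the VCF/GFF3 boundary and 0-based
half-open internally and in all BED output.

## The synthetic-data generator

`simulate_cohort()` emits a complete toy study: reference FASTA, GFF3
gene models, sorted biallelic VCF, group table, truth BED. Its defaults
*are* the emulated study conditions:

* subgroups W (wild, 10), A (ornamental, 8), B (6), C (8), D (7), E (9),
  F (9) — the scan's published subgroup sizes plus a ten-accession wild
  group;
* `theta_per_site` 2.6×10⁻³ for wild (the genome-wide diversity scale of
  the emulated cohort) and 1.3–1.8×10⁻³ for cultivated subgroups
  (wild > cultivated);
* `inbreeding_f` 0.45 (wild) and 0.75 (cultivated), chosen so that
  per-accession heterozygous-call ratios land in the observed selfing
  regime — a few percent, with wild roughly 3× cultivated;
* two injected sweeps (edible-only and ornamental-only), mode
  `low_freq_excess`, diversity reduced to 30% of neutral.

Sites are simulated independently given the window's parameters: the
per-window count is Poisson with mean
$\text{reduction} \times \theta\, a_1(n_\text{hap})\, L$, and each
site's derived count is drawn from the mode's spectrum — $P(i) \propto
1/i$ (neutral; this makes $E[\pi - S/a_1] = 0$ exactly, so windowed $D$
centers at zero by construction), $P(i) \propto i^{-4}$
(`low_freq_excess`), or Gaussian weights centered at $n/2$ with sd $n/8$
(`intermediate_excess`).

**Why $i^{-4}$ for sweeps.** The scan's subgroups are small ($n =
6..9$). In the large-$S$ limit $D \to \Delta/\sqrt{e_2}$ where $\Delta$
is the per-site diversity deficit of the spectrum. Working that out for
$n_\text{hap} = 16$: an $i^{-2}$ or even $i^{-3}$ skew asymptotes near
$-1.5$, *above* the published lower limits — a scan with those spectra
is structurally powerless at any effect size. The near-complete
singleton excess $i^{-4}$ (≈ 92% singletons), the regime a hard sweep
leaves, asymptotes near $-2.4$ and is detectable. This choice was fixed
by that calculation, not by tuning against test outcomes.

**Inbreeding as a lineage mixture.** With probability $F$ an accession
contributes a single identical-by-descent lineage (both haplotypes
copies); otherwise two independent lineages. The site's derived count is
drawn over lineages. Consequences: heterozygous calls scale with
$(1-F)$; $F = 1$ forces complete homozygosity; and — importantly — a
"singleton" in a selfed accession surfaces at dosage frequency
$2/2n$, not $1/2n$.

**Selfing compresses $D$.** That doubling raises the per-site $\pi$ of
the singleton class from 0.125 to 0.233 (at $n_\text{hap} = 16$), so
under strong selfing the most negative attainable windowed $D$ rises to
about $-1.0$ — inside every neutral range used here. This is a real
limitation of small-sample $D$ scans on highly selfed material, not an
artifact: at the default `inbreeding_f = 0.75` the injected sweeps are
*not* recovered by the $D$ rule (they remain visible through ROD), while
on outbred cohorts the same effect size is recovered almost always. The
scan-calibration and sweep-recovery validations therefore run on
outbred ($F=0$) cohorts, where the neutral-range theory's sampling
assumptions hold; the selfed defaults exercise the heterozygosity and
summary machinery.

What the generator does **not** emulate: intra-window linkage from a
genealogy (sites are exchangeable given the window; the optional
`ld_block_bp` mode creates block-structured $r^2$ for LD tests, nothing
subtler), recombination gradients, shared polymorphism between
subgroups (sites are subgroup-private, so cross-subgroup $F_{ST}$ nulls
are tested by splitting one subgroup), demographic history, and
sequencing error. Passing tests therefore validate the estimators and
the scan logic under controlled spectra — they do not certify behavior
on real resequencing data with LD, shared ancestry and call errors.

## Numerical and degenerate-input choices

* $D$ undefined (`NA`) when $S < 3$ (configurable) or the variance term
  is non-positive; undefined windows are never candidates.
* Per-site statistics use pairwise-complete data; variant sites with
  fewer than two called subgroup samples are skipped and the effective
  window length reduced accordingly.
* Site classification priority when transcripts overlap: each gene
  contributes its longest transcript (ties: smallest transcript ID),
  then CDS > 5′ UTR > 3′ UTR > intronic. The emulated study does not
  state a rule; this one is documented rather than inherited.
* Coding effects substitute the strand-corrected allele into the codon
  and compare amino acids under the standard genetic code; a
  reference-allele mismatch against the FASTA is an error, not a guess.
* LD half-decay interpolates linearly between bin midpoints at the
  first crossing of half the curve's maximum; a curve that never falls
  below half its maximum has an undefined half-decay distance.
* PCA centers sites without variance standardization (plain covariance
  of the 0/1/2 matrix), imputes missing dosages to the site mean, and
  fixes each eigenvector's sign by making its largest-magnitude loading
  positive.
* The beta limits use equal-tail quantiles; the published ranges are
  two-sided and reproduce to ±0.001 under the accession convention.

## Problem sizes used by the validation suite

The test and acceptance runs use sizes chosen to make the checks sharp
but quick: 500-window replicates for neutral calibration and diversity
contrasts (standard errors small enough for 3-SE bands), 50 seeded
cohorts for sweep recovery through the full set logic, 20 seeds for LD
block-scale recovery, 10⁵ draws for spectrum marginals, and two-contig
(2 × 200 kb or smaller) toy genomes for end-to-end runs.

## Known limitations

* The $D$ scan loses power under strong selfing (quantified above);
  ROD/F_ST corroboration does not.
* Windows are labeled on a fixed grid; sweeps straddling window
  boundaries dilute across two windows.
* The accuracy mixture and sensitivity arithmetic are faithful
  re-implementations of simple validation algebra; they inherit the
  limitations of the validation designs they summarize.
* Indel and structural-variant annotation are out of scope; the effect
  machinery is SNP-only.
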