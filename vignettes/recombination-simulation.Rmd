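---
title: "Simulating recombination patterns in DH, RIL and MAGIC populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating recombination patterns in DH, RIL and MAGIC populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombsim)
```

## The model

`recombsim` is a forward simulator of meiosis for maize-like genomes, built
around two empirically measurable parameters:

1. **A per-chromosome crossover-count distribution.** In each meiosis, each
   chromosome independently receives $k \in \{0, 1, 2, 3\}$ crossovers with
   probabilities taken from genotyped maize F1-DH material. The measured raw
   rates are $0.16, 0.30, 0.23, 0.15$; they sum to $0.84$, and the package
   renormalizes them over the support $\{0..3\}$, giving
   $\bar{k} = 1.4405$ crossovers per chromosome and
   $10\,\bar{k} \approx 14.4$ per gamete on a 10-chromosome genome. We chose
   renormalization over assigning the residual mass to $k \ge 4$ because only
   the renormalized reading reproduces the observed mean of $\approx 14$
   recombination events per F1-DH line; any allocation of the residual to
   higher counts forces a genome-wide mean of 18 or more.

2. **A window-level recombination landscape.** Each chromosome is tiled into
   windows (125 kb by default) carrying a nonnegative rate $c_w$ (cM-like
   weight). Crossover *placement* uses the normalized probabilities
   $p_w = c_w / \sum_{w' \in \text{chrom}} c_{w'}$, so only the relative
   shape of the landscape matters — the absolute cM scale cancels. This is
   deliberate: the published per-window means (3.48 cM per 125 kb) would sum
   to an implausible total map length if read as absolute genetic distances,
   so the package treats rates strictly as placement weights.

A crossover position is drawn by picking a window with probability $p_w$ and
then a uniform offset inside it. Crossover interference is modelled as a hard
minimum distance: all crossovers of one chromosome in one meiosis must lie at
least 10 Mb apart (configurable). The whole position set is rejected and
redrawn until the constraint holds; the count $k$ is never changed by
rejection, so interference reshapes positions without deflating the count
distribution. If no valid configuration is found in `max_resample` attempts
(possible only on short chromosomes with large $k$), the best-spread sample
is kept and a fallback is logged (`fallback_count()`).

Transmission is a random walk over the two parental haplotypes: the
transmitted chromatid starts from a fair-coin choice and switches parental
haplotype at every crossover position. Chromosomes are founder-labelled
segment mosaics; junctions where both parental haplotypes carry the same
founder label are invisible and merged away, so segment boundaries are
exactly the observable recombination breakpoints. The sampled count is the
budget of the single transmitted chromatid, matching how counts are measured
in DH lines (breakpoints per chromosome per line); no four-strand chiasma
bookkeeping, obligate chiasma, or gene conversion is modelled, and the count
distribution is shared by all chromosomes (an optional length-scaling was
considered and rejected because the source distribution is genome-aggregated).

## Breeding schemes

All schemes operate per line with an independent derived seed stream, so
populations are bit-reproducible from `(spec, seed)` and insensitive to
evaluation order.

* **Fk-DH series** (`scheme_spec("dh_series", dh_generation = t)`): biparental
  cross, $t - 1$ generations of single-seed-descent selfing, then
  doubled-haploid induction — one gamete duplicated into a fully homozygous
  line. `dh_generation` counts the generation of the *plant* induced
  ($t = 1$ induces the F1).
* **RIL** (`scheme_spec("ril")`): biparental cross and six selfing
  generations by single seed descent. Residual heterozygosity is
  $2^{-6} \approx 1.6\%$ of the genome in expectation; for breakpoint
  counting, each line is read as its first haplotype (a deterministic
  consensus). Averaging the two haplotypes instead changes means negligibly.
* **MAGIC** (`scheme_spec("magic", n_parents, magic_method)`): each line
  shuffles the 8/16/32 founders into its own funnel — pairwise intercrosses
  over $\log_2 n$ generations (F3/F4/F5 funnel products for 8/16/32
  parents) — then either DH induction (`"dh"`) or five further selfing
  generations (`"cs"`). Post-DH selfing adds no recombination and is treated
  as a generation counter only; the five CS selfings mirror the F8/F9/F10
  completion schedules of the corresponding DH programs.

A useful closed form for validation: writing $\lambda = 10\bar{k}$ for the
expected junctions per gamete from an F1, heterozygosity halves each selfing
generation, so the expected breakpoints of a DH induced at $F_t$ are
$\lambda\,(2 - 2^{1-t})$ — 14.4 at F1, 25.2 at F3, plateauing near
$2\lambda \approx 28.8$. The test suite checks simulated means against this
recursion within Monte-Carlo error, and the same argument gives
$\lambda(\ell + 1 - 2^{\ell - g})$-type predictions for MAGIC funnels of
depth $\ell$, which the simulated means (about 43/58/72 for 8/16/32-parent
DH-MAGIC and 57/72/85 for CS-MAGIC) track closely.

## The synthetic landscape generator

The generator (`generate_synthetic_map()`) emulates the statistical shape of
the intermated B73 x Mo17 (IBM) landscape rather than its (unpublished)
window values; it defines the package's reference study conditions:

* rates drawn from a gamma with shape 0.8 (strong right skew: most
  recombination concentrated in a minority of hotspot windows);
* 20% of windows set to rate 0 (cold windows);
* centromeric suppression: the middle 20% of each chromosome multiplied by
  0.1 (centromere position defaults to mid-chromosome; real maize
  centromeres are not all metacentric, but their positions do not enter any
  reported statistic beyond producing larger centromeric fragments);
* clipping to 12.1 cM and linear rescaling so the mean window rate is
  *exactly* 3.48 cM at 125 kb — clip and rescale are iterated to convergence
  (relative error $< 10^{-9}$, typically 2–3 passes) because rescaling can
  push values back over the cap.

The defaults (mean 3.48, max 12.1, 125 kb) are the measured IBM values; the
skew, zero fraction and suppression parameters are free choices fixed once at
values typical of maize recombination landscapes. What the generator does
*not* emulate: spatial autocorrelation of hotspots along chromosomes,
chromosome-specific landscape shapes, and the length-dependence of crossover
numbers. Passing tests therefore demonstrate the engine's fidelity to its
two input parameters, not to any particular real population's genotypes.

The bundled genome is a 10-chromosome table totalling 2,060.2 Mb,
approximating the maize B73 reference; every statistic that depends on
genome size does so only through ratios, so the approximation is benign, and
both genome and map are overridable from TSV/BED-like files.

## Statistics and maps

* **Events per line**: the sum over chromosomes of observable breakpoints of
  the line's mosaic.
* **Per-line fragment length**: total genome length divided by the line's
  event count (Mb); undefined (NA) at zero events. This quantity lives on
  the hundreds-of-Mb scale by construction.
* **Recombination bins**: breakpoints of all lines are snapped to 125 kb
  window starts and pooled per chromosome; distinct snapped positions
  partition chromosomes into bins. Pooled bin lengths are the sub-Mb-scale
  fragment statistics (median around 0.5–0.6 Mb for 200-line biparental
  populations); both scales are reported, clearly labelled, since both
  definitions are in common use. A bin boundary requires a single breakpoint
  in any line — no frequency threshold.
* **Linkage maps**: markers are realized at window midpoints; adjacent-marker
  recombination fractions $r$ (proportion of lines with differing genotypes)
  are mapped through Kosambi, $d = 25 \ln\frac{1 + 2r}{1 - 2r}$, and summed
  along physical order (marker order is taken from physical coordinates; no
  de-novo grouping or ordering). For RILs the observed fraction $R$ is first
  corrected to the single-meiosis scale with the selfing-series relation
  $r = R / (2 - 2R)$. Map comparisons evaluate cumulative positions at the
  coarser map's marker positions (step-function lookup, interpolation-free)
  and pool chromosomes before computing the Pearson correlation.

Numerical care: fractions at or above 0.5 are clipped to 0.4999 before the
Kosambi transform (with a warning); cumulative placement probabilities are
renormalized so their final value is exactly 1; window tiling uses integer
window counts so chromosomes whose length is an exact multiple of the window
size do not acquire a zero-width window.

## A worked run

```{r example, eval = FALSE}
genome <- maize_genome()
map <- generate_synthetic_map(make_window_grid(genome, 125e3),
                              synthetic_map_params(), seed = 1)
engine <- meiosis_params(map)   # empirical counts, 10 Mb separation

pop <- sim_population(scheme_spec("dh_series", dh_generation = 3,
                                  n_lines = 200), engine, seed = 1)
summary(pop)
#> <pop_summary> F3-DH, 200 lines (seed 1)
#>   events/line : mean 25.65, sd 4.59, median 26.0
#>   fragment    : 83.0 Mb per line (genome/events)
#>   bins (125 kb): 3625; pooled length mean 0.57, median 0.38, sd 0.77 Mb
```

## Problem sizes and reproducibility

Reported summary statistics use 200-line populations averaged over three
seeds — the population size at which the reference measurements were made
and large enough that scheme means have standard errors of a few tenths of
an event. `scripts/acceptance.R` re-derives every headline quantity from
scratch at exactly these sizes. Engine-level property tests use smaller toy
genomes (1–2 chromosomes) where closed-form oracles are available, so the
full suite runs in a few minutes.

## Limitations

Unmodelled factors, inherited from the two-parameter design: gene
conversion, environmental and paternal effects on crossover number,
chromosome-length-dependent count distributions, obligate chiasma, and
four-strand interference beyond the hard 10 Mb rule. The simulator predicts
recombination *pattern* statistics; it does not model selection, phenotypes,
or pedigree import, and comparisons against real genotype matrices require
data the package does not ship.
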