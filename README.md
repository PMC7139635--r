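# recombsim

Forward simulation of recombination patterns in plant breeding populations.

Breeders and geneticists choosing between population designs — doubled-haploid
(DH) induction at different selfing generations, recombinant inbred lines
(RILs) by single seed descent, or multiparent MAGIC funnels — need to know how
much recombination each design accumulates before committing years of field
work. `recombsim` predicts those recombination patterns *in silico* for
maize-like genomes from just two measurable parameters:

* the **per-chromosome crossover-count distribution** per meiosis
  (defaults: the empirical maize DH rates 0.16 / 0.30 / 0.23 / 0.15 for
  0 / 1 / 2 / 3 crossovers, renormalized over {0..3});
* a **window-level recombination landscape** (125 kb windows by default),
  used after per-chromosome normalization
  `p_w = c_w / Σ c_w` as crossover-placement probabilities — either loaded
  from a BED-like file or produced by a built-in synthetic generator
  calibrated to the intermated B73 × Mo17 (IBM) landscape
  (rates in [0, 12.1] cM, mean 3.48 cM per 125 kb, hotspot skew,
  centromeric suppression).

Crossovers on a chromosome must be ≥ 10 Mb apart (hard interference,
rejection-sampled positions); gametes follow a random walk over the two
parental haplotypes; chromosomes are founder-labelled segment mosaics whose
junctions are the observable recombination breakpoints. On top of the meiosis
engine the package provides:

* breeding schemes: the F1-DH … F6-DH induction series, 6-generation SSD
  RILs, and 8/16/32-parent MAGIC by DH induction or continuous selfing;
* summary statistics: recombination events per line
  (`Σ_k breakpoints on chromosome k`), per-line fragment length
  (genome length / events), pooled recombination-bin maps and fragment
  length distributions;
* linkage maps: window-midpoint genotype matrices, adjacent-marker
  recombination fractions, the Kosambi map function
  `d = 25·ln((1+2r)/(1−2r))` with the selfing-RIL correction
  `r = R/(2−2R)`, and map-to-map correlation at shared physical positions.

## Worked example

```r
library(recombsim)

genome <- maize_genome()                      # 10 chromosomes, 2,060.2 Mb
map <- generate_synthetic_map(make_window_grid(genome, 125e3),
                              synthetic_map_params(), seed = 1)
engine <- meiosis_params(map)                 # empirical counts, 10 Mb rule

pop <- sim_population(scheme_spec("dh_series", dh_generation = 3,
                                  n_lines = 200), engine, seed = 1)
summary(pop)
#> <pop_summary> F3-DH, 200 lines (seed 1)
#>   events/line : mean 25.65, sd 4.59, median 26.0
#>   fragment    : 83.0 Mb per line (genome/events)
#>   bins (125 kb): 3625; pooled length mean 0.57, median 0.38, sd 0.77 Mb
```

Reading the output: an average F3-DH line carries ~26 founder switches across
the genome (roughly 1.75× the ~14.4 of an F1-DH, per the junction recursion
`14.4·(2 − 2^(1−t))`); the 83 Mb figure is the coarse per-line ratio of
genome length to events, while the pooled bin statistics (median 0.38 Mb)
describe the population-level mosaic resolution. A Kosambi map of the same
population:

```r
gm <- genotype_matrix(pop, make_window_grid(genome, 500e3))
build_linkage_map(gm, "DH")
#> <linkage_map> DH, 4124 markers, total length 2543.5 cM
```

From the shell, the same run is
`Rscript inst/cli/recombsim.R simulate --scheme dh --dh-generation 3 --n 200 --seed 1 --out f3dh`,
which writes the genotype CSV, bin BED, summary JSON and a log; `sweep`,
`map` and `synth-map` subcommands cover scheme comparisons, map construction
from a genotype CSV, and landscape generation.

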