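# connectisim

Soil microbial communities live in fragmented habitats: a cell trapped in a
pore or aggregate shares its immediate environment with at most a couple of
neighbours, while a cell in a stirred suspension competes with the whole
community at once. `connectisim` simulates the growth of a diverse,
soil-derived community under these two regimes — **high environmental
connectivity** (mixed liquid suspension) and **low environmental
connectivity** (cells isolated singly or in pairs inside agarose beads) —
and provides the analytics needed to compare the simulations with
bead-imaging and 16S amplicon observations.

It is aimed at microbial ecologists who want to ask how compartmentalizing
a community into many 1–2 cell habitats reshapes productivity and
diversity, and which kind of pairwise interspecific interaction regime best
explains observed paired growth.

## The model

A founder community of *n* = 200,000 in-silico cells is sampled from a t = 0
OTU abundance distribution with occurrence probabilities

P(OTU_i) = 100 · OTU_i / Σ OTU_i.

Each OTU receives one maximum specific growth rate µ_max ∈ [0.01, 0.6] h⁻¹,
either uniformly at random or rank-coupled to its abundance (abundant OTUs
tend to be fast). Growth on a single shared carbon pool follows Monod
kinetics,

µ_i = µ_max,i · S / (K_S + S),

with K_S = 0.3 × 10⁻⁶ g ml⁻¹, yield 0.3 g g⁻¹, cell mass 120 fg,
S₀ = 50 mg ml⁻¹, and 120 steps of 0.5 h; growth stops when S falls below
S_min = 3 × 10⁻⁶ g ml⁻¹. Optional founder-death models (random, or
85% death among fast growers with µ_max > 0.25 h⁻¹) thin the starting
community.

In the bead environment, 75% of beads hold one founder and 25% hold two.
Single founders suffer a growth penalty inversely proportional to their
initial abundance; paired founders draw multiplicative rate factors from
one of six interaction scenarios (`null`, `bimodal`, `biased_positive`,
`positive_on_slow`, `biased_negative`, `random`), all capped at 0.6 h⁻¹.

Downstream readouts mirror the experimental pipeline: hypergeometric
subsampling of stationary-phase counts (50,000 reads / 5,000 beads),
per-bead productivity (PBP) with the four pair-growth categories
(no-growth threshold log₁₀ PBP = 3.25, balanced ratio band [0.125, 8]),
12 × 12 paired-growth grids, five alpha-diversity measures, and
simulation-versus-observation comparison (bootstrap Spearman, 2-/4-fold
accuracy, PCA of binned histograms, confidence-envelope deviation of ratio
profiles, scenario ranking).

## Worked example

```r
library(connectisim)

# a synthetic t = 0 sand community (7 sequencing replicates)
tab <- generate_master_distribution(community_config(seed = 1))
s <- summarize_distribution(tab)
s$union_richness   # 1106 OTUs seen in >= 1 replicate
s$mean_richness    # 491.9 OTUs per replicate on average

# full-scale experiment: two scenarios, two repeats
cfg <- run_config(scenarios = c("null", "biased_positive"),
                  n_repeats = 2, master_seed = 1)
exp <- run_experiment(cfg)
exp
#> <connsim_experiment> 2 scenarios x 2 repeats (master seed 1)
#> # A tibble: 2 x 2
#>   scenario        mean_paired_single_ratio
#>   <chr>                              <dbl>
#> 1 biased_positive                     544.
#> 2 null                                519.

dplyr::filter(exp$diversity, rep == 1)
#> # A tibble: 4 x 7
#>   condition             rep richness shannon simpson inv_simpson evenness
#> 1 t0                      1      763    4.23  0.0416       24.0     0.638
#> 2 high                    1      340    3.30  0.0823       12.1     0.567
#> 3 low_null                1      356    3.27  0.130         7.70    0.556
#> 4 low_biased_positive     1      326    3.82  0.0676       14.8     0.661
```

The `mean_paired_single_ratio` column is the ratio of mean stationary
biomass in paired beads to single-occupancy beads: values far above 2 say
that, under the single-occupancy penalty and fast-biased founder death,
being randomly partnered is strongly beneficial. The diversity table shows
the characteristic richness loss from the t = 0 community (763 OTUs in
this subsample) to both grown environments, with bead growth below liquid
growth.

`autoplot()` works on simulations, PCA results and deviation profiles;
`plot_rank_abundance()`, `plot_pair_grid()` and `plot_diversity()` cover
the tables.

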