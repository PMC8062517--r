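---
title: "Modeling microbial community growth under high and low environmental connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling microbial community growth under high and low environmental connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(connectisim)
library(dplyr)
```

## The question and the model

Fragmenting a community into many tiny habitats — each seeded by one or two
founder cells — changes who competes with whom. `connectisim` models this
with a deliberately minimal growth engine: every lineage (founder cell) is
a point mass of biomass growing on one *shared* substrate pool, whether it
sits in a liquid suspension (high connectivity) or inside an agarose bead
(low connectivity). Beads do not have private substrate compartments;
their isolation acts only through *who modifies whose growth rate*:

* **single occupancy** (75% of beads): the founder's rate is multiplied by
  a penalty, by default inversely proportional to the log10 of its initial
  abundance — the view that abundant taxa rely most on community
  goods and suffer most from isolation;
* **paired occupancy** (25%): each partner draws a multiplicative rate
  factor from a global interaction scenario.

Growth follows Monod kinetics, `mu = mu_max * S / (Ks + S)`, evaluated
synchronously for all lineages from the substrate concentration at the
start of each 0.5 h step, with exact exponential growth within the step.
Biomass formation consumes substrate through a fixed yield; when the pool
falls below `Smin` growth stops. The engine contains no randomness: all
stochasticity lives in community assembly and in the scenario factor
draws.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `Ks` | 0.3e-6 | g ml⁻¹ | half-saturation constant, common to all taxa |
| `yield` | 0.3 | g g⁻¹ | biomass per carbon consumed (remainder is CO₂) |
| `cell_mass_fg` | 120 | fg | converts biomass to cell numbers |
| `S0` | 0.05 | g ml⁻¹ | initial carbon (50 mg ml⁻¹) |
| `Smin` | 3e-6 | g ml⁻¹ | concentration below which growth stops |
| `dt`, `n_steps` | 0.5, 120 | h, – | 60 h of simulated growth |
| `mu_cap` | 0.6 | h⁻¹ | global cap on any effective rate |
| rate range | [0.01, 0.6] | h⁻¹ | assigned maximum specific growth rates |
| death (`fast_biased`) | p = 0.85 above 0.25 h⁻¹ | – | non-dividing founders |
| `fraction_single` | 0.75 | – | single-occupancy bead share |

With these defaults the substrate supports far more biomass than 200,000
founders need for realistic colony sizes; the pool typically depletes
around step 55–60, which is what terminates growth. This is a property of
the printed parameter set, kept as-is; users probing absolute cell numbers
should treat `S0` as a tuning knob.

## Interaction scenarios

Each scenario is a stochastic rule for one multiplicative factor per
paired lineage, drawn once at t = 0 (rates are constant during growth —
interactions modulate *attributed* rates, not dynamics):

* `null` — factor 1.
* `bimodal` — community split at log10 reads = 2.8: rare members draw from
  U(0.01, 1.0), abundant from U(1.0, 2.2).
* `biased_positive` — 40% U(0.4, 0.6) (hindering), 60% U(0.6, 1.4).
* `positive_on_slow` — with probability 0.4 the rate becomes
  `-ln(mu) * mu`, boosting slow growers.
* `biased_negative` — strong suppression U(0.01, 0.1) with probability 0.2
  for fast growers (mu > 0.15) and 0.4 for slow ones.
* `random` — factor U(0.01, 1.25).

The bimodal "interaction curve" is specified in the source material only
by its range and abundance threshold; two uniform modes meeting at the
threshold are the simplest shape consistent with it, and both modes are
configurable. The single-occupancy penalty has a second, literal mode
(`verbatim_eq3`) in which the rate itself is replaced by `1.2/log10(mu)`;
since rates are below 1 h⁻¹ this is negative and floors to zero — it
represents the opposite reading, in which slow growers are the penalized
ones. The abundance-argument reading is the default because it matches
the description of the penalty as proportional to initial abundance.

## The synthetic community generator

The generator stands in for a measured t = 0 sand-community 16S table. It
emulates three statistical features: a heavy-tailed (log-normal in log10
counts) abundance distribution; a mean per-replicate richness near 543;
and a union richness over 7 replicates near 1200 — i.e. replicates that
share a pool but each detect only a subset of it. Mechanistically each
replicate applies logistic detection thinning (probability rising with
abundance, midpoint 10² reads, scale 1.6 decades) followed by a
multinomial draw of 50,000 reads. The defaults were calibrated once
against those richness targets and are fixed.

What it does **not** emulate: taxonomy (labels are opaque), phylogenetic
structure, compositional correlations between OTUs, chimeras or other
sequencing artifacts, and any temporal structure. Tests passing on
generated tables therefore validate the pipeline's arithmetic and the
model's internal claims, not the behaviour of any particular real soil
community.

`generate_bead_table()` plays the analogous role for imaging data: it
emits per-colony area × intensity records whose pair-growth categories hit
requested proportions, so the PBP classifiers can be tested against a
known ground truth.

## Numerical choices

* **Within-step growth is exact**: `X <- X * exp(mu * dt)` with `mu` frozen
  at the step start. In the saturated regime (`S >> Ks`) the whole
  trajectory is then exact, which the tests exploit.
* **Depletion step**: if a step's total demand would drive `S` below zero,
  all increments are scaled by one common factor so `S` lands exactly at
  zero — proportional scaling preserves relative competition and keeps the
  carbon balance exact to machine precision.
* **Conservation**: `(S0 - S_t) * V * yield = sum(X_t - X_0)` holds at
  every step by construction; `conservation_error()` exposes the maximum
  relative discrepancy and the test suite bounds it at 1e-6.
* **Subsampling** is multivariate hypergeometric (sequential `rhyper`)
  for integer counts with totals inside the 32-bit range; for real-valued
  cell counts (totals ~1e11 cells) it switches to the multinomial limit,
  which is indistinguishable at sampling fractions below ~1e-4.
* **Degenerate inputs**: dead lineages keep their initial biomass and
  never grow; zero PBPs classify as below the no-growth threshold; pairs
  with sizes ≤ 1 land in the first grid bin unless excluded; identical
  degenerate diversity groups short-circuit to p = 1.
* **Ratio orientation**: bead partners are unordered, so paired-growth
  ratios are reported as |log10(size1/size2)|.

## Design choices where the design was open

* **One rate per OTU**, shared by all its lineages: growth rates are an
  OTU-level trait; two founders of the same OTU grow identically.
* **Abundance-proportional rate attribution** is implemented as weighted
  rank-coupling: draw uniform rates, then hand them out (largest first)
  along an OTU order sampled without replacement with weights
  ∝ log10(reads + 1). Expected rate rises with abundance while the
  marginal rate distribution stays exactly uniform.
* **Rates are assigned before death** — the fast-biased death model needs
  them.
* **Cell budget vs bead split**: the 75/25 occupancy split is per bead;
  bead counts are drawn per-bead i.i.d. and consume the 200,000-cell
  budget exactly (a final pair may be downgraded to a single).
* **Repeats share one t = 0 table**: independent simulation repeats
  re-randomize founder sampling, rates, death, pairing and interactions
  against a single community distribution, mirroring repeated simulation
  against one measured dataset. Between-repeat variance therefore reflects
  the simulation's stochasticity, not generator resampling.
* **Exceedance reference**: the "10-fold productivity increase" fraction
  uses the cohort median PBP at t = 0 as its reference level, with a
  normal-approximation CI across replicate fractions (bootstrap when no
  replicate labels exist).
* **75th-percentile comparison** between single and multiple occupancy
  uses replicate-level percentiles in a Wilcoxon rank-sum test, after
  dividing multiple-bead PBPs by their mean colonies per bead.
* **Deviation ranges**: the paired-growth ratio axis is split into
  smallest [0, 0.5), mid [0.5, 2) and largest [2, 6] log10-ratio ranges
  (configurable); scenario ranking minimizes the summed absolute
  deviations from the 5th–95th percentile envelope, with PCA distance as
  tie-break.
* **Five diversity measures**: richness, Shannon (natural log), Simpson,
  inverse Simpson, Pielou evenness. Conclusions in the test suite are
  anchored on richness, the least convention-dependent of the five.

## Problem sizes used in the test suite

The full-scale experiment (200,000 cells, 120 steps, 6 scenarios, 5
repeats) runs in a few minutes on one core; the suite runs it once and
reuses it across checks. Sampler audits use 10⁵ draws; the generator
calibration check averages 20 seeded communities; scenario recovery uses
a library of 5 simulations per scenario and 5 independent synthetic
observations. Smaller richness/uniformity properties run at reduced sizes
chosen for statistical resolution, not speed of the machine at hand.

## Limitations

* No spatial structure inside beads, no diffusion, no lag phases, no
  maintenance energy, no per-bead substrate compartments.
* Interactions are phenomenological rate multipliers fixed at t = 0; there
  is no mechanistic cross-feeding and no time-varying interaction.
* The generator's log-normal law is a stand-in: the real t = 0 abundance
  law is known only through ranked plots, and any heavy-tailed law meeting
  the richness calibration would serve equally.
* Absolute cell yields exceed experimental densities under the printed
  carbon parameters; comparisons should stay on relative scales
  (ratios, subsampled compositions), which is how every readout here is
  defined.

## A compact run

```{r, eval = FALSE}
cfg <- run_config(scenarios = c("null", "biased_positive"),
                  n_repeats = 2, master_seed = 1)
exp <- run_experiment(cfg)
exp$summary
plot_diversity(exp$diversity)
```
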