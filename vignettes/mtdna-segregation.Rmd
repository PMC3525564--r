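---
title: "Models and methods: simulating mtDNA heteroplasmy segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating mtDNA heteroplasmy segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtsegsim)
```

## The scientific problem

Cells carrying a pathogenic mtDNA point mutation such as m.3243A>G are
usually heteroplasmic: each cell holds a mixture of mutant and wild-type
genomes. If the thousands of mtDNA molecules of a cell segregated
independently at mitosis, per-cell mutation loads would drift apart passage
after passage (vegetative segregation), spreading the single-cell load
distribution and eventually fixing lineages at 0% or 100%. Single-cell
genotyping of cultured cybrid clones instead shows long periods of tight,
stable heteroplasmy interrupted by discrete shifts — a pattern better
explained by a *metastable segregation unit*: a block of several mtDNA
molecules with a fixed mutant/wild-type ratio that replicates faithfully and
segregates as one object, occasionally reorganizing.

`mtsegsim` implements both competing models as stochastic simulators, an
observation model for the in situ genotyping readout (Padlock probe /
rolling-circle amplification, "Padlock/RCA"), and the histogram analysis
used to compare them, so the quantitative consequences of each hypothesis
can be computed and tested end to end.

## The molecule-level drift model

`simulate_drift()` follows the cell-culture protocol literally. A single
founder cell with copy number $N$ and mutation load $p_0$ (mutant count
$\mathrm{round}(p_0 N)$, halves away from zero) is grown to confluence;
each subsequent passage retains a uniform random 10% of cells and regrows to
confluence, which corresponds to $\log_2 10 \approx 3.3$ population
doublings per passage (`effective_generations()`).

One cell cycle is:

1. **Optional turnover** (below).
2. **Replication** of the cell's pool to $2N$ molecules, templates chosen
   with no preference between the alleles. Two modes are exposed because the
   predicted drift rate differs by a factor of two:
   * `relaxed_urn` (default): copies are added one at a time, the template
     drawn uniformly *with replacement* from the current pool — a Pólya urn.
     Replication itself then contributes sampling variance, as in relaxed
     mtDNA replication where some molecules are copied repeatedly and others
     not at all.
   * `strict_doubling`: every molecule is copied exactly once per doubling
     round (a remainder that is not a full doubling copies templates
     *without* replacement), so replication adds no variance and only the
     partition at division drives drift.
3. **Partition**: each molecule goes to daughter 1 independently with
   probability 1/2, so daughter totals are unequal but sum exactly to the
   parent pool. The (astronomically rare at realistic $N$) zero-molecule
   daughter is treated as dead, removed, and counted.

The Pólya urn is sampled exactly through its de Finetti representation: the
number of mutant additions among $j$ urn draws from an urn with $m$ mutant
and $w$ wild-type templates is Beta-Binomial$(j, m, w)$, drawn as
`rbinom(j, rbeta(m, w))`. This is distributionally identical to the
one-molecule-at-a-time process and makes every cell cycle an $O(1)$
operation, which is what lets the simulators run the full 81-passage
protocols in seconds.

**Turnover.** mtDNA is degraded and re-synthesised between divisions.
`turnover_events_per_cycle = r` models one culture cycle of turnover as:
each molecule survives with probability $e^{-r}$ (Poisson degradation at
rate $r$ per molecule per cycle), and the losses are replaced by urn
replication from the survivors, restoring the copy number. Turnover is off
by default; it is the knob that reconciles the low-copy clone predictions
(below) with the protocol, and it accelerates drift by roughly
$1 + 2r(1-e^{-r})^{-1}\!/\!N$-fold per generation relative to
partition-only drift.

## The analytic variance oracle

Grid scans over copy numbers would be wasteful by brute simulation, so
`drift_variance_oracle()` computes the expected per-cell heteroplasmy
variance in closed form. Every step of the cell cycle has a conditional
variance exactly proportional to $p(1-p)$:

* urn replication of a $t$-pool to $T$ copies:
  $\mathrm{Var}(p' \mid p, t) = p(1-p)\,\frac{T-t}{(t+1)T}$ (beta-binomial);
* partition of a $T$-pool into a daughter of size $s$: hypergeometric
  composition, $\mathrm{Var} = p(1-p)\frac{T-s}{s(T-1)}$, averaged over
  $s \sim \mathrm{Bin}(T, 1/2)$ conditioned on $s \ge 1$;
* turnover: thinning plus replenishment, averaged over the binomial
  survivor count.

Hence the expected heterozygosity $h_g = E[p_g(1-p_g)]$ contracts
geometrically, $h_g = h_0 \prod_g (1-\gamma_g)$, and

$$\mathrm{Var}(p_g) = p_0(1-p_0)\left(1 - (1-\gamma_1)(1-\gamma_\infty)^{g-1}\right),$$

where $\gamma_1$ is evaluated at the founder's exact copy number $t = N$ and
$\gamma_\infty$ averages over the stationary daughter-size law. In the
large-$N$ limit $\gamma \to c/N$ with $c = 1$ for relaxed-urn and $c = 1/2$
for strict doubling. The only neglected term is the weak cross-generation
correlation between a cell's copy number and its heteroplasmy variance; the
test suite checks the oracle against brute-force lineage simulation at
$N \in \{4, 16, 64\}$, $g \in \{1, 5, 20\}$ in both modes, and against exact
enumeration of one doubling-and-partition generation at $N = 4$.

With the oracle, the copy-number requirement for *apparent* heteroplasmy
stability drops out analytically. A clone founded at 67% load and observed
stable over 81 passages ($\approx 269$ generations) within a single-cell
measurement SD of ~7% requires

```{r}
copy_number_threshold_scan(0.67, 81, criterion_sd = 0.07,
                           confirm_lineages = 0)$threshold
```

copies per cell under relaxed-urn replication — an order of magnitude above
the ~1,800 copies measured in such clones, which is exactly the argument
that molecule-level random segregation cannot explain the observations. The
criterion SD is an explicit parameter because the original argument's
statistical criterion is not stated beyond the measurement SD; the
acceptance band for this reproduction is therefore a factor of two.

## The segregation-unit model

A `unit_cell()` is a collection of units, each with $k$ mutant of $n$
copies. Faithful replication duplicates every unit exactly; partition sends
each of the $2U$ copies to a daughter with probability 1/2 (a balanced
hypergeometric split is available as an option, since schematic drawings of
the model implicitly balance daughters). Two consequences carry the model's
explanatory power, and both are exact martingale arithmetic:

* **Stability.** A cell whose units all share one composition transmits its
  load to *every* descendant, forever (`test-unit-model.R` checks this
  exactly over 30 generations).
* **Fixation = initial frequency.** After a metastable event alters one
  unit, the altered genotype fixes in a lineage with probability equal to
  its frequency among the $U$ units ($1/U$ for a single unit), at its own
  load $k/n$. `fixation_probabilities()` computes this;
  `simulate_unit_lineages()` verifies it by Monte Carlo, and the test suite
  additionally solves small cases exactly by absorbing-Markov-chain
  enumeration.

`hitchhike_bulk_fraction()` packages the bulk-measurement consequence: one
altered unit among 100 caps its subpopulation at 1% of cells, and a
1/10-wild-type unit on a homoplasmic-mutant background then contributes only
0.1% bulk wild type — a clone that looks homoplasmic in bulk while carrying
a genetically heteroplasmic founder unit. Conversely
`min_unit_size_from_spacing()` turns the smallest observed spacing between
stable heteroplasmy peaks (5–10%) into a lower bound of 10–20 copies per
unit, since a fixed unit can only shift the load in steps of $1/n$.

Reorganization events are modelled at division: `single_unit` redraws one
unit's $k$ from Binomial$(n, p_{\text{cell}})$; `full_redistribution` deals
the cell's pooled mutant molecules into fresh units, either exactly
(multivariate hypergeometric, conserving the total by construction) or as
independent binomials whose total is then repaired by uniform reassignment,
because a real cell has a fixed molecule pool.

## The observation model

Padlock/RCA reports each detected target as a coloured dot (red mutant,
green wild type). Detection efficiency per molecule $\varepsilon$ is low; a
unit of $k$ mutant and $n-k$ wild-type copies is seen red with probability
$(1-(1-\varepsilon)^k)(1-\varepsilon)^{n-k}$, green symmetrically, yellow
(both colours) with probability
$(1-(1-\varepsilon)^k)(1-(1-\varepsilon)^{n-k})$, and is missed otherwise
(`unit_color_probabilities()`). Two readings of the same ~60 dots/cell at
~1,800 copies follow: treating dots as single molecules gives an apparent
efficiency of ~3% (`apparent_efficiency_independent()`); treating them as
$\le$ 1 dot per unit gives ~4–5% per molecule
(`infer_efficiency_unit_mode()`), consistent with the scarcity of yellow
dots at low efficiency. Loads are estimated as red/(red+green); yellow dots
are excluded because they carry both alleles. Per-cell dot-count
heterogeneity arises naturally from binomial detection, with an optional
log-normal per-cell efficiency multiplier reproducing the roughly two-fold
variability seen between preparations; `apply_rfmt_noise()` adds the 4–8%
Gaussian measurement noise of the PCR-based single-cell assay, clamped to
$[0,1]$.

## Histogram analysis

`build_histogram()` bins loads into 5% or 10% bins, left-closed with a
closed top bin, after discarding cells below a dots-per-cell stringency.
`select_stringency()` encodes the published rule: demand that more than 30%
of cells contribute; prefer ($\ge$ 40 dots, 5% bins), fall back to
($\ge$ 20 dots, 10% bins), otherwise flag the sample as under-detected.
Peaks and shoulders are identified by eye in the original analyses;
`detect_subpopulations()` fixes a testable rule instead — a peak is a strict
local maximum (plateaus resolved leftmost) with frequency at least
`min_fraction` (default 10%), and adjacent above-threshold bins are reported
separately as shoulders. `compare_distributions()` summarises a simulated
load distribution against an observed histogram (mean, SD, fraction
homoplasmic, chi-square distance) and issues the "greater variation"
verdict when the simulation spreads more than the observation; note that
simulated homoplasmy (literally 0 or 100% of molecules) and observed
"apparent homoplasmy" (a single-colour cell) are reported as distinct
quantities.

## The synthetic-data generator

`generate_scenario()` composes the layers into a complete in silico
experiment with known ground truth: segregation model, passaging protocol,
optional reorganization events, optional growth advantage, and the
detection model applied to every cell of every passage. The growth advantage
is a *division-propensity* multiplier attached to a reorganized lineage — a
proxy for a nuclear genomic event on which the altered unit hitchhikes —
not a fitness effect of the mtDNA genotype, which would contradict the
neutrality of the segregation models. Reorganizations occur at division
with a fixed probability (default 0, since no rate is known); a single
event can be forced at a chosen passage for controlled experiments.

The presets in `clone_presets()` pin the generator to the study conditions:

* `V_3.2` — founder 67%, 1,800 copies/cell, 81 passages;
* `G_55.2` — founder 55%, 350 copies/cell, 32 passages, turnover 2 per
  molecule per cycle;
* `unit_toy` — 72 molecules in 9 units of 8, half mutant;
* `V_50_like` — 95% load, 100 units of 20, rare single-unit events with a
  two-fold advantage.

The `G_55.2` turnover rate is set a priori from the diffusion argument: with
partition-only drift at $N = 350$, 32 passages ($\approx 106$ generations
plus the first outgrowth) give $\gamma g \approx 0.3$ — far from fixation —
whereas the prediction to reproduce is that the *great majority* of cells
would be homoplasmic. A turnover rate of 2 per molecule per cycle (mtDNA
half-life about a third of the cell-cycle time, in the regime of relaxed
replication uncoupled from the cell cycle) gives $\gamma g \approx 4$,
pushing >90% of lineages to fixation, which matches that qualitative
prediction. Detection presets use 3.3% independent-molecule efficiency for
the drift clones (about 60 dots/cell at 1,800 copies) and 5% unit-clustered
efficiency for unit scenarios.

What the generator deliberately does **not** emulate: spatial structure of
the mitochondrial network, physical repulsion of RCA products, nuclear
karyotype evolution (the advantage multiplier abstracts it), cell-cycle
duration variability, and selection on mtDNA genotype. Passing tests on
synthetic data therefore show internal consistency of the models and
pipeline, not that real cultures obey them.

## Numerical choices and problem sizes

* **Population cap.** Cultures reach ~10^6 cells; the simulators default to
  10^4. Per-cell load drift is dominated by within-cell sampling, not
  population size, so the final spread is insensitive to the cap (tested:
  caps 300 vs 1,200 agree within Monte Carlo error). The cap is a plain
  parameter, so full-scale runs are one argument away.
* **Lineage shortcut.** `simulate_drift_lineages()` samples the intrinsic
  within-cell drift component directly (one random daughter per division),
  which is what grid scans and Monte Carlo confirmations use; the full
  population simulator is kept for the end-to-end protocol including
  bottleneck resampling.
* **Test problem sizes.** Monte Carlo tests use 2,000–10^4 replicates with
  3-standard-error bands computed from the data (fourth-moment standard
  errors for variances); the threshold scan confirms its selected copy
  number with 1,000 lineages over 269 generations.
* **Ties and edges.** Founder mutant counts round half away from zero; the
  top histogram bin is closed; plateau peaks resolve leftmost; dead
  (zero-molecule or zero-unit) daughters are removed and counted, and
  lineage simulators redraw them, i.e. condition on survival.
* **Determinism.** All randomness flows through R's global RNG; every
  config object carries an optional seed, the CLI honours `--seed`, and
  generated datasets are byte-identical given scenario + seed.

## Known limitations

The variance oracle ignores a small cross-generation correlation (checked
to be within Monte Carlo error down to $N = 4$, but it is an approximation,
not an exact result, for $g > 1$). The binomial redistribution method is
exactly binomial only before its conservation repair. Turnover uses
batch thinning-and-replenishment per cycle rather than one-at-a-time
degradation/replication events; the two differ in higher moments at large
rates. The unit model does not regulate unit number per cell (daughter unit
counts drift binomially), mirroring the molecule model's treatment of the
pool between replications. Copy-number heterogeneity between cells of a
clone, mixed unit sizes within a cell, and de novo mutation are not
modelled.
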