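---
title: "Models and methods: clonal evolution of coexisting gut strains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: clonal evolution of coexisting gut strains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexistevo)
```

# The question and the model

Two *E. coli* strains colonize the same gut at very different abundances
(about $10^{8.5}$ and $10^{7.4}$ CFU/g of feces), each split into two
neutrally marked fluorescent lineages. Over three months the major strain
keeps both of its markers while the minor strain fixes one — a pattern that
constrains what the supply (*u*) and strength ($\bar s$) of beneficial
mutations can look like. `coexistevo` implements a Wright–Fisher model of
strictly clonal evolution to map that constraint, together with the
analysis procedures used on the experimental readouts (CFU marker
trajectories, pooled-sequencing variant tables, coverage profiles, reads,
growth curves, competition series).

## Wright–Fisher simulator

The total population across both strains has constant census $N$
(default $10^6$, a rough count for a fecal sample) and non-overlapping
generations. It is partitioned into lineages, each a triple
(marker type, relative fitness, count); the four founders have fitness
exactly 1 and counts given by largest-remainder rounding of the initial
fractions $(0.05, 0.05, 0.45, 0.45)$ — markers 0–1 are strain A (10% of
the census), markers 2–3 strain B1.

Each generation:

1. **Mutation.** Every lineage yields $\mathrm{Binomial}(\text{count}, u)$
   new mutants; each founds a lineage of count 1 with fitness
   $w_\text{parent} (1 + s)$, $s$ drawn from the DFE. Across the whole
   population the number of mutations per generation is then binomial with
   mean $Nu$ — indistinguishable in practice from the Poisson supply the
   model assumes, without needing an approximation regime.
2. **Selection and drift.** The next generation is one multinomial draw of
   size $N$ with probabilities proportional to count × fitness. Extinct
   lineages are pruned.

Mutation precedes resampling, so a mutant must first survive drift in the
generation it arises — the natural reading of "a new mutation arises and
escapes genetic drift". The model is silent on the alternative order
(mutate after sampling); at the parameter scales involved the difference is
one generation of drift on a count-1 lineage.

Fitness composes multiplicatively across mutations in a lineage,
$w = \prod_i (1 + s_i)$: the standard Wright–Fisher convention, which keeps
fitness positive for any sequence of beneficial effects. The lineage ledger
is exact — no fitness-class binning — so continuous gamma-distributed
effects are represented without discretization error.

## Distribution of fitness effects

`dfe_params()` supports a point mass at $\bar s$ ("fixed") and gamma
distributions parameterized by mean and shape, with scale
$\bar s/\text{shape}$ so the mean is $\bar s$ for every shape. Shape 1 is
the exponential DFE common in theory; shape 100 has coefficient of
variation 0.1 and behaves like the fixed-effect limit; the package's tests
verify the moments and the fixed/shape-100 agreement on grid outcomes.

## Outcome classification

A replicate is *compatible* with the experimental pattern when, at the
final generation:

- the minor strain maintains exactly one marker,
- the major strain maintains both, and
- both strains are extant.

A marker counts as maintained when its within-strain frequency is at least
`loss_threshold` (default $10^{-3}$). A strict-extinction rule
(threshold 0) makes loss nearly unreachable at $N = 10^6$ within 1600
generations under weak selection, whereas CFU plating cannot see lineages
much rarer than $10^{-3}$ of a strain; both readings are available through
the parameter.

Strain extinction defaults to the literal sense: a strain is extant while
it has at least one individual (`extinction_threshold = 0`, configurable).
Under directional selection with a census-proportional mutation supply, the
minor strain routinely ends far below 1% of the census while its marker
pattern is exactly the observed one; requiring a 1% floor would declare
essentially every replicate incompatible at every DFE and erase the
contrast the sweep is designed to measure. The compatibility definition
being matched speaks only of marker maintenance within each strain, so the
package treats coexistence as non-extinction and leaves stricter floors to
the caller.

## Parameter sweep and Fisher scoring

`run_grid()` crosses log-spaced $u \in [10^{-8}, 10^{-4}]$ and
$\bar s \in [10^{-4}, 10^{-1}]$ with DFE shapes {fixed, 100, 10, 1},
10 replicates per cell by default. Each cell's compatible/incompatible
split is compared with the experimental 8-of-8 mice by a two-sided Fisher
exact test on the 2×2 table (rows: experiment vs simulation; the
orientation does not affect the p-value); cells with $p > \alpha = 0.05$
are "starred" as statistically compatible. The test is computed by direct
hypergeometric enumeration: the two-sided p-value sums the probabilities of
all tables with the observed margins whose probability does not exceed that
of the observed table, with a relative slack of $10^{-7}$ (plus an absolute
$10^{-12}$ floor) to absorb floating-point ties — the same convention as
`stats::fisher.test`, against which the implementation is cross-checked,
alongside a binomial-coefficient enumeration oracle over all margins up
to 20. The Fisher test is applied per cell; pooling across cells is not
attempted because the cells answer separate questions.

Replicate seeds are `seed + (cell - 1) * replicates + replicate`, making
every cell reproducible and independent.

# Marker-trajectory analysis

CFU counts come with a plating detection limit (default 300 CFU/g). A zero
count is reported as *below LOD* with the frequency upper bound
$\mathrm{LOD}/(\mathrm{LOD} + \text{CFU}_\text{other})$ rather than 0; a
day where both markers of a strain are zero carries a strain-absent flag
and no frequency.

Polymorphism is called *lost* for a (mouse, strain) when exactly one marker
is below LOD on each of the last $k = 2$ sampled days — one vanishing
observation can be a plating fluke, two consecutive ones at series end
behave like fixation of the partner marker. A strain absent on every
sampled day from day 7 onward is *not colonized* (early samples can be
positive from the gavage itself). Neither rule is formalized in the source
experiments; both are parameters.

The strain-dependence of polymorphism maintenance is tested exactly:
Fisher's test on the 2×2 maintained/lost table, excluding uncolonized
strains. Strain loads are summarized as per-mouse time-averaged
$\log_{10}$ CFU/g over coexistence days (both strains at or above LOD),
then averaged across mice with a standard error across mice — so mice with
many samples do not dominate.

# Variant-table analysis

Coordinates are 0-based half-open throughout; conversion to or from
1-based happens only at file boundaries. The ancestral false-positive
filter blacklists ancestral calls with frequency strictly above 0.015 that
are supported by strictly more than 3 reads, plus all ancestral
consensus-mode calls, and removes matching evolved variants; it is
idempotent and an identity for empty blacklists. Event counts report
per-class totals and per-mouse means; means are rounded half away from
zero to one decimal (so 82 events over 8 mice
reports as 10.3 and 38 over 8 as 4.8), with the denominator (successfully co-colonized
mice) exposed as a parameter. dN/dS is the raw non-synonymous to
synonymous count ratio — no substitution-model correction — with a flagged
undefined value when no synonymous SNPs exist. Selective sweeps use the
strict rule frequency > 0.95, flagging full fixation separately.
Parallelism distinguishes gene-level hits (same target, ≥ 2 mice) from
mutation-level hits (identical change); convergence intersects targets
across strains at gene and, given a mapping, pathway level.

The rate of mutation accumulation per mouse is
$M(t) = \sum_i f_i / g$, allele-frequency sums over elapsed generations
($g = \text{days} \times 18$; 88 days = 1584, 43 days = 774), averaged
across mice with its SD; an optional genome size yields a per-bp rate.
$M(t)$ is linear in the frequencies by construction.

## Coverage ratios and HGT reads

The presence frequency of a genomic element (prophage, deletion region) is
the mean of the ratios of the element's median depth to the median depths
of its left and right flanks; the deletion/excision frequency is one minus
presence. Flank width defaults to 5,000 bp — wide enough to stabilize the
median at typical depths while staying local to the element — and zero
flank coverage is an error, not a zero. The raw ratio is retained alongside
the [0, 1]-clipped value, since sampling noise can push it slightly
above 1.

A variant is a potential horizontal-transfer event when strictly more than
1% of its overlapping reads match the other strain's genome *exactly* over
their full span (forward or reverse complement). Exact string equality
stands in for a 100%-identity alignment match: the decision rule only asks
whether a read is identical to a reference window, so a full local aligner
would add machinery without changing the answer. Reads identical in both
references are uninformative and count toward neither tally (but remain in
the denominator). Flagged variants within `max_gap` of each other merge
into half-open tracts with a mean donor fraction per tract.

# Fitness assays

The maximum growth rate slides a window of 5 consecutive readings
(10-minute spacing in the emulated plates) over $\ln(\mathrm{OD} -
\mathrm{OD}_\text{blank})$, fits ordinary least squares, and returns the
steepest slope among windows with $R^2 > 0.9$ (strict), ties
to the earliest window; readings at or below blank never enter a window.
Windows overlap — the readings are dense enough that tiling would discard
information. With noisy readings the maximum over many windows is upward
biased when near-blank points enter the logarithm, so `min_signal` can
exclude readings below the instrument's effective noise floor (the
pipeline uses ten times the configured reader repeatability); the default
0 preserves the strict OD-above-blank rule for clean curves. No qualifying
window returns an explicit no-estimate row, not an error. Carrying
capacity is the blank-subtracted maximum OD floored at zero, and relative
metrics divide evolved values by the mean of the ancestor matched by
fluorescent label.

The in vivo selection coefficient is, per mouse, the OLS slope of
$\ln(\text{CFU}_\text{focal}/\text{CFU}_\text{reference})$ on day; days
with a zero count are dropped with a warning and mice with fewer than two
usable days get no estimate. The pooled value is the mean of per-mouse
slopes with SE = SD/$\sqrt{n}$, and the per-generation value divides by 18
generations/day (reported to two decimals, so 4.0/day prints as 0.22 per
generation). The estimator is antisymmetric under swapping focal and
reference.

# Synthetic data: what it emulates and what it does not

Every generator is driven by one `synth_config()` whose seed is expanded
with fixed per-stage offsets (+101 trajectories, +202 variants, +303
coverage, +404 reads, +505 growth, +606 competition), so stages are
independently reproducible. Defaults are the study conditions: strain
loads lognormal around $10^{8.5}$ and $10^{7.4}$ CFU/g with 0.4 log10 SD
(the scale of the reported between-mouse standard errors), a 300 CFU/g detection limit, marker
fractions $(0.05, 0.05, 0.45, 0.45)$, per-mouse event means 10.25 and 4.75
(the 82 and 38 totals over 8 mice) with the observed class mix, nine
planted sweeps in the minor strain and none in the major, 100× coverage,
2% reference divergence (within the observed per-window nucleotide
identity band), logistic growth at the ancestors' scale (r = 1.08/h,
K = 0.8 OD), and a competitive advantage of 4.0/day with 0.3 lognormal CFU
noise. Every generator returns a `truth` table (`truth_`-prefixed columns)
that recovery tests consume rather than re-deriving.

What the generators deliberately do not emulate: instrument-specific
sequencing error profiles, read mapping or variant calling itself (tables
are generated at the post-calling stage), within-day autocorrelation of
CFU noise, plasmid dynamics, or frequency-dependent selection. Passing
recovery tests therefore demonstrates that the estimators invert the
generative models stated here — not that they are robust to every artifact
of real sequencing or plating.

# Problem sizes and numerical choices in the test suite

The suite favors closed-form oracles at reduced size: neutral
heterozygosity decay is checked against $H_0 (1 - 1/N)^t$ at $N = 100$
over a few thousand replicates; selection trajectories against the
deterministic recursion $x_t = x_0(1+s)^t / (x_0(1+s)^t + 1 - x_0)$ at
$N = 2000$; the mutation supply against $Nug$ by Poisson thinning at
$N = 10^4$; and the DFE-shape contrast at the full study point
($N = 10^6$, 1600 generations, $u = 10^{-5}$, $\bar s = 0.01$) with ten
fixed-seed replicates per shape. Monte-Carlo assertions use three standard
errors. The Fisher implementation is compared against brute-force
enumeration for every table with margins up to 20. These sizes were chosen
so the oracles are sharp (standard errors well below the effects tested)
while keeping each property a desk-scale computation.

# Known limitations

- The simulator models a single well-mixed compartment; gut spatial
  structure, migration, and bottlenecks are out of scope, as are
  recombination and within-simulation gene transfer (transfer is detected
  from data, not simulated).
- Deleterious and frequency-dependent mutations are not modeled.
- The exact-match read rule understates donor evidence when sequencing
  error is high; with the default error-free synthetic reads this is
  immaterial, but real data at ~1% error would need the aligner-based
  original.
- The exact construction behind the strain-dependence p-value reported for
  the original experiments is ambiguous; the package implements the
  Fisher-exact path and does not attempt to reproduce that particular
  number.
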