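---
title: "Modelling vascular epiphyte communities in dynamic forest canopies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vascular epiphyte communities in dynamic forest canopies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

epivox is an individual-based model of vascular epiphyte communities in a
three-dimensional forest canopy. The model space is a lattice of 1-m^3
voxels (0-based integer coordinates, half-open `[i, i+1)` metre bins on
every axis; up to 50 m of canopy). Each voxel carries three environmental
state variables per year: light intensity $I$ (µmol m^-2^ s^-1^), total
arboreal substrate area $S_B$ (m^2^ of bark available for attachment), and
the relative annual substrate loss $S_{Loss}$ (%). These microhabitat
matrices are derived from yearly snapshots of a forest stand and drive the
four processes applied to every individual epiphyte each year: dispersal
and recruitment, growth, and four mortality channels, followed by an age
increment.

Individuals carry an identity, species, age $A$, mass $M$ (g) and voxel
position. Species are trait vectors: age and mass at maturity
($A_{Mat}$, $M_{Mat}$), maximum mass ($M_{Max}$), von Bertalanffy growth
constant $K$, potential fecundity $n_{RPot}$, dispersal kernel parameters
($D_K$, $D_{KAs}$), and a parabolic light niche ($I_{Min}$, $I_{Opt}$,
$I_{Max}$ with coefficients $I_A, I_B, I_C$).

### Growth

Mass follows the cubic (length-to-mass) von Bertalanffy trajectory,
modulated by the light response $f(I) \in [0, 1]$:

$$M' = M_{Max}\left(1 - \left(1 - (M/M_{Max})^{1/3}\right)
  e^{-K f(I)}\right)^3.$$

The single constant $K$ is derived from three traits so that a plant
growing from zero mass under optimal light reaches $M_{Mat}$ exactly at
age $A_{Mat}$: $K = -\log(1 - (M_{Mat}/M_{Max})^{1/3})/A_{Mat}$. The
parabola $f$ has roots at the niche limits and value 1 at the midpoint
$I_{Opt} = (I_{Min}+I_{Max})/2$. We fix $I_{Opt}$ at the midpoint — the
minimal construction consistent with listing all three niche traits;
asymmetric light responses are out of scope.

### Recruitment

Mature individuals ($A \ge A_{Mat}$; mass at maturity only enters through
the derivation of $K$, so age and mass maturity coincide under optimal
light) produce Poisson-distributed propagules with mean
$n_{RPot} \, f(I_{parent})$ — potential fecundity is realized fully only
under optimal light. Each propagule lands in a voxel drawn with
probability proportional to

$$S_B(v)\, e^{-D_K d(parent, v)} \times
  \begin{cases} D_{KAs} & \Delta z < 0 \\ 1 & \Delta z \ge 0,\end{cases}$$

i.e. a negative-exponential kernel weighted by local substrate, with a
multiplicative downward bias (gravity). The neighborhood is truncated
where the kernel falls below $10^{-3}$ of its peak, which bounds the cost
with negligible probability mass. Propagules landing outside the species'
light niche are lost, as are propagules arriving in voxels without enough
free substrate: establishment requires `est_area_factor` (default 6)
times the seedling's own occupied area to be free beside the standing
occupants, reflecting that germination and anchoring need more room than
the plantlet body. We initially let recruits establish regardless of
space and culled them at the next mortality step, but that books the
surplus as competition deaths and drives the competition mortality rate
several-fold above both its empirical range and the metabolic rate;
requiring free substrate at establishment keeps the cause ledger faithful
to what each channel means. Recruits enter at a seedling mass of 0.5 g (a
global default; real epiphyte propagules are far smaller, but the value
stands for the smallest tracked established stage).

### Mortality

Four channels apply in a fixed annual order — deterministic environmental
filters first, then the stochastic channels — because the death ledger's
cause attribution depends on the order, so it is frozen and documented:

1. **Light niche**: death iff the voxel's $I$ lies outside
   $[I_{Min}, I_{Max}]$ (forest change moved the habitat out of the
   niche).
2. **Space competition**: each individual occupies
   $a = g_S M^{p_A}$ m^2^ (default $p_A = 2/3$, geometric
   surface-to-mass scaling). Where a voxel's total demand exceeds $S_B$,
   individuals are removed smallest-mass-first (ties broken by keeping
   the lower individual id — deterministic replay) until the rest fit. A
   lone individual exceeding its voxel's area dies too (cause
   "oversize"); both express space limitation and are merged as
   "competition" in summary outputs, with the split retained.
3. **Dislodgement**: Bernoulli($S_{Loss}/100$) — falling with shed
   branches or fallen trees.
4. **Metabolic**: Bernoulli($\min(1, k_M M^{-1/4})$), the quarter-power
   mass scaling of the metabolic theory of ecology; it absorbs all
   mortality causes not modelled explicitly (desiccation, herbivory,
   pathogens) and dominates for seedlings.

### Scheduling and reproducibility

Each year executes recruitment → growth → mortality → age increment. One
base seed drives a simulation; every (year, submodel) pair derives its own
substream seed, so a change in one submodel's draw count cannot silently
reshuffle another's. The test suite pins the exact semantics with a
straight-line, loop-based re-implementation of the annual step that must
reproduce the package's vectorized/compiled path bit for bit on a small
lattice.

## The synthetic forest generator

The epiphyte model consumes only voxel summaries of the stand, so any
forest input reproducing realistic stem turnover, size structure and
occasional large-tree falls suffices. The built-in generator is a minimal
gap-model-style demographic simulator:

- stems recruit at 10 cm DBH at the least crown-covered of three candidate
  positions, with density regulation toward ~500 stems ha^-1^;
- DBH grows by a saturating increment (0.9 cm a^-1^ at small sizes,
  asymptote 120 cm);
- background mortality is **tuned by bisection** during burn-in so the
  realized long-run mean stem turnover — the mean of annual mortality and
  recruitment rates — hits the scenario target (the four natural-dynamics
  scenarios use 1.6, 2.2, 2.7 and 3.2 % a^-1^, spanning the 1–4 % a^-1^
  range of tropical stands); an unreachable target is an error, not a
  silent miss;
- yearly mortality is scaled by a lognormal interannual multiplier
  (CV 0.25) — turnover varies between years but no specific form was
  available, so a lognormal is the least-structured positive choice;
- mortality is mildly U-shaped in DBH (factor $1 + (D/90)^2$), so large
  trees fall occasionally and produce the gap-driven abundance crashes
  that characterize epiphyte dynamics;
- selective logging removes every tree reaching the target DBH (40, 45 or
  50 cm) each year; a static mode freezes the burnt-in stand.

Tree allometry uses standard tropical power laws (height, crown radius and
depth, branch surface area and leaf area from DBH), with coefficients
exposed in the configuration. Trunks contribute exact cylindrical lateral
area to the voxels they cross. Branch surface is concentrated
inner-crown-first at a fixed density of 0.5 m^2^ per filled voxel — a
branch-like, spatially stable allocation in which a growing tree only adds
substrate voxels; spreading the same area uniformly over the whole crown
was rejected because it strands capacity in thousands of tiny-area voxels
and produces implausibly high space-competition mortality. Light follows
Beer–Lambert extinction down each column
($I(z) = I_{top} e^{-k_{ext} LAI_{above}}$, defaults $I_{top} = 1000$
µmol m^-2^ s^-1^, $k_{ext} = 0.35$), with a linear blend toward full light
within 3 m of lateral plot boundaries (edge brightening). Substrate loss
between consecutive years is the clamped relative decrease
$100 \max(0, S_B^t - S_B^{t+1})/S_B^t$: gains are not negative losses,
because the quantity acts strictly as a fall-mortality probability.

## Trait calibration and the viability screen

The shipped trait ranges (`inst/extdata/trait_ranges.yaml`) and global
defaults are surrogate values calibrated in-house. There is no external
reference forest or published trait table to import, so we followed the
same calibration loop a field-parameterized build would use: sample trait
sets, simulate, and compare against the target community patterns
(long-term dynamic equilibrium, community-wide mortality around 14 % a^-1^
with metabolic > dislodgement ≈ competition ≫ light-niche mortality, a
static-forest saturation plateau near 85 %, long-run abundance of a few
tens of thousands per hectare, right-skewed rank abundance). Masses and the lower light niche limit are
sampled log-uniformly (both span decades — without the latter, replicate
sets can miss the deep-shade or full-sun ends of the gradient and leave
large substrate fractions uncolonizable); $M_{Mat}$ is a uniform fraction (0.25–0.5) of
$M_{Max}$ to guarantee $M_{Mat} < M_{Max}$; $A_{Mat}$ follows the
trait correlation $A_{Mat} = k_{Mat} M_{Max}^{q_{Mat}}$ (defaults
$k_{Mat} = 2$, $q_{Mat} = 1/4$), jittered ×0.8–1.25.

Unscreened communities have no interior equilibrium: depending on
fecundity they either decline to extinction or grow until space
competition dominates. The viability screen resolves this exactly as in
the source study: each candidate species is simulated alone (100 founders,
one century) on reference microhabitat matrices, and passes iff the
geometric mean of its annual population growth rate lies in [1.00, 1.01]
— persisting without outcompeting. (The geometric mean is the standard
choice for multiplicative growth; the arithmetic alternative differs
negligibly at these rates.) `viable_species_pool()` repeats
sample-and-screen until a target pool size is reached, and replicate
community sets are drawn from the pool. Screened communities fluctuate
around a dynamic equilibrium punctuated by tree-fall crashes, as intended.

## Summary statistics

- **Saturation**: occupied area $\sum_i g_S M_i^{p_A}$ over total
  substrate $\sum_v S_B$ (all voxels, the literal reading of "total
  available substrate"), in percent. Because space competition acts per
  voxel, values well below 100 % can already be effectively saturated.
- **Mortality decomposition**: per cause, deaths over start-of-year
  standing abundance (the annual-census convention; zero-abundance years
  are excluded).
- **Structural distributions** (pooled over a year window): rank
  abundance; vertical distribution in 1-m bins (the voxel resolution);
  mass histogram over quarter-decade log bins; per-species height
  quantiles (2.5/50/97.5 %) sorted by median height.

## Experiments

`scenario_presets()` returns the nine study scenarios (four turnover
levels, static, three logging targets, three fragment sizes 0.25/0.5/1 ha
— the 0.5-ha fragment is realized as 50 × 100 m). `run_experiment()`
crosses scenarios with independent forest replicates and species sets
(the full design uses 5 forests × 10 sets = 50 runs per scenario, 600
years, initialized at 40,000 individuals ha^-1^ spread evenly over 100
species); forests replicate by seed only. Forests are burnt in to
quasi-equilibrium for 200 years before year 0, so epiphytes start on
stands in equilibrium. Scenario comparisons pool the second half of each
run, after the community has re-assembled from its uniform initial
conditions.

## Problem sizes used in the shipped checks

The automated checks run scaled-down versions of the full design, chosen
as the smallest sizes at which the targeted patterns are stable: the
stochastic reproduction checks use 300-year runs on 0.25-ha plots, five
replicate runs on two forest replicates with species sets drawn from a
screened pool of ≥60 viable species, pooling years 150–299; the
scenario-ordering checks use one run per turnover scenario and a 0.5-ha
versus 0.25-ha fragment contrast; the generator-turnover checks use the
full 600-year horizon (they are cheap). The acceptance script reports the
realized reference-forest stem turnover from five independent 600-year
forests.

## Known limitations

- The synthetic stand generator reproduces turnover, size structure and
  large-tree falls, not the architecture of any real or previously
  published forest; absolute substrate totals and light profiles are
  internally consistent rather than field-calibrated.
- Clonal vegetative growth, humidity/bark/canopy-humus niche axes,
  growth spillover into neighbouring voxels, edge-effect tree mortality
  and metacommunity seed exchange are out of scope by design.
- Passing the shipped checks shows the model reproduces the targeted
  community-level patterns under the surrogate calibration; it does not
  validate the model against field data.
- With 100 founders per species in a closed plot, local extinction is
  permanent and richness declines faster than in open real-world systems;
  screened near-neutral species slow but do not stop this.
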