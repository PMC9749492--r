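---
title: "Macromolecular allocation and emergent plankton stoichiometry: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macromolecular allocation and emergent plankton stoichiometry: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoalloc)
```

## The model

`phytoalloc` implements a coarse-grained macromolecular allocation model of
phytoplankton physiology. A cell is described by the fraction of its carbon
held in a small set of functional pools -- photosynthetic protein,
biosynthetic protein, constitutive ("other") protein, RNA, DNA, chlorophyll,
thylakoid phospholipid, other carbon (carbohydrate, lipid, wall) -- plus
storage pools for carbon, nitrogen, phosphorus and iron. Each pool has a
fixed elemental composition (the `Y` ratios), so the elemental quotas
$Q_i$ (mol element per mol cellular C, with $Q_\mathrm{C} \equiv 1$) follow
from the macromolecular allocation.

Three empirical relationships close the system under a pseudo-steady-state
assumption (intracellular re-allocation is fast -- hours to days -- relative
to the environmental change imposed on the cell):

* chlorophyll scales with growth rate,
  $Q_\mathrm{C}^{Chl} = A_{Chl}\,\mu + B_{Chl}$, with
  $A_{Chl} = (1+E)/v_I$ and $B_{Chl} = m/v_I$; $E$ is growth-dependent
  respiration, $m$ maintenance respiration, and
  $v_I = v_I^{max}\,(1 - e^{-A_I I})$ the chlorophyll-specific
  photosynthesis rate (light $I$ in µmol photons m^-2^ s^-1^);
* photosynthetic protein, thylakoid phosphorus and photosystem iron are
  proportional to chlorophyll ($A_{Pho}$, $A_{Pho}^{P:Chl}$,
  $A_{Pho}^{Fe}$);
* biosynthetic protein is proportional to growth rate ($A_{Bio}$) and RNA
  phosphorus to growth rate times total protein ($A_{RNA}^{P}$), plus a
  minimum RNA content.

Substituting these into the elemental budgets makes each structural quota a
quadratic in growth rate,
$Q_i^{NonSto} = a_i\,\mu^2 + b_i\,\mu + c_i$ for $i \in \{N, P, C\}$
(`quota_coefficients()`), and a linear function for iron. The quadratic
coefficients depend on light only through $A_{Chl}$ and $B_{Chl}$: low light
inflates the chlorophyll terms, so the structural N and C costs at zero
growth ($c_N$, $c_C$) *decrease* with increasing light.

Inverting the quadratic gives the growth rate each element could support if
it were the only limitation (`growth_if_limited()`), and Liebig's law takes
the minimum over N, P, C and Fe (`liebig_growth()`). Storage of each
non-limiting element is the excess of its quota over its structural demand
(`storage_partition()`), with carbon storage computed last as the residual
that closes the carbon budget at 1, accounting for the carbon cost of
nitrogen storage. Storage is finite: nitrogen storage is capped at a
prescribed capacity above the structural quota, while phosphorus and iron
quotas are capped at class constants (laboratory quotas saturate nearly
independently of growth rate). Anything above the cap is "excess" and is
exuded back to the dissolved pool on a timescale $\tau^{Exu}$
(`excess_quota()`, `effective_uptake()`).

Quotas evolve as
$\mathrm{d}Q_i/\mathrm{d}t = V_i^{E\!f\!f} - \mu\,Q_i$ with Monod uptake
$V_i = V_i^{max}\,[i]/([i] + K_i)$ -- uptake minus exudation minus growth
dilution -- in the six-step order: quota-growth relations, Liebig minimum,
storage, excess, effective uptake, explicit update (`step_quota()`).

### A note on one printed coefficient

The published coefficient block for $b_P$ carries an RNA N:P ratio factor on
the RNA term. Direct substitution of the RNA relationship (which is already
expressed in phosphorus units) into the phosphorus budget produces no such
factor, and the corresponding $a_P$ term correctly has none. The package
implements the substitution result; the pool-summation oracle test (which
rebuilds the quadratic from the individual pools) would fail with the extra
factor.

## Two size classes

Inter-taxonomic variation is reduced to two classes. The **small** class is
a picocyanobacteria analogue (gleaner): low half-saturation constants, low
maximum uptake and photosynthesis rates, low phosphorus storage capacity,
and a steep photosynthesis-light response (low-light specialist). The
**large** class is a eukaryote analogue (opportunist): higher $V^{max}$,
$K$, $v_I^{max}$ and a roughly 2.3-fold higher maximum phosphorus quota.
The per-class light-response coefficient deserves a comment: with a single
shared $A_I$, the chlorophyll-specific initial slope $v_I^{max} A_I$ would
scale with $v_I^{max}$ and the large class would out-photosynthesize the
small class at *every* irradiance, handing it all low-light habitats --
contrary to the observed dominance of picoplankton in dim, stratified
subtropical columns. Making $A_I$ a class trait (0.025 vs 0.006 per
µmol m^-2^ s^-1^) crosses the two light curves near 40 µmol m^-2^ s^-1^:
the small class wins dim habitats, the large class bright ones. This is the
standard gleaner-opportunist photophysiology trade-off.

Mortality is linear ($m_l$, sinking and maintenance losses) plus a *small*
quadratic term ($m_q$, implicit grazers whose biomass tracks their prey).
The quadratic term matters qualitatively: in a steady 0-D environment a
purely linear closure hands every competition to whichever class has the
lower subsistence resource level (always the gleaner), and the
opportunist's eutrophic dominance could never emerge. With the quadratic
closure the classes coexist with biomass proportional to their net growth
advantage, so the small-class fraction $f_S$ falls smoothly along an
oligotrophic-to-eutrophic gradient rather than flipping between exclusions.
A corollary honestly stated: $f_S$ approaches ~0.4 rather than 0 in the
eutrophic limit; the monotone decline (tested as Spearman rank correlation)
is the robust prediction at desk scale.

## Parameters

All parameters live in a commented INI file
(`inst/extdata/traits.ini`; `read_traits()` validates positivity,
$m < v_I^{max}$, and the imposed large > small trait ordering). The
numerical table of the source model was not available to this
implementation, so values were transcribed from the surrounding literature
and standard biochemistry, chosen once against laboratory anchors:

* **Y ratios** from molecular composition: protein N:C 0.26, RNA N:P 3.8 and
  C:P 9.5 (per-nucleotide averages), DNA N:C 0.39 and P:C 0.103,
  chlorophyll-a N:C 4/55, thylakoid phospholipid C:P 40, N-storage
  (cyanophycin-like) C:N 2.
* **Allocation coefficients** sized so that structural composition spans the
  observed ranges: maximum growth rates ~1.4 d^-1^ (small) and ~1.9 d^-1^
  (large); N:C from ~0.07 (N-starved, bright) to ~0.22 (replete, dim);
  structural C:P of order 100-300.
* **P storage and uptake**: maximum quotas 0.012 (small) and 0.028 (large)
  mol P (mol C)^-1^ -- picocyanobacteria store little phosphorus, eukaryotes
  (vacuoles, polyphosphate) considerably more; phosphate half-saturations
  0.05 and 0.3 mmol m^-3^, so storage filling discriminates over the
  0.01-1 mmol m^-3^ PO~4~ range found between gyres and upwelling regions.
  A first-cut table with higher caps and much smaller $K_P$ was rejected
  because it implied replete-eukaryote N:P below the minimum observed in
  any cultured phytoplankton and saturated storage at trace PO~4~.
* **Exudation timescale** $\tau^{Exu} = 0.05$ d: overflow excretion is
  fast. Its size controls a small positive bias in steady-state quotas of
  capped elements (the cell holds the excess it has not yet exuded, of
  order $V^{max} \tau^{Exu}$); the paired-culture storage estimator sees
  this bias, which is why its self-consistency test corrects for it
  analytically.

## Numerics

* **Update scheme**: forward Euler on the element-conserving tracers
  (biomass and biomass x quota), so Droop dilution emerges from the
  bookkeeping and closed boxes conserve N, P and Fe to machine precision.
  Mortality uses exact exponential decay over the step; uptake is
  demand-limited (at most 95% of a dissolved pool per step) so
  concentrations cannot go negative.
* **Exudation** is clamped to the available excess per step. This removes
  $\tau^{Exu}$ from the stability bound (the prescribed ceiling
  $0.1\,\tau^{Exu}$ would have forced a 10x smaller step) while leaving the
  continuous fixed point exactly intact for $\mathrm{d}t \le \tau^{Exu}$.
  The effective ceiling is $\mathrm{d}t \le 0.1/\mu$; `step_quota()`
  refuses larger steps. Default $\mathrm{d}t = 0.05$ d.
* **Steady states** (`steady_state()`) are found by enumerating the
  candidate limiting element and solving its scalar balance by bisection,
  then checking Liebig consistency; a damped fixed-point iteration was
  rejected because the limiting-quota map is too steep at low growth. The
  solution matches a long explicit integration to better than 1e-8
  (tested).
* **Ties** in Liebig's minimum break by the fixed priority N, P, C, Fe --
  observationally irrelevant, deterministic for tests.
* **Degenerate inputs**: zero light is a distinct "degenerate light" error
  (infinite chlorophyll demand); quotas at or below the structural minimum
  give zero growth rather than an error; negative storage intermediates are
  floored and flagged; a cell whose non-storage carbon exceeds its budget
  is an explicit infeasibility error.

## The synthetic world

Because no external data are used, the package carries seeded generators
for the two kinds of forcing it needs.

**Culture scenarios** (`make_culture_grid()`, `simulate_culture()`) form a
factorial design over light, target dilution rate and limitation regime,
emulating the structure of steady-state laboratory compilations. The
chemostat emulator inverts the steady-state growth-rate map to find the
medium concentration at which the culture equilibrates at the target
dilution rate. Inter-study scatter can be emulated with multiplicative
lognormal noise on concentrations (off by default; the scatter in real
compilations is inter-study, not process noise).

**The meridional scenario** (`make_meridional_grid()`) is a 20-latitude x
10-depth idealized ocean: surface light $30 + 220\cos^2(\phi)$ µmol m^-2^
s^-1^ attenuated at 0.03 m^-1^; dissolved nutrients restored toward
profiles with a nutricline that is deep (~180 m) under the subtropical
gyres, shallow (~30 m) poleward of 45 degrees and intermediate at the
equator; deep N:P of 16 with 25 mmol m^-3^ NO~3~; a hemispheric asymmetry
knob that depletes northern-gyre PO~4~ targets by 35%; and a
Southern-Ocean (poleward of 45 S) iron supply reduced to 15% of its
background, producing an HNLC analogue. Restoring is slower under the
gyres (40 d vs 10 d), mimicking stratification. Each grid cell is an
independent restoring box -- there is no transport between cells -- run
540 days with the final 180 days averaged, and cells whose biomass still
drifts are flagged rather than silently averaged.

What a green pattern test does and does not establish: the scenario
reproduces the *regime structure* of the zonal-mean ocean (oligotrophic
gyres, nutrient-rich subpolar bands, an HNLC band, a north-south PO~4~
contrast) and the package's pattern checks show that the model's responses
to those regimes have the right sign, ordering and rough magnitude. It
does not validate absolute biomass, the depth of the nutricline, seasonal
dynamics, or any feature that depends on real circulation.

## Diagnostics

* `np_size()` decomposes bulk N:P into the part explained by the size-class
  mixture, $N\!:\!P_{Size} = f_S M_S + (1-f_S) M_L$, and the acclimation
  residual $\delta N\!:\!P$. $M_S$ and $M_L$ are biomass-weighted global
  means over the analysis window and the decomposition identity is exact by
  construction (and checked). Cells carrying less than 0.1% of the biomass
  of the richest cell are excluded: population stoichiometry is undefined
  in empty aphotic cells, and including them swamps the diagnostic with
  noise.
* `coefficient_of_variation()` is the population (n-denominator) standard
  deviation over the mean, applied to per-latitude means -- the definition
  used for the latitudinal-contrast statistic; no sampling correction is
  applied.
* `p_storage_from_pairs()` estimates luxury phosphorus storage from paired
  cultures: each N-limited observation is matched to the P-limited
  observation of the same group with the closest growth rate (default
  tolerance 0.1 d^-1^, configurable since "closest" is not quantified in
  the source procedure); the estimate is the P:C difference, floored at
  zero, summarized per group as median and quartiles.
* `biomass_weighted_histogram()` bins biomass by stoichiometric ratios
  (N:P bin width 1 by default). A bin is "occupied" when it holds at least
  0.1% of the total biomass -- the analogue of visibility in a log-shaded
  trait histogram; the occupied N:C span is insensitive to this threshold
  over 1e-3 to 1e-6.
* `zonal_profiles()` averages over the top 260 m (the standard analysis
  depth), biomass-weighted by default; a volume-weighted mode is provided
  because the source convention is unstated.

## Known limitations

* 0-D boxes and independent water columns: no transport, no seasonality, no
  self-shading; subsurface maxima arise purely from the light-nutrient
  trade-off.
* The detrital closure (single pool per element, first-order
  remineralization at 0.1 d^-1^, no sinking) is a placeholder; the source
  biogeochemistry delegates these to a full ocean model and does not state
  desk-scale values.
* Scalar light: no spectral dependence; the class difference in light
  response is carried entirely by $(v_I^{max}, A_I)$.
* No diazotrophs, no silica, no transporter proteome, single inorganic
  nitrogen pool.
* Eutrophic dominance of the large class is partial (see the mortality
  discussion above).

## Reproducibility

Every generator is a pure function of (config, seed); run manifests record
the package version, seed, config hash and conservation residuals, and
rerunning any driver with the same configuration and seed reproduces its
outputs bit for bit (tested). The acceptance report
(`scripts/acceptance.R`) regenerates the meridional scenario, reruns the
grid and recomputes the modal N:P from scratch at each invocation.
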