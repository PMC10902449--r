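---
title: "Model and methods: tumor metabolism, immune predation, and metaphenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mphenosim)
```

## Overview

`mphenosim` is a hybrid cellular-automaton / reaction–diffusion simulator of
a two-dimensional tumor slice. Three agent roles live on a square lattice of
20 µm sites: tumor and normal cells (at most one cell per site), cytotoxic
T-cells (which migrate through stroma but never share a site with a tumor
cell), and vessels (point sources of oxygen, glucose, and pH buffering that
do not exclude cells). Oxygen, glucose, protons, and an anti-PD-L1 antibody
diffuse between vessels and cells. On top of the agent dynamics, every tumor
cell is scored each step on seven graded *metaphenotype* expressions that
describe how the cell, its neighbors, and its microenvironment jointly evade
immune attack.

This vignette documents the model equations, the design choices made where
the published description left the form open, the calibration of the free
numerical parameters, and what the bundled synthetic experiments do and do
not demonstrate.

## Fields and the quasi-steady-state solver

Cell-scale events (division, death, immune engagement) occur on the scale of
hours to days, while diffusion over a few hundred micrometers equilibrates in
seconds. The fields are therefore re-solved to steady state at every cellular
step (quasi-steady state) rather than co-integrated:

$$D \nabla^2 C - a(x)\,C - V(x)\frac{C}{C + k} + s(x) = 0$$

discretized with the 5-point Laplacian on the 20 µm lattice, zero-flux domain
edges (the tumor is embedded in tissue, with no external reservoir), and
Dirichlet blood values at vessel sites ($O_0 = 0.0556$, $G_0 = 5$ mmol/L,
pH 7.4). The solver is red-black successive over-relaxation (default
$\omega = 1.82$) with the Michaelis–Menten denominator lagged, warm-started
from the previous step's field; convergence is declared when the largest
per-sweep relative change falls below the configured tolerance (default
$3\times10^{-6}$, relative to the field maximum), and non-convergence is an error carrying the residual, never a
silent result. On lattices small enough for a dense direct solve of the same
discretization, the relaxed fields agree with the direct solution to better
than $10^{-6}$ relative error (this is asserted in the test suite).

### Protons and perivascular clearance

Protons are produced by glycolysis, diffuse with $D_H = 1080$ µm²/s, and are
cleared by perfusion and tissue buffering. The published model defers the
exact buffering form to supplementary material, so the package adopts the
simplest formulation with the right spatial structure: a per-site linear
clearance $a(x)\,(H - H_0)$ toward blood pH, with a high rate
(`proton_clearance_peri`, default 0.05 s⁻¹) within `peri_radius` (default 2)
sites of a vessel and a small background rate (`proton_clearance`, default
0.002 s⁻¹) elsewhere. The contrast between the two rates is what makes the
model behave like tissue: perfused regions hold blood pH (clearance shells
sit closer together than the proton diffusion length), while patches that
lose their vessels acidify from cellular production alone. A single uniform
rate cannot do both — calibrating it for healthy-tissue pH leaves avascular
patches too mild to select for acid resistance, and vice versa — which is why
the clearance is spatial. The rates were fixed once so that (i) an isolated
normal cell beside a vessel sits at pH ≈ 7.4 and (ii) intact tissue at the
mean vessel spacing stays well above the normal acid-death threshold
(pH 6.65), and were not revisited afterwards.

Proton production converts glycolytic flux (mmol/L/s) to the molar proton
source via the buffering coefficient $k_H = 2.5\times10^{-4}$ and the
conversion `proton_yield` (default 0.005). The yield and the two clearance
rates jointly set the absolute pH scale; they were calibrated once, by scan,
to four anchors: perfused tissue at the mean vessel spacing holds pH ≥ 7.2;
an isolated normal cell beside a vessel sits at blood pH; an avascular patch
a few hundred micrometers across reaches the published tumor range
(pH 6.4–6.6) from cellular production alone; and the weak-vasculature regime
shows acid-resistance selection without extinguishing its own tumor. A
stronger yield collapses the weak-vasculature tumor (acid and starvation
outpace the evolution of resistance); a weaker one never ignites
acid-mediated invasion at desk scale.

## Cell metabolism and fate

The metabolic closed form follows the precursor family of this model.
Oxygen consumption is Michaelis–Menten,
$f_O = V_O\,O/(O + k_O)$; glucose uptake meets the cell's $p_G$-scaled ATP
demand net of oxidative yield,

$$f_G = \max\!\left(0, \frac{p_G A_0 - \tfrac{27}{5} f_O}{2}\right)
        \frac{G}{G + k_G},$$

with 2 ATP per glucose glycolytically and 27/5 ATP per O₂ oxidatively; ATP
production is $f_A = 2 f_G + \tfrac{27}{5} f_O$ and proton production
$f_H = k_H f_G$. The baseline $A_0$ is defined as $(29/5)V_O$, the ATP rate
of a metabolically normal cell at the oxidative optimum; the realized
blood-condition rate equals $A_0$ up to the glucose half-saturation
correction ($\sim 0.1\%$), so exact equality is asserted only to 1% in
tests. Two consequences matter for the dynamics: hypoxia alone does not
starve a glucose-fed cell (glycolysis compensates, the Pasteur effect), so
ATP-selection acts in the *glucose-poor* margin where high-$p_G$ cells pull
harder on scarce glucose; and acid output rises with $p_G$, so the Warburg
phenotype is also selected through acid-mediated killing of less resistant
neighbors.

Fate gating: a cell is in poor conditions when $f_A/A_0 < A_d = 0.35$ or the
local pH is below its acid-resistance threshold $p_H$; it then dies with
probability $1-(1-p_\Delta)^{dt}$ per step ($p_\Delta = 0.7$/day). Survivors
with $A_d \le f_A/A_0 < A_q = 0.8$ are quiescent (cycle frozen, consumption
unchanged — the model keeps quiescent metabolism at full rate, a deliberate
simplification). Proliferating cells advance their division clock by
$dt\cdot\min(f_A/A_0, 1)$: the cap encodes that $\tau_{min} = 0.95$ days is
a *minimum* cycle time that surplus ATP cannot shorten. At $D \le 0$ the
cell divides into a uniformly chosen empty Moore site (contact inhibition:
with no empty site it stalls at the gate), both cells reset to
$T_m = \tau_{min}$, and each daughter trait independently drifts by
$\pm\Delta$ or 0 with equal probability, clamped to its admissible range
($p_G \in [1, 50]$, $p_H \in [6.1, 6.65]$, $p_P \in [2.7, 5]$). The
published table labels $p_{P,min} = 5$ the "maximal PD-L1 phenotype"; the
package follows the table's value and treats larger $p_P$ as more PD-L1,
reading the "min" subscript as a naming artifact.

Death routing: tumor cells dying of metabolic/acid causes become necrotic
debris that occupies the site and turns over at $p_n = 5\times10^{-4}$/day
(effectively permanent on simulated horizons, producing the necrotic core);
T-cell kills clear the site immediately (cytotoxic clearance); normal-tissue
deaths — baseline turnover at $p_D$ and acid/ATP lysis — free the site. The
last choice matters: if acid-killed normal tissue left permanent debris,
acid-mediated invasion (the mechanism the mixed-vs-shell demonstration
isolates) would be blocked by a wall of its own casualties. Normal cells
occupy all non-tumor, non-vessel sites initially and consume at $p_G = 1$.

**Normal tissue is homeostatic.** A normal cell with an empty Moore neighbor
re-fills it at `normal_regrowth` = 0.1/day, so baseline turnover ($p_D$)
maintains a ~2% steady-state vacancy instead of slowly evaporating the
tissue. Without regrowth, half the tissue is gone by day 150 and every tumor
— in every vascular regime — simply grows into the vacancies at the same
rate, drowning out both acid-mediated invasion and the vascular-regime
contrast. With regrowth, a tumor must clear tissue (by acid, or via immune
and metabolic attrition) or out-compete it for vacancies, which is the
competition the model is about. Tumor cells divide an order of magnitude
faster than the regrowth rate, so the tumor still wins adjacent vacancies.

## Vasculature

Vessels are a hard-core point process: initial placement accepts uniform
candidates at least $\sigma_{min} = 80$ µm from accepted vessels, targeting
one vessel per $\sigma_{mean}^2 = (150\ \mu m)^2$. Each vessel draws an
exponential lifetime with mean $\nu_{mean}$ (vessel stability) at creation.
Two readings in the published description were left open and were resolved
by implementation:

* **Collapse is tumor-conditioned.** The lifetime clock advances only while
  a tumor cell is within the vessel's Moore neighborhood. Tumor-associated
  vasculature is unstable; undisturbed normal tissue is homeostatic. With
  domain-wide collapse, the entire tissue — including distant normal tissue —
  becomes avascular within a few lifetimes and starves, which contradicts
  the large invasive tumors the weak-vasculature regime is supposed to
  produce.
* **Renewal is a global rate.** While hypoxia persists (sites with
  $O < k_O$), new vessels sprout as a Poisson process with rate `p_ang` per
  day, each candidate at a uniformly chosen hypoxic site, accepted only if
  it keeps $\sigma_{min}$ spacing. A per-hypoxic-site probability reading is
  degenerate: with hundreds of hypoxic sites, any appreciable rate refills
  every vascular hole within a day and the hard-core spacing — not the
  renewal parameter — sets the equilibrium, erasing the stability/renewal
  gradient entirely.

Under these rules, "weak vasculature" ($\nu_{mean} = 20$, $p_{ang} = 0.1$)
develops a chronically avascular, acidic tumor core, while "intermittent
hypoxia" ($\nu_{mean} = 20$, $p_{ang} = 0.9$) keeps the core marginally
supplied through rapid re-sprouting.

## T-cells

T-cells are recruited after a delay $\tau_T = 4$ days as
$\mathrm{Poisson}(\alpha_T\, n_{tumor}\, dt)$ per step, entering at free
vessel sites (excess recruits are deferred, never dropped). Free T-cells die
at the glucose-scaled baseline rate
$(1/\beta_T)\,\frac{1 - S(g)/100}{1 - L_i/100}$ — exactly $1/\beta_T$ at
blood glucose and ≈ 2.26× that as glucose vanishes. $S(g)$ is the log-linear
survival curve through the published anchors ($S(G_0) = 65.35$%, floor
21.78%, slope −16.67% per decade). The death *scaling* formulation (rather
than an independent per-day Bernoulli on $1 - S/100$) reflects that the
survival percentages were measured over a fixed assay window; used raw they
would extinguish T-cells within days even at blood glucose.

Each step a non-engaged T-cell moves with probability $T_M = 1$ to a
uniformly chosen Moore site not occupied by a tumor cell or another T-cell
(stroma does not block migration — if it did, tissue-embedded T-cells could
never leave their entry vessel). On contact with a tumor neighbor the cell
first tests acid inactivation, $P_{AI}(pH) = 1/(1 + e^{\sigma_p (pH - H_p)})$
(half-max 6.6, steepness 6); inactivated cells permanently lose effector
function (a config flag makes this reversible, reflecting experimental
evidence that low-pH-rescued cells can recover) but keep moving and
stamping interactions. Otherwise the T-cell engages a uniformly chosen
adjacent tumor cell and is immobilized for
$d_e (1 + 1/(1 + e^{\sigma_e (pH - H_e)}))$ days — $d_e$ at physiological
pH, up to $2 d_e$ in deep acid — after which it kills with probability
$P_k = \mathrm{clamp}(1 - p_{P,\mathit{eff}}/5,\ 0,\ 1)$ and disengages.
These four response curves hit every published anchor (half-maxes,
steepnesses, endpoint survivals) but interpolate with logistic/log-linear
shapes of the package's choosing; they are injected as plain functions so an
alternative form can be swapped in.

## The interaction grid and metaphenotypes

A per-site clock $T(x,y)$ records the last time any T-cell (free, engaged,
or inactivated — blocked attacks count as survived interactions) traversed
the site's Moore neighborhood; the interaction indicator is
$I = 1$ iff $T \ge t - T_w$. $T_w$ has no published value; the default is 1
day ("recent" on the cell-decision timescale) and is configurable.

Per tumor cell the seven expressions are computed exactly as defined:
MP1 $= 1 - I$ (Immune Desert); MP2 $= (1-P_k)\,I$ (PD-L1 Attack);
MP3 $= P_k (1-I) \max_j \mathrm{PDL1}_j$ over the 8 Moore neighbors with
neighbor PD-L1 normalized by the maximal expression (Mooch PD-L1);
MP4 $= P_{AI}\,\bar p_R\, I$ (Self-Acidify);
MP5 $= P_{AI} (1-\bar p_R)\, I$ (Mooch Acid);
MP6 $= (1 - D/T_m)\, I$ (Proliferate Fast); and MP7 $= P_g\, I$ with
$P_g = 1 - S(g)/100$ (Starve Glucose). $\bar p_R$ is the cell's proton
output normalized by the calibrated buffering capability of a vessel and
clamped to $[0,1]$. Note the printed $(1-I)$ factor in MP3: it makes Mooch
PD-L1 the one expression available to never-contacted cells, in tension with
the prose convention that all non-desert metaphenotypes require a recent
interaction; the package implements the equations as printed and leaves the
tension to the user-facing documentation rather than resolving it silently.

**Calibration of $\bar p_R$.** The vessel buffering capacity is found once
per configuration by bisection: a lone cell is placed beside a single vessel
on a quiet lattice and its glycolytic phenotype is raised until its own
steady-state pH first drops below $H_p = 6.6$. Inside the perivascular
clearance shell no admissible phenotype (up to $p_G = 50$) achieves this —
single cells cannot overwhelm a vessel, acidification is collective, which
is precisely the group-effect the mixed-vs-shell demonstration shows — so
the calibration falls back to the production of the maximal phenotype. The
normalization then spans $[0,1]$ over the admissible range: a maximal
Warburg cell scores as fully self-acidifying, a metabolically normal cell
as almost fully mooching.

For map overlays the package also exports a *non-canonical* convenience
score, `immune_susceptibility(pH, p_P_eff)` — the probability that an
approaching T-cell both escapes acid inactivation and succeeds in its kill.
It is a display layer, not one of the seven expressions.

## Desk-scale immune response

T-cell recruitment is proportional to tumor burden ($\alpha_T\,n_{tumor}$
per day). The published response-rate levels (medium $10^{-3}$, high
$10^{-2}$) are calibrated against tumor burdens of order $10^4$ cells;
desk-scale tumors carry of order $10^2$, so those rates deliver less than
one T-cell per day and predation cannot register at all. The bundled
experiments therefore preserve the *absolute influx regime* rather than the
printed coefficient: the effective-predation arm uses $\alpha_T = 10^{-1}$
(the top of the published range), delivering ~10 recruits/day against a
~100–300-cell tumor, the same T-cell-to-tumor ratio regime the published
medium/high arms produce at scale. The no-immune arm stays $\alpha_T = 0$.

Similarly, end-of-run metaphenotype comparisons between treatment arms are
taken at the *end of the treatment window* and as expression *fractions*
(Immune Desert excluded): desk-scale runs are too short for a
post-treatment selection legacy to persist once the drug or buffer washes
out, and raw expression masses confound composition with tumor size.

## Treatments

* **Anti-PD-L1**: a diffusible antibody ($D_A = 100$ µm²/s) held at the
  source concentration at vessel sites during the treatment window and
  solved to its quasi-steady profile; outside the window the field decays
  exponentially at $\gamma_A$. The published table prints the decay rates in
  s⁻¹; taken literally the drug's diffusion length would be 14 µm (it could
  never leave a vessel site) and bound PD-L1 would unbind within minutes,
  so the package interprets $\gamma_A = 0.5$ and $\gamma_P = 0.001$ as per
  day. Cellular bound PD-L1 relaxes toward the saturating occupancy target
  $p_P A/(A + K_A)$ at a fast binding rate while drug is present and decays
  at $\gamma_P$ without it; the effective expression $p_P - b$ feeds the
  kill probability. $K_A$ and the source concentration are not published;
  the defaults (source 1, $K_A = 0.1$, binding rate 100/day) were chosen
  once so that sustained treatment drives effective PD-L1 below 10% of its
  phenotype value within a few days.
* **Buffer**: a systemic level $B(t) \in [0,1]$ (default 0.8 inside the
  window — no published level exists, so the value is exposed and recorded
  in all outputs) scaling every cell's proton source by $(1-B)$.

The default window is days 100–160 with observation to day 300; the
experiment harness runs untreated / anti-PD-L1 / buffer / combination from
one configuration on shared seeds, so arm comparisons use common random
numbers and identical pre-treatment trajectories.

## Update loop and determinism

Each step (default $dt = 1/24$ day, constrained to be at most the
engagement duration so engagements resolve on the step grid): solve fields →
metabolize, fate, divide (simultaneous conflict resolution with random
priorities, which avoids lattice sweep bias) → necrotic turnover → vessel
collapse/renewal → T-cell recruit/step → drug binding → interaction grid and
recording. All randomness draws from the single seeded R stream; identical
configuration and seed reproduce results exactly (`identical()` on the full
result object), and configurations round-trip through YAML bit-exactly.

## Tumor size: viable area and lesion area

The recorded time series carries two size measures. `tumor_area_mm2` counts
viable tumor cells times the site area (the bookkeeping identity the result
object guarantees). `lesion_area_mm2` adds the necrotic core. The regime
comparisons use lesion area for "tumor size": the weak-vasculature regime
grows by acid-mediated invasion while its avascular core necroses, so the
viable count nets rim gains against core losses and ends up measuring core
survival rather than growth; gross lesion area is what a caliper or image
would report. Both series are always recorded, so either convention can be
plotted.

## What the synthetic experiments show — and what they do not

The bundled experiments run at desk scale, with problem sizes chosen once:
the vascular-regime comparison and the mixed/shell demonstration on 60×60
lattices (1.44 mm²) at 150 and 30 days; immune-predation experiments on
48×48 at 80–100 days; the treatment factorial on 40×40 at 60 days with the
window over days 20–60; five paired seeds per comparison throughout. The
harness accepts larger grids, longer horizons, and more replicates
unchanged. At this scale the simulations demonstrate *orderings* —
shell beats mixed seeding, weak vasculature out-selects intermittent
hypoxia, combination therapy beats monotherapy — under common random
numbers, not effect sizes, and the phenotype transformation is partial:
with $\Delta_G = 0.15$ per division, reaching a deeply Warburg state takes
many hundreds of selected generations, so desk-scale means are far from the
$p_G = 50$ ceiling. The generator also idealizes real tissue: no stromal
mechanics or cell pushing, no directed T-cell chemotaxis, no Tregs or
suppressive cytokines, no alternative fuels (glutamine, lactate), 2-D
geometry, and vessels as points without flow. Passing tests therefore show
that the implemented mechanisms interact as the model intends under the
stated conditions — not that the parameterization is predictive for any
real tumor.

## Numerical choices and degenerate inputs

* Negative concentrations are clamped to zero inside the relaxation sweep
  and consumption vanishes at zero concentration, so the clamp is a safety,
  not a model term.
* Division and movement conflicts resolve by random priority; losers retry
  the next step (a divider whose chosen site is taken stalls at the gate).
* A zero-duration run returns exactly the initial state; a grid too small to
  host the requested tumor fixture fails loudly; recruits with no available
  vessel entry are deferred with a counter, never silently dropped.
* Times are anchored to the step grid (`t = i * dt`) to avoid accumulated
  floating-point drift in recorded time stamps.
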