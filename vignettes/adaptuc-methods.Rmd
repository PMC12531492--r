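---
title: "Designing ALE starting strains: model, reformulation, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing ALE starting strains: model, reformulation, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The design problem

A host strain is to be evolved toward assimilating an *unadapted carbon
source* (UC) — a substrate it cannot natively grow on, such as methanol for
*E. coli* — with a natively utilisable *cosubstrate* keeping it viable
during adaptive laboratory evolution (ALE).  `adaptuc` searches for
reaction-knockout sets in a genome-scale metabolic model that create a
selective pressure for UC uptake while guaranteeing the starting strain's
viability.

All growth phenotypes are evaluated with flux balance analysis: maximise
the biomass flux subject to steady state, `S v = 0`, and flux bounds.  A
knockout forces a reaction's bounds to zero.  The convention throughout is
that exchange flux is negative for uptake, and all user-facing uptake
rates are magnitudes in mmol/gDW/h (the biomass flux is in 1/h).

Three inner FBA problems, sharing one knockout pattern, encode the
requirements on the design:

1. *Growth on the UC alone* (UC open at the uptake bound, cosubstrate
   closed).  Variant A demands the knockout strain's maximal growth stay at
   or below 10 % of the reference (pre-deletion) UC-only growth — the
   strain must need the cosubstrate.  Variant B instead demands at least
   50 % retained — the strain keeps the potential to live on the UC alone.
2. *Dependence*: maximal growth on the cosubstrate alone at most 10 % of
   the reference cosubstrate growth.
3. *Recovery*: maximal growth with both substrates at least the reference
   cosubstrate growth.

Both fractions (and all bounds) are `design_config()` parameters; the
defaults are the conventional 90 %-reduction / 50 %-retention thresholds
and a substrate uptake bound of 10 mmol/gDW/h.

Designs are ranked by the substrate assimilation driving force

$$\overline{\mathrm{SADF}} \;=\; \frac{v^{0}_{bio,cosub} - v^{2}_{bio}}{v^{UC}}
\qquad [\mathrm{gDW/mmol}],$$

where $v^{2}_{bio}$ is the knockout strain's maximal growth on the
cosubstrate alone and $v^{UC}$ the minimal UC uptake that restores growth
to the reference cosubstrate level (UC bound widened to 1000 mmol/gDW/h for
this recovery problem so the minimum is never clipped).  The units work
out because a growth rate (1/h) divided by an uptake rate (mmol/gDW/h)
is gDW/mmol.  A second score, UC/Co, is computed by a two-step LP: minimise
UC uptake subject to growth ≥ 0.1 1/h, then fix that minimum and minimise
the cosubstrate uptake; the ratio of the two minima measures how
parsimoniously the starting strain can use the new substrate.  Zero UC
requirement gives UC/Co = 0; a zero cosubstrate minimum is reported as an
infinite-coupling sentinel rather than a number.

## Single-level MILP reformulation

The bilevel program (outer: binary knockouts `y`, maximise SADF; inner:
the FBA optimisations above) is collapsed into one MILP using the weakest
certificate that suffices for each inner problem:

* *inner max ≥ b* (variant B requirement 1; requirement 3): a primal
  witness — one feasible flux vector reaching `b` — is enough.
* *inner max ≤ b* (variant A requirement 1): a dual-feasible point of the
  inner LP whose dual objective is ≤ `b`; by weak duality this bounds the
  inner maximum without any complementarity constraints.
* requirement 2's value $v^{2}_{bio}$ *enters the objective*, so its block
  carries a strong-duality certificate (primal objective ≥ dual objective
  alongside primal and dual feasibility), pinning it at the exact inner
  maximum.

The fractional objective is linearised by the Charnes–Cooper substitution
$t = 1/v^{UC}$: the minimal-uptake problem's flux block is scaled by $t$,
normalised by $-g^\top (t v^4) = 1$ (the scaled UC uptake is exactly one),
and the objective becomes the linear
$v^{0}_{bio,cosub}\, t - c^\top (t v^2)$.  Because $t$ is maximised and any
feasible scaled witness corresponds to an achievable uptake $1/t$, primal
feasibility alone pins $v^{UC}$ at its true minimum — the minimal-uptake
block therefore needs no dual certificate, which removes one block of
big-M products.  Requirement 2 guarantees the numerator is positive, so
the pressure on $t$ is always upward and the argument is airtight.

Products of binaries with continuous variables are linearised with
envelopes: `tau = t*y` uses the bounds `t in [1/1000, 1/eps_uc]`, and the
dual products `mu*y` use *t-proportional* envelopes (`a <= M tau`,
`a >= mu - M(t - tau)`, with the scaled dual capped by `mu <= M t`).  This
keeps every big constant of the order of `M*t` at the optimum rather than
`M*t_max`, which matters numerically (below).  The knockout budget is
`sum(y) <= K` with K the user-facing maximal knockout count (default 5).

Alternative designs are produced by iteratively re-solving with an
*integer cut* over each found set S: `sum(y_j, j in S) <= |S| - 1`, which
excludes S and all its supersets.  A literal strict-inequality reading of
the cut (≤ |S| − 2) would be infeasible for singleton sets and would
terminate enumeration after any one-deletion design, so the
superset-excluding form is the default; the exact no-good cut (excluding
only S itself, allowing supersets to surface later) is available via
`exclude_supersets = FALSE` and is the right choice when the enumeration
pool is meant to cover the whole design space, e.g. in the
enumerate-then-score fallback mode (`build_milp(mode = "feasibility")`),
where a feasibility MILP minimising the knockout count is paired with
exact LP scoring of every enumerated set.

## Numerical choices

* LP/MILP solving: HiGHS (through scipy), single-threaded and
  deterministic; relative MIP gap 1e-4; primal/dual/integrality
  feasibility tolerances tightened to 1e-9.  The tightening is not
  cosmetic: with the default 1e-6 integrality tolerance a binary can sit
  at ~1e-6, and multiplied by a 1e7 big-M constant that admits order-one
  violations of the duality certificates, silently inflating the
  objective.
* Bound tightening: before building the MILP all flux bounds are
  intersected with wild-type flux-variability ranges under the widest
  medium (`fva_tighten = TRUE`).  Knockouts only shrink the flux cone, so
  these ranges are valid for every knockout pattern, and small bounds keep
  every big-M envelope small.
* Big-M values: dual variables are capped at `M_dual = 1000`
  (configurable); the scaling variable lives in `t in [1/1000, 1/eps_uc]`
  with `eps_uc = 1e-3` — i.e. minimal UC uptakes down to 0.001 mmol/gDW/h
  are representable, two orders below any value the toy family or the
  genome-scale strategies produce.  If any dual variable or `t` finishes
  within 0.1 % of its cap, the solution is flagged and the MILP is rebuilt
  with a tenfold larger cap.
* Verification as a first-class safeguard: every MILP incumbent is
  re-scored by direct FBA (`sadf()`, `check_requirements()`), entirely
  independent of the MILP certificates.  A solution is only `verified`
  when all three requirements re-pass and the MILP objective agrees with
  the direct score within 1e-3 relative.  If an optimal incumbent's
  claimed objective *exceeds* its direct score (the signature of an eroded
  certificate), `solve_design()` excludes exactly that knockout pattern
  with a no-good cut and re-solves; since a pattern's claimed value can
  never understate its exact score, eliminating corrupted incumbents
  preserves global optimality.
* Degenerate optima: objective values are the contract everywhere; flux
  vectors are solver-dependent under degeneracy, so any operation that
  reports a flux distribution offers a parsimonious (total-flux-
  minimising) refit and flags it.  Printed carbon-split percentages of a
  specific optimal flux pattern are descriptive, not contractual.
* Requirement flags use an absolute tolerance of 1e-6 on growth-rate
  comparisons; steady-state residuals of accepted FBA solutions are
  checked against 1e-6.
* `v2bio` used in scoring is always recomputed by direct FBA rather than
  read out of a MILP certificate, so scores are independent of the
  reformulation.

## Model preprocessing

`apply_preprocessing()` encodes the aerobic-use conventions for the two
case-study organisms: the *E. coli* profile deactivates the
anaerobic-only formate lyases (`PFL`, `OBTFL`) and two reactions widely
considered unrealistic (`DRPA`, `PAI2T`); the *C. glutamicum* profile adds
a xylose transport (plus exchange if missing).  Both then restrict
carbon fixation: every internal reaction able to consume CO2/HCO3 outside
a whitelist of genuine carboxylases (PEP carboxylase, carbamate kinase,
isocitrate dehydrogenase, carbamoyl-phosphate synthase, pyruvate
carboxylase, acetyl-CoA carboxylase, methylmalonate-semialdehyde
dehydrogenase) has its *fixing direction* blocked.  Blocking only the
direction, rather than the whole reaction, was a deliberate choice:
deactivating a reversible reaction outright would also remove essential
decarboxylations running the other way.  Missing targets are warnings,
never errors, so one profile works across model versions.

The RuMP insertion (`rump_pathway()`) writes the methanol dehydrogenase as
NAD-dependent by default; the literature is divided between NAD- and
PQQ-dependent enzymes, so the cofactor is a parameter (`"pqq"` writes the
oxidation cofactor-free, since PQQ chemistry is normally absent from host
models).  The growth medium is handled by `set_medium()`: listed exchanges
open at given uptake bounds, every other *carbon* exchange closed (carbon
detection by chemical formula; an exchange without a formula is
conservatively treated as carbon), and non-carbon components (O2, ions)
left at the source model's defaults — genome reconstructions ship a
sensible mineral medium, and second-guessing it would be less reproducible
than inheriting it.

Biomass-precursor producibility opens only the cosubstrate, adds a unit
demand for each biomass substrate-side metabolite, and calls the precursor
producible when the demand can carry at least 1e-4 flux (guarding against
numerically trivial leak fluxes).  Mass fractions are stoichiometric
coefficient × molar mass (from formulas; coefficient-weight basis with a
warning when formulas are missing).  The coupling classes are: *full*
when no precursor is producible, *minimal* when the coupled mass fraction
is at most 10 %, *intermediate* otherwise; the 10 % boundary is our
choice of a round threshold separating cell-envelope-only coupling
(~5 % of biomass) from multi-precursor coupling.

## The toy family and what it does (not) show

`make_toy()` builds the smallest network exhibiting the coupling
phenomenon: cosubstrate A feeds precursor P directly and precursor Q
either directly (`rQ1`) or through a 1:1 condensation with the UC M
(`rQ2: A + M -> 2Q` — the RuMP motif, where formaldehyde condenses 1:1
with ribulose-5-phosphate).  Biomass consumes `(1-phi) P + phi Q`; all
metabolites have equal molar mass, and the uptake-to-growth yield is 1.
Deleting `rQ1` therefore gives, in closed form: `v2bio = 0`,
`vUC(g) = phi*g/2`, `SADF = 2/phi`, `UC/Co = phi/(2-phi)`, and a coupling
fraction of exactly `phi`.  The family is parameterised further by a
UC-to-cosubstrate conversion route (making variant B non-trivial), an
inefficient leak route to Q with stoichiometric cost `c_leak` (making
requirement 2 quantitative rather than structural; the generator refuses
costs that would break its own analytic pass/fail claim), serial or
parallel duplications of the Q route (making enumeration and budget
effects testable), and seeded decoy reactions (blocked or
gene-unassociated) that a sound prefilter must remove and a sound
optimiser must never select.

These toys give exact oracles — every metric has a hand-derivable value,
and `brute_force_designs()` exhaustively enumerates all knockout subsets
(memoising on the blocked-reaction-collapsed effective set) as an
independent check of the MILP.  What passing them does *not* show:
behaviour under the thousandfold larger and highly degenerate flux spaces
of genome-scale models (cofactor balancing, redundant isozymes, GPR
structure), realistic biomass compositions, or thermodynamic/kinetic
limits.  The genome-scale scripts exist precisely to close that gap where
model downloads are possible.

## Problem sizes in the shipped tests

The test suite runs entirely on generated toys: networks of 6–12
reactions, candidate sets up to ~10, knockout budgets K ≤ 3, twenty seeded
random configurations for the MILP-vs-oracle equivalence, and a
five-point coupling-fraction grid for the closed forms.  These sizes keep
the full suite under a minute of solver time while exercising every code
path; the same functions scale to genome reconstructions (the MILP builder
and FBA layer are sparse throughout), where a single design solve is
minutes rather than milliseconds.

## Known limitations

* Knockouts are reaction-level; gene-level (GPR-resolved) deletions are
  out of scope, and gene associations are only tracked as presence and
  token sets (including through SBML round trips).
* The MILP requires finite flux bounds (standard in published
  reconstructions; ±1000 convention).
* Thermodynamic and enzyme-capacity constraints are not modelled; an FBA
  optimum can overstate achievable phenotypes.
* The infinite-coupling sentinel of UC/Co and the `NA` statuses of
  `sadf()` deliberately refuse to coerce degenerate designs onto a
  numeric scale; downstream tabulations must handle them.
* SBML support targets the FBC-v2 subset used by constraint-based models;
  kinetic SBML constructs are ignored.
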