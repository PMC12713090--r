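---
title: "Enforced-objective flux scanning for overproduction target prediction"
author: "fluxscan"
output: rmarkdown::html_document
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Spinosad — an insecticidal mixture of the macrolides spinosyn A (~85%) and
spinosyn D (~15%) produced by *Saccharopolyspora spinosa* — is assembled
from central-carbon precursors: a polyketide aglycone built from
acetyl-/propionyl-CoA starters with malonyl-CoA and methylmalonyl-CoA
extenders, decorated with TDP-L-rhamnose (genes *gtt*, *gdh*, *epi*,
*kre*) and TDP-D-forosamine. Deciding which genes to overexpress or
attenuate in such a network is a systems question: precursor pools are
shared with growth and with competing pathways.

`fluxscan` treats the question with constraint-based analysis. A
genome-scale metabolic model (GEM) is a stoichiometric matrix $S$, flux
bounds $l \le v \le u$, gene–reaction rules, and a biomass pseudo-reaction.
Flux balance analysis (FBA) solves

$$\max_v \; c^\top v \quad \text{s.t.}\quad S v = 0,\; l \le v \le u,$$

and parsimonious FBA (pFBA) breaks the usual degeneracy of that optimum by
additionally minimizing total absolute flux $\sum_r |v_r|$ at the fixed
objective value, implemented the standard way by splitting every
reversible reaction into non-negative forward/backward halves.

## The scan

The target-prediction procedure is a modified FSEOF (flux scanning based
on enforced objective flux) run "backwards" through growth:

1. Compute the theoretical maximum biomass flux $\mu^{\max}$.
2. For each fraction $f \in \{0.2, 0.3, \dots, 0.8\}$ (the default grid;
   the range endpoints are part of the procedure, the 10% step is the
   smallest round grid spanning them and is configurable): pin biomass at
   $f\,\mu^{\max}$, maximize the production target, pin the target at that
   per-level optimum, and take the pFBA distribution.
3. The control is pure growth: biomass maximized, production left at its
   unenforced optimum (zero), with pFBA applied at the pinned maximum for
   comparability with the levels (a deliberate choice; the procedure is
   usually described without stating it).

The score of reaction $A$ is the ratio of its production-regime flux to
its pure-growth flux,

$$s_A = \frac{\left|\overline{v_A^{\,\text{prod}}}\right|}{\left|v_A^{\,\text{ctrl}}\right|},$$

with the production-regime flux aggregated as the signed mean over the
enforced levels (the `mean_flux` default; averaging per-level ratios
instead is available as `mean_ratio` — the two coincide whenever the
control flux is a constant, and mean-of-flux is the more robust choice
when the control flux is small). A score above 1 means the reaction works
harder when production is enforced — an overexpression candidate; below 1,
an attenuation candidate.

Three boundary cases are resolved explicitly, because a ratio does not
define them:

* **ACTIVATED** — zero control flux but production-regime flux above
  `activation_epsilon` (default 1e-6). This is the fate of every
  heterologous pathway reaction, and such reactions head the up-list,
  ranked by mean production flux.
* **Direction flips** — control and production fluxes of opposite sign get
  no call (the ratio's sign semantics are undefined); they are flagged and
  excluded.
* **Inactive** — both regimes below epsilon: score 0, excluded.

Classification applies a dead-band $\delta$ (default 0.05) around score 1
to suppress numerical neutrals: up is `ACTIVATED` $\cup\, \{s > 1+\delta\}$,
down is $\{0 < s < 1-\delta\}$ with nonzero control flux. The biomass
reaction (its score is $\overline{f} = 0.5$ by construction on the default
grid — a useful closed-form self-check), the scan target, and exchange
pseudo-reactions are never listed as targets; reactions without gene
rules can be excluded with `gene_only` when predictions must be
actionable. Gene scores inherit the extremal reaction score through the
gene rules (maximum for the up direction, `ACTIVATED` dominating; minimum
for down) — the gene-level aggregation is not uniquely determined by the
procedure's description, so the extremal rule is a documented choice.

```{r}
library(fluxscan)
host <- make_host_toy()
model <- graft_module(host, build_spinosad_module("branch"),
                      toy_host_mapping())
scan <- run_scan(model, scan_config("BIOMASS", "DM_spinosynA"))
targets <- classify_targets(score_reactions(scan), model)
```

## Grafting heterologous chemistry

`build_spinosad_module()` encodes the biosynthetic route (aglycone
assembly, the four-step rhamnose branch, a lumped forosamine branch,
attachment and tailoring, demands for spinosyn A, D, and the 0.85:0.15
blend). The pathway topology fixes which branches are obligatory — that is
what the structural tests assert — but the cofactant coefficients (NADPH
per aglycone, SAM per tailoring step) are not uniquely determined at this
lumping; they are documented defaults carried in the module notes and
overridable where exposed.

`build_ncm_module()` encodes the non-carboxylative malonyl-CoA route:
pyruvate → 3-oxopropanoate (BauA) → malonyl-CoA (MCR-C). Its defining
constraints are structural and tested as such: no CO2 release, no ATP
consumption, carbon-conserving (C3 in, C3 delivered). Pyruvate and
3-oxopropanoate share the formula C3H3O3, so the BauA step is elementally
an isomerization at this lumping; MCR-C is written oxidatively with NADP+
as the documented electron acceptor.

`graft_module()` resolves the module's currency species onto host
metabolites through an explicit mapping — silent name-matching across GEM
dialects is the classic failure mode, so the mapping is always an
argument. A mapping entry may be `NA`, meaning the species is dropped as
freely buffered; the shipped `toy_host_mapping()` documents every such
choice (CoA, SAM/SAH, ammonium, water, protons, pyrophosphate are not
tracked by the desk-scale host; the TDP carrier is charged to the
adenylate pool).

Interventions mirror the engineering strategies: `amplify` multiplies
bounds (extra copies / stronger promoters), `knockout` zeroes them,
`add_module` grafts, and `enable_degradation` opens a previously closed
degradation reaction. The last is a static approximation: TAG degradation
is a dynamic, late-growth-phase strategy, while FBA is steady-state, so
the intervention can only show what a permanently open degradation route
does — on the shipped host, a storage cycle closed at steady state, its
delta is zero, and no stronger claim is made.

## The synthetic test bed

Real GEMs have no ground truth, so correctness is established on toys:

* **Linear toy (T1)** — 4 reactions; every fact has a closed form
  (max biomass 10, envelope $10(1-f)$, uptake score exactly 1, biomass
  score exactly $\overline f$, product branch ACTIVATED).
* **Redundant toy (T3)** — two parallel routes of length 1 and 2; plain
  FBA is degenerate between them, total flux is $30 + 2t$ in the detour
  flux $t$, so pFBA must choose the short route exactly.
* **Branched family (T2)** — seeded generator (a pure function of its
  spec) emulating what the scan assumes: one glucose uptake, a core chain
  with a redundant bypass (exercising pFBA), a sugar branch, a capped
  precursor supply feeding both a two-step product module and growth-only
  competing branches. The cap is drawn log-uniformly *between* the
  pure-growth demand (×1.1, so the score clears the dead-band) and the
  per-level production need (so it binds at every level) — the planted
  bottleneck is therefore classifiable by construction, which is what a
  recovery test needs; background bounds are drawn log-uniformly above any
  attainable flux so only the planted cap binds.

What the toys do not emulate: genome-scale redundancy (thousands of
alternate routes), cofactor-swap degeneracy, blocked subnetworks, and
numerically awkward biomass coefficients. Passing here shows the
procedure and its implementation are correct, not that target predictions
on a real GEM are biologically right.

* **Independent oracle** — the scan is recomputed end-to-end in Python
  (dense numpy matrices, `scipy.optimize.linprog` with the HiGHS backend)
  over a fine fraction grid (step 0.01), and scores must agree with the
  main path within 1e-6. Two solvers, two languages, one procedure.

## Numerical choices

* **The LP solver** is a dense two-phase primal simplex with Bland's rule,
  written in-package. Bland's rule makes it cycle-free and fully
  deterministic (fixed variable order, no presolve randomness) — scores
  are flux ratios and must not wobble between runs, so determinism is a
  contract, not a convenience. Variables whose bound interval is a point
  are eliminated before solving; infinite bounds are boxed at ±1e6 and a
  solution pressing such a box with nonzero objective weight is reported
  `unbounded`. The dense tableau targets desk-scale models (tens of
  reactions); a genome-scale run wants an external LP backend and is the
  main scale limitation.
* **Pinning** a flux to a value uses the interval
  $v \pm 10^{-9}\max(1, |v|)$ — strict equality is numerically brittle
  when the pinned value is itself an LP optimum.
* **Feasibility contracts**: every optimal distribution satisfies
  $\|S v\|_\infty \le 10^{-6}$ and bound feasibility; the suite asserts
  this on all solutions it touches.
* **Degenerate alternate optima**: pFBA plus a deterministic solver pins
  the reported distribution; the toy family is additionally constructed so
  the pFBA optimum is unique (routes of distinct length, continuous random
  bounds), which is what makes 1e-6 oracle agreement a fair test.
* **Equality tolerance** for model round-trips is 1e-9 on coefficients and
  bounds.

## Scope and limitations

* Scores carry no statistical significance; the procedure is a ranking
  heuristic over LP solutions.
* No MILP-based design (OptKnock-style bilevel searches), no flux
  sampling, no thermodynamic or enzyme-capacity constraints.
* The deposited genome-scale model for the organism is an external input:
  `read_model()` ingests any FBC-valid SBML and `analysis/05_deposited_model.R`
  shows the full-scale run, but the package does not redistribute the
  model, and the bundled solver is not sized for it.
* Elemental validation checks only reactions whose species all carry
  formulas, and exempts exchanges, biomass, and sink/demand
  pseudo-reactions; charge balance is not checked.
* The problem sizes used throughout (a 30-reaction grafted host, 50 seeded
  toy instances, a 0.01 oracle grid) are the package's desk-scale study
  conditions, chosen so every claim is verifiable by enumeration or
  closed form.
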