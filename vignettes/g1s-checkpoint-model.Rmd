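---
title: "A Boolean model of the lncRNA-miR-34a axis at the NSCLC G1/S checkpoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Boolean model of the lncRNA-miR-34a axis at the NSCLC G1/S checkpoint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g1sbn)
```

## The biological question

Non-small cell lung cancer (NSCLC) cells over-express the long
non-coding RNAs ANRIL and UFC1. Both act as molecular sponges for
miR-34a, a tumour-suppressor microRNA that is itself induced by the
DNA-damage response (DDR) through ATM and p53. Active miR-34a silences
a panel of proliferation and survival factors -- Myc, HDAC1, Sirt-1,
E2F1, Cdc25A, BCL2 and the two G1/S cyclin-CDK complexes -- and
thereby tips a damaged cell away from proliferation and towards p21-
mediated senescence or caspase-mediated apoptosis. Because E2F1 and
Myc are simultaneously (i) targets of miR-34a and (ii) transcriptional
drivers of ANRIL and UFC1, the sponge axis closes three positive
feedback circuits (miR-34a/E2F1/ANRIL, miR-34a/E2F1/UFC1 and
miR-34a/Myc/ANRIL) whose state decides whether the checkpoint can fire
at all.

`g1sbn` implements this system as a 32-node Boolean network with one
input (`DNA_Damage`) and three mutually exclusive phenotype outputs
(`Proliferation`, `Senescence`, `Apoptosis`), together with the
general machinery needed to analyse it: asynchronous state-transition
graphs, complete fixed-point enumeration, Monte Carlo and exact
absorption probabilities, and signed-circuit functionality analysis.

## Boolean semantics

Every node holds 0 (inactive) or 1 (active). Each non-input node has a
logical rule over its regulators built from `&`, `|`, `!`. Updating is
*fully asynchronous*: a state has one outgoing transition per node
whose rule value disagrees with its current value, and that transition
flips exactly that node. Input nodes are parameters of a run; they are
never updated. Knockout (KO) clamps a node to 0, ectopic expression
(E1) clamps it to 1; clamped nodes are frozen.

The reachable dynamics from a root state is the state-transition graph
(STG). Its terminal strongly connected components are the attractors:
a singleton with no outgoing transition is a fixed point (steady
state); a terminal component with two or more states is a cyclic
attractor. A fixed point's phenotype is the unique output node that is
ON (`None` if all outputs are OFF); every rule set shipped or accepted
by the package keeps the three outputs mutually exclusive in reachable
attractors, and the analysis functions flag a violation as `Mixed`.

Every rule must be *monotone*: non-decreasing in each activator,
non-increasing in each inhibitor. `validate_model()` checks this
exhaustively over all regulator contexts, and checks that the
variables of the rules reconstruct the declared signed edge set
exactly, so the regulatory graph and the logic can never drift apart.

## The checkpoint model

```{r}
bundle <- build_nsclc_model()
bundle$model
```

The wild-type model has exactly three fixed points:

```{r}
fps <- fixed_points(bundle$model)
data.frame(
  damage = fps[, "DNA_Damage"],
  phenotype = apply(fps, 1, classify_attractor, model = bundle$model),
  miR34a = fps[, "miR34a"], p53A = fps[, "p53A"], p53K = fps[, "p53K"])
```

Without damage the cell rests in a proliferative state in which the
sponges win: E2F1/Myc sustain ANRIL and UFC1, EZH2 is recruited,
miR-34a is silenced, and the cyclin-CDK complexes run. With damage the
checkpoint breaks the sponge deadlock through the p53 arm: p53
represses Myc, E2F1 collapses, the lncRNAs and EZH2 decay, miR-34a
fires and locks the proliferative arm down. The cell then commits to
one of two p53 phospho-states: the arrester form (p53-A, driving p21
and senescence) or the killer form (p53-K, driving Bax/caspase-3 and
apoptosis). Commitment is a genuine race between asynchronous update
orders, which is why the damage response is bistable and why its
outcome is quantified as an absorption probability.

### How the rules were fixed

The published account of this model prints its interaction skeleton,
its attractors, its mutant phenotypes and its Monte Carlo
probabilities, but the full rule file lives in an appendix that is not
part of the text this package was built from. The shipped rule set was
therefore *reconstructed*: the signed skeleton was taken verbatim from
the text, the default rule template is "(OR of activators) AND NOT (OR
of inhibitors)", and every deviation from that template was introduced
only where a printed observable forces it. The behavioural constraints
used for calibration are all machine-checkable and shipped as
`check_nsclc_calibration()`:

* exactly three wild-type fixed points with the printed activity
  patterns;
* lncRNA knockouts derepress miR-34a in every damage fixed point;
  lncRNA (or Myc) over-expression silences it;
* any combination involving a miR-34a knockout abolishes senescence
  and leaves apoptosis as the only fate;
* miR-34a over-expression or Myc knockout shuts both lncRNAs down and
  preserves both damage fates;
* all 24 rows of the circuit-perturbation screen reproduce their
  phenotype sets;
* the wild-type damage split is close to 80% apoptosis / 20%
  senescence, and the two sponge-rescue experiments (UFC1 KO + miR-34a
  E1, ANRIL KO + miR-34a E1) close to 40% / 60%.

The main deviations this forces, and why:

* **p53 activation overrides Mdm2 under ATM** (`p53 = ATM | (!Mdm2 &
  !HDAC1)`). With a plain AND-NOT rule the damage signal can never
  break through basal Mdm2, and no damage fixed point with active p53
  exists.
* **Cyclin D is constitutive** (`CDK46_CycD = !(miR34a | p21)`),
  reflecting CCND1 over-expression in NSCLC. Without a constitutive
  growth driver the model acquires a fourth, quiescent fixed point
  that the published attractor count excludes.
* **E2F1 carries a derepression arm** (`!RB & !p53 & !Sirt1`): E2F1 is
  re-expressed whenever RB is lost in an undamaged cell. This is what
  destabilises the quiescent state, while `!p53` prevents a
  damage-resistant proliferative fixed point.
* **KLF2 overrides the Myc/HDAC1 repression of p21**. Without the
  override, rows of the circuit screen that clamp the lncRNA arm ON
  while rescuing miR-34a could never reach senescence.
* **The arrester/killer conversion is explicit**: p53-A induces
  p53-INP1 while the proliferative context (HDAC1, E2F1 or Myc) is
  still present, p53-INP1 activates the Ser-46 kinase HIPK2, and HIPK2
  extinguishes p53-A. Wip1 antagonises the killer switch (and ATM,
  closing the p53/Wip1/ATM negative loop). Two gates in this module --
  the transient BCL2-dependent shield on HIPK2 and the BCL2/HDAC1/
  Cdc25A context on p53-K -- are the least constrained part of the
  reconstruction; their form is pinned by the printed probability
  splits rather than by a specific referenced interaction, and they
  are the first place to revisit if the original rule file becomes
  available.
* Chk2 (ATM -> Chk2 -| Cdc25A) and HIPK2 are included as explicit
  nodes; both are canonical members of this pathway and bring the
  model to its stated 32 nodes.
* The ATM -> E2F1 stabilisation edge was left out. With it, the E2F1/
  Sirt-1 negative loop oscillates forever under a miR-34a knockout, so
  those scenarios would have no fixed point at all, contradicting the
  published mutant table.

One consequence of reconstruction is worth stating plainly: the
*short* functional-circuit inventory calibrates exactly (16 functional
circuits with at most three nodes, including the three novel sponge
circuits), but the reconstructed graph supports several hundred
functional circuits of length four and above, where the reference
analysis reports 28 functional circuits in total. The count of long
functional feedbacks is extremely sensitive to the precise rule file
-- far more than any reported dynamical observable -- and no monotone
rule assignment we found reproduces both the dynamics and the long-
circuit count. `run_circuit_report()` therefore reports the computed
counts and raises an explicit warning when they differ from the
reference inventory.

## Probabilities: Monte Carlo and exact absorption

Phenotype probabilities interpret the asynchronous STG as a Markov
chain with the uniform distribution over the enabled transitions of
each state -- each applicable update is equally likely. This is the
"exact exit probabilities" convention of the GINsim tool family; the
choice is isolated in one place so alternative weightings could be
plugged in.

Two estimators are provided and cross-validated against each other:

* `monte_carlo_phenotypes()` runs seeded random walks to absorption
  (100,000 walks by default in the scenario runners, matching the
  reference experiments). Walks that exceed `max_steps` (default
  10,000) are routed to cycle detection.
* `exact_absorption()` lumps terminal SCCs into absorbing classes and
  solves the linear system `(I - Q) x = b`; above 200,000 transient
  states it switches from a sparse direct solve to fixed-point
  iteration, since LU fill-in becomes prohibitive.

The wild-type damage STG of the checkpoint model exceeds nine million
states, so the exact solve is reserved for smaller scenarios (for
example `Myc_E1`, about 4,600 states) and for the synthetic fixtures,
while the full-scale scenarios use the Monte Carlo estimator -- the
same division of labour as in the original analysis.

```{r}
run_scenario(bundle, "WT_damage", n_runs = 20000, seed = 1)
run_scenario(bundle, "UFC1_KO_miR34a_E1", n_runs = 20000, seed = 1)
```

All scenario runs start from the damage-free proliferative fixed point
with `DNA_Damage` switched on and the clamps applied: a cycling cell
hit by genotoxic stress in the given genetic background. The
biological initial condition is not stated explicitly in the source
text; this choice is the package's own and sits behind the single
function `nsclc_root_state()`. Output nodes never regulate anything,
so the dynamics run on the 29-node subnetwork and the phenotype is
evaluated from the output rules afterwards -- an exact reduction that
shrinks the state space eight-fold.

## Circuit functionality

A feedback circuit shapes dynamics only where its edges are
*operative*. The discrete derivative of an edge u -> v at state x is
`f_v(x[u:=1]) - f_v(x[u:=0])`; for monotone rules its sign, when
nonzero, equals the edge sign. A circuit is functional iff some state
makes every circuit edge's derivative nonzero. The search is exact and
local: each derivative depends only on the target's other regulators,
so `is_functional()` solves a small constraint problem over the
circuit's regulator context instead of scanning 2^32 states. Clamping
any circuit member makes the circuit non-functional, which is why the
24-row screen of the three novel circuits is run as a perturbation
experiment:

```{r, eval = FALSE}
rep <- run_circuit_report(bundle)      # inventory + 24-row screen
rep$short_functional
```

Positive circuits (even number of inhibitions) enable multistability;
negative circuits enable oscillations. The three sponge circuits are
positive, and the screen shows that senescence is recovered exactly
when miR-34a is forced ON while its partner driver (E2F1 or Myc) is
knocked out.

## Synthetic fixtures and what the tests show

`random_boolean_network()` draws seeded random monotone networks
(three rule families: AND-NOT, nested canalyzing, random monotone DNF)
whose complete attractor structure is computable by
`brute_force_attractors()` from the full 2^n STG (guarded at n <= 14).
The engine's fixed-point enumerator, attractor detector and Monte
Carlo estimator are validated against these oracles on a hundred
seeded networks per test run. The generator mirrors the rule *shapes*
of the checkpoint model, not its topology: random networks are not
scale-free, have no inputs or outputs and carry no biological
structure, so passing these tests certifies the *engine*, while the
calibration constraints above certify the *model*. Neither certifies
the unpublished original rule file; they bound it behaviourally.

## Numerical choices

* Successor enumeration and state serialisation follow declared node
  order; fixed seeds make every Monte Carlo run bit-reproducible
  (R's own RNG drives the C++ walk kernel).
* Defaults: `max_steps = 10000` per walk, `max_states = 2e6` per
  exhaustive STG, functionality context guarded implicitly by the
  constraint search.
* Fixed-point enumeration is depth-first branch-and-prune with unit
  propagation over partial assignments; it never enumerates 2^n
  states and resolves the 32-node model in well under a second.
* Problem sizes used in the shipped tests (100k-walk scenarios,
  20k-walk cross-checks, hundred-network oracle batteries, 3k-walk
  screen rows) were chosen so a full run stays desk-scale.

## Limitations

* The logic is strictly Boolean: no multi-valued activity levels, no
  kinetic rates, no stochastic rule noise. Probabilities quantify
  update-order uncertainty only.
* The rule set is a behaviourally calibrated reconstruction, not a
  transcription; observables not pinned by the calibration set (most
  visibly the long-circuit count) should not be over-interpreted.
* Cell-line differences (A549 vs H1299 vs SPC-A1) enter only through
  which experiment a scenario is compared against, not as distinct
  models.
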