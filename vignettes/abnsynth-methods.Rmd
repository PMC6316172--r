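---
title: "Constraint-based synthesis of Boolean gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based synthesis of Boolean gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abnsynth)
```

## The modelling problem

Transcription-factor circuits such as the network maintaining naive
pluripotency in mouse embryonic stem cells are known only incompletely:
the component roster is well supported, but for many pairwise interactions
the evidence is correlative. Committing to a single Boolean network
therefore over-claims. `abnsynth` instead works with an **Abstract Boolean
Network (ABN)**: a component set with *definite* interactions (always
present) and *optional* ones (possibly present). With $n$ optional
interactions the ABN describes $2^n$ candidate topologies; each topology
combined with one update rule per gene is a **concrete model**.

Experimental observations — "EpiSCs in 2i+LIF reset to the naive state and
stay there", "Nanog knockouts do not" — are encoded as constraints on
bounded synchronous trajectories. The package *synthesises* the set of
concrete models consistent with every constraint (the **constrained ABN**,
cABN) and formulates predictions only where all consistent models agree,
so predictions never depend on an arbitrary choice among equally supported
models.

## Update semantics

### Regulation conditions

Update rules are not tied to named regulators (which vary between
candidate topologies). A rule sees only the *availability level* of a
gene's activators and of its repressors: `none` (no instantiated regulator
of the class is active), `some`, or `all` (every instantiated one is
active, and at least one exists). A valid **regulation condition** must be
false without active activators, monotone (more activators never switch a
gene off, more repressors never switch it on) and true at
(`all` activators, `no` repressors). Exactly nine Boolean tables on the
$3\times3$ level grid satisfy these requirements;
`regulation_conditions()` enumerates all $2^9$ tables and filters them, so
the family is derived, not transcribed. Conditions are indexed 0–8 from
least permissive (condition 0: all activators and no repressor) to most
permissive (condition 8: any activator, repressors ignored), ties broken
lexicographically. Because published models may order the family
differently, `abn()` accepts an explicit allowed-condition set per gene
and the loader accepts explicit indices.

Level totals count *instantiated* interactions of the concrete model, so
a gene with one instantiated activator can only ever see levels `none` or
`all` for that class, and a gene with no instantiated activator is
permanently off.

### Synchronous dynamics, signals and clamps

Under the synchronous scheme every gene updates simultaneously from the
previous state. Signals (LIF, CH, PD) have no regulators; they are clamped
to the culture-condition inputs at every step. Perturbations are clamps:
forced expression holds a gene High over the whole trajectory, a
knockout/knockdown holds it Low, and finite windows model transient
(DOX-style) induction. Fixed points are evaluated on the full state
vector, signals included.

Two deliberate conventions make each concrete model's trajectory
deterministic:

* **Partial initial states default to Low.** Constraint initial states in
  practice specify either a full discretised profile or "everything off
  except …"; defaulting unspecified genes to Low matches that usage and
  removes a hidden existential quantifier from the semantics.
* **Knockouts are clamps, not component removals.** Removal would change
  the `all`-level denominator of downstream genes; the clamp reading keeps
  one network shared by all constraints. A consequence worth noting: a
  target gene whose rule demands *all* of a set of activators including a
  clamped-Low one can never fire, so constraint targets drop genes the
  perturbation makes trivially unreachable (the Nanog-knockout constraints
  target the naive state minus Nanog; the 2i-only constraint, where Stat3
  has no input, targets the naive state minus Stat3).

## Constraints

An `experiment()` fixes inputs, clamps, an initial state, a bound
(20 steps by default, after which trajectories of these circuits have
invariably settled) and a list of expectations over a partial state with
one of four modalities: `reached` (holds at some step of a range), `never`
(at none), `held` (at every step of a range — with the default two-step
range this is the "final state at two sequential steps" encoding used when
a full stable state cannot be specified), and `stable` (holds at a step
whose full state is a synchronous fixed point).

A `comparative()` constraint relates two trajectories of the *same*
concrete model: the treated trajectory must not reach a target at a
strictly earlier step than the reference (first-hitting steps, not
first-stable). When the reference never reaches the target within the
bound the constraint is vacuously satisfied — the relation says "not
earlier than", and with no reference hit there is nothing to be earlier
than.

`builtin_resetting_constraints()` returns the six resetting observations
(control, EpiSC in 2i+LIF / 2i / 2i+forced Tfcp2l1, Nanog knockout in
2i+LIF and in LIF+CH) plus the comparative constraint that forced Sall4
expression never accelerates resetting. A maintenance-era reconstruction
ships as `inst/extdata/maintenance_synthetic.exp` in the same file format
rather than being hard-coded, so it can be replaced by an original
constraint file where available.

## Synthesis by bounded model checking

Choice variables — one presence bit per optional interaction, a one-hot
condition selector per gene — are shared across all experiments. Each
experiment contributes one unrolled trajectory (steps $0..B{+}1$; the
extra step serves fixed-point tests) whose transition relation encodes the
regulation-condition semantics via availability-level indicator literals.
Because initial states are fully determined, the trajectory variables are
functions of the choice variables and the solver's search space is exactly
the concrete-model space.

The decision engine is a conflict-driven clause-learning (CDCL) SAT
solver implemented in C++ within the package (watched literals, first-UIP
learning, activity-based branching, Luby restarts; fully deterministic).
Solver answers are never trusted blind:

* every satisfying assignment is checked clause-by-clause in R;
* every decoded witness model is re-simulated with the reference dynamics
  (`sync_trajectory()`/`check_constraint()`) against every constraint;
* on random instances small enough to enumerate (≤ 4 components,
  ≤ 6 optional interactions), satisfiability, model counts,
  required/disallowed classification, condition usage and minimal models
  are compared exactly against the vectorised brute-force path
  (`bf_synthesize()`), which shares no code with the CNF encoder or the
  solver.

A conflict budget (default $2\times10^6$ conflicts) bounds each query;
exhausting it yields the explicit status `indeterminate`, never
`unsatisfiable`.

Derived analyses follow the published recipes: `classify_interactions()`
finds one witness and tests each optional interaction individually
(removal of a present one unsatisfiable ⇒ *required*; imposition of an
absent one unsatisfiable ⇒ *disallowed*); `count_models()` enumerates with
blocking clauses over the full choice vector, so the count is of concrete
models; `minimal_model()` binary-searches a sequential-counter cardinality
bound and certifies minimality by unsatisfiability one interaction lower;
`component_deletion_scan()` removes a gene, its interactions and the
expectations that concern only it; `random_abn_control()` draws
shape-matched random networks (same roster, same definite/optional and
sign counts, no duplicate signed edges, self-loops only if the template
has them) as a specificity control.

## Predictions

Every query tests a hypothesis *and its null* against the constraint set:
hypothesis satisfiable with null unsatisfiable ⇒ positive prediction (all
models agree); the converse ⇒ negative; both satisfiable ⇒ `no_prediction`
(the model set genuinely disagrees — which is itself informative, naming a
discriminating experiment).

* `steps_to_target()` tests "stabilised in the target at step $s$" for
  each $s$: the satisfiable range is where *some* models have settled, the
  least $s$ with unsatisfiable null is where *all* have. With constant
  clamps stability is monotone in $s$ per model and both boundaries are
  found by binary search; transient clamp windows fall back to a per-step
  scan.
* `activation_step()` defines permanent activation at $s$ as High from
  $s$ through one step past the bound, so pulses do not count.
* `compare_schedules()` encodes both trajectories in one query with shared
  choice variables and asks whether any model lets A reach the target
  strictly later than B. First-hitting steps are the default, matching the
  comparative-constraint semantics; a `mode = "stable"` switch uses
  first-stable steps instead, since published wording does not fix the
  choice.
* `precedes()`, `essentiality()` and `cocktail_outcome()` are the
  gene-order, depletion and reprogramming-cocktail specialisations;
  cocktail factors outside the roster (cMyc in OSKM) are dropped with a
  warning.
* `score_predictions()` reports accuracy over definitive predictions and,
  alongside its denominator, a conservative accuracy that counts
  `no_prediction` as incorrect.

## Interaction inference from expression

`call_possible_interactions()` implements the correlation rule: a pair is
possible-and-positive when at least one of its per-dataset Pearson
coefficients is at or above the threshold (comparisons are inclusive, so
the candidate-grid search is well defined at observed values) and a strict
majority of the *remaining* coefficients are positive; the negative rule
mirrors it. "Remaining" excludes the single extremal coefficient — under
this reading the majority check is threshold-independent, and lowering the
threshold can only add calls (the monotonicity the threshold search
relies on). When both signs trigger, the majority sign over all defined
coefficients decides; ties yield no call (conservative, keeping the ABN
small). Coefficients undefined because a gene is constant in a dataset
are excluded from majority counts, and self-correlations are never
called. Calls are emitted bidirectionally because correlation does not
orient an interaction.

`find_max_threshold()` seeks the largest threshold whose induced ABN
(definite interactions plus calls) satisfies the constraints.
Satisfiability is monotone in the threshold — an un-instantiated optional
interaction never changes dynamics, so enlarging the optional set
preserves satisfiability — which turns the search into a binary search
over the candidate grid. An unsatisfiable minimum raises an error naming
the first violated constraint.

## The synthetic-data generator

The generator exists so that every stage of the pipeline is testable
without downloads, and its defaults define the study conditions used by
the tests: 12 genes, 3 signals, up to 25 interactions, emission ratio
$\mu_{High}/\mu_{Low} = 10$, log-normal noise sd 0.2, 7 datasets of 80
samples, planted threshold 0.5.

`sample_ground_truth()` draws a layered network: genes get depths 1–3,
every gene's guaranteed activator comes from a shallower layer with
signals at the root, most extra edges are feed-forward (25% repressing)
and a 15% fraction are positive feedback edges. The layering ensures that
input variation propagates through the whole circuit — the property
correlation inference needs — while feedback keeps the family cyclic.
Regulation conditions for repressor-bearing genes are drawn only from the
conditions under which repression is functional (0, 1, 2, 4, 6), so no
planted interaction is dynamically inert. In-degree is capped at 2
because a balanced two-regulator Boolean target caps the pairwise Pearson
correlation with either regulator near $0.58$; the planted threshold of
0.5 sits just below that ceiling, and single-regulator targets correlate
exactly ($|r|=1$ at zero noise). Recovery of planted edges at the planted
threshold is therefore designed-in but partial on dense networks — the
fixed-seed values recorded by the test suite are around 0.7–0.85 recall
with precision near 0.4–0.8 — and recall degrades monotonically with
emission noise.

`simulate_expression()` reads near-steady states of the ground-truth
model under per-sample random input combinations (with occasional
single-gene perturbations), emulating expression panels collected across
culture conditions. It does **not** attempt transcriptomic realism: no
counts, no dropout, no library-size effects. Passing tests therefore show
that the inference rule recovers the statistical structure it assumes,
not that it would survive raw single-cell noise — which is exactly the
division of labour in the original workflow, where discretisation
(`discretize_bulk()`, half-of-reference inclusive; and
`discretize_single_cell()`, per-gene 2-means on log10 values with the
midpoint of centroids as threshold) handles the measurement layer.

`generate_observations()` simulates the ground truth under a design panel
(unperturbed "resetting" from a partially active state, knockdowns,
forced expression) and encodes the observed endpoint behaviour as
constraints — `stable` when the trajectory reaches a fixed point, the
two-sequential-steps `held` form otherwise — plus a held-out panel of
gene-depletion outcomes with matching prediction queries. By construction
the ground truth satisfies its own constraints, so it is a member of the
synthesised cABN and no definitive prediction can contradict its
behaviour; the test suite checks this soundness chain across 20 seeds.

## The bundled pluripotency reconstruction

`pluripotency_network()` loads `inst/extdata/pluripotency_synthetic.net`,
a *synthetic reconstruction* of the naive-pluripotency circuit built for
the worked analyses: the definite signalling axes (LIF→Stat3, CH⊣Tcf3,
PD⊣MEK/ERK) and the published local topology of Tfcp2l1 (definite
activators Stat3 and Esrrb, optional activators Tbx3, Gbx2, Klf2, Klf4,
inhibitor Tcf3) and of Esrrb (definite activators Sall4, Nanog, Tfcp2l1;
a definite and an optional inhibitor) are encoded as described in the
literature; the remaining optional interactions are invented, chosen once
so that the six resetting constraints are jointly satisfiable, and not
revised since. MEK/ERK and Tcf3 carry definite self-activations with
condition 0 so that they latch their culture-determined activity: active
under FGF/Activin, switched off by PD or CH respectively. Step counts and
classifications computed on this network illustrate the machinery; they
are not reproductions of the original supplementary model, which would be
loaded through the same `read_network()` format were it available.

## Asynchronous cross-validation

`async_trajectory()` updates one unclamped gene per step, chosen
uniformly at random (default) or in random-permutation rounds — the
round policy enforces the weak fairness that uniform sampling lacks, and
the choice is exposed because no single convention is canonical.
`async_battery()` evaluates prediction queries empirically: reachability
counts positive when the target is hit in any run (the permissive
convention appropriate to non-deterministic reachability; the threshold
is configurable), ordering queries by the majority of runs. On toy models
the empirical reachability is checked against the exact Markov-chain
solution of the uniform-update process, and the analysis scripts compare
the minimal model's asynchronous behaviour with the synchronous verdicts.

## Numerical and engineering choices

* Solver determinism: no randomised branching; identical inputs give
  identical answers, and every stochastic routine takes an explicit seed.
* Tie-breaks: condition ordering by (true-cell count, lexicographic);
  interaction-call ties yield no call; `minimal_model()` returns the
  first witness at the minimal cardinality.
* Degenerate inputs: genes with a single distinct single-cell value are
  flagged and set Low; constant genes yield undefined correlations that
  never contribute calls; zero-activator genes are permanently off.
* Problem sizes: the validation suite uses 200 random instances for
  oracle equivalence, 20 seeds for the soundness chain, a 16-component
  reconstruction with seven constraints for the resetting battery, and
  hundreds of asynchronous runs per query — sizes at which the full suite
  completes in a few minutes on a single core while still exercising
  every code path at the scale the method targets.

## Known limitations

Synthesis is exact but worst-case exponential; networks far denser than
the dozens-of-optional-interactions regime may exhaust the conflict
budget (reported as `indeterminate`). The comparative-constraint and
prediction semantics assume deterministic trajectories, so they are not
offered under asynchronous updates. The expression generator validates
the inference rule's assumptions rather than challenging them with
realistic measurement noise. And the bundled network is a reconstruction:
analyses on it demonstrate the pipeline, not the original study's exact
numbers.
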