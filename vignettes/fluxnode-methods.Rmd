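---
title: "Metabolite-centric constraint-based analysis with fluxnode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite-centric constraint-based analysis with fluxnode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxnode)
```

# The model

A metabolic network is a stoichiometric matrix $S$ (rows: metabolites,
columns: reactions; negative entries substrates, positive products)
together with per-reaction reversibility flags.  Under the steady-state
assumption, internal metabolite concentrations are constant, so every
feasible flux vector $v$ (units mmol gCDW$^{-1}$ h$^{-1}$ throughout)
satisfies

$$S\,v = 0, \qquad lb \le v \le ub.$$

Metabolites flagged *boundary* are exempt from the balance: they model
pools outside the system and obtain no row of $S$.  Bounds and the
objective live in a *scenario* detached from the network, so one model
can be simulated under many conditions; a reaction without explicit
bounds defaults to $[0, \infty)$ if irreversible and
$(-\infty, \infty)$ if reversible.  Contradictory scenario bounds are
deliberately only rejected when a scenario is applied to a model
(`resolveBounds()`), so parameter files parse independently of any
network.

# Reaction-centric analyses

**FBA** maximizes or minimizes a single objective flux over the
feasible set — one LP.  **FVA** constrains the objective to a fraction
$\gamma$ of its optimum (lower-bounding it for maximization,
upper-bounding for minimization) and then solves two LPs per reaction
for its minimal and maximal flux.  Because the objective is always a
single reaction flux here, the $\gamma$-constraint is applied as a
bound tightening rather than an extra matrix row.  $\gamma$ defaults to
0.95 — the conventional "at least 95% of optimal growth" setting — and
is recorded in every report; `fraction = NULL` drops the constraint
entirely (used by the MOMA preprocessing below, where plain feasibility
boxes are wanted).

**MOMA** minimizes $\sum_j (v_j - w_j)^2$ over the perturbed feasible
set, $w$ being a wild-type reference distribution.  The distance runs
over *all* reactions, exchanges included: that is the plainest reading
of "closest flux distribution", and any subsetting would need a
biological argument the method itself does not supply.  Optionally the
variable boxes are first tightened to the perturbed model's FVA ranges
(`fvaReduce = TRUE`); since every feasible point, in particular the
optimum, lies inside those ranges, the optimum is provably unchanged.
The implementation additionally intersects the boxes with the ball
$\lVert v - w\rVert \le \lVert x_0 - w\rVert$ around the wild type,
where $x_0$ is the feasibility-phase point — again optimum-preserving,
and it keeps the quadratic subproblem numerically small.

**Knockout scans** pin one reaction at a time to $[0,0]$ and re-score
the objective by FBA or MOMA (MOMA referenced to the unperturbed FBA
solution).  **Batch FBA** evaluates independent scenarios, recording
per-row failures without aborting.

# Metabolite-centric analyses

The package's distinguishing methods shift the unit of analysis from
reactions to metabolites.

**Metabolite flux minimization (MFM).**  After a standard FBA, (1) the
objective is constrained to $\gamma$ of its optimum (default 95%), (2)
reversible reactions are split into forward/backward pairs so all
fluxes are nonnegative, which makes the total producing flux of
metabolite $m$ the linear form
$p_m(v) = \sum_j \max(S_{mj}, 0)\, v_j$, and (3) each $p_m$ is
successively minimized by LP.  A zero minimum means the network can
sustain the objective level without producing $m$ at all
(non-essential); a positive minimum is the metabolite's irreducible
turnover.  Lowering $\gamma$ relaxes the feasible set, so minimal
producing fluxes are monotonically non-increasing and the non-essential
count non-decreasing — a property the test suite checks explicitly.
Essentiality uses an absolute threshold of $10^{-9}$ on the minimal
flux; ranking breaks ties lexicographically by metabolite id so reports
are deterministic.

In the split model, a reversible reaction carrying flux in both
directions would inflate $p_m$; the minimization itself drives such
futile two-way flux to zero wherever $p_m$ is being minimized, which is
exactly the intended reading of "producing flux".

**Split-ratio analysis** describes one *realized* flux state rather
than a variational quantity, so it works on net fluxes: the
contribution of reaction $j$ at metabolite $m$ is $S_{mj} v_j$,
positive contributions are production, negative consumption, and a
reversible reaction contributes according to the sign of its net flux.
Turnover is total production; percentages are contributions relative to
total production (producers) or total consumption (consumers), which
coincide at steady state for non-boundary metabolites.  Contributions
with magnitude $\le 10^{-9}$ are omitted; zero-turnover metabolites get
empty producer/consumer lists.  Inputs are checked against
$\lVert S v\rVert_\infty \le 10^{-6}$ before any ratio is formed.

Because an LP optimum need not be unique, split ratios (and reported
FBA flux vectors generally) describe *one* optimal solution; reports
embed the solver and $\gamma$ so a configuration reproduces bit-wise,
but a different solver may legitimately realize a different optimal
branch usage.  No parsimonious post-processing is applied silently.

**Bipartite export** renders a flux state as a metabolite/reaction
graph with turnover-labelled metabolite nodes, percentage-labelled
edges oriented along realized flux, and an `active` flag (flux above
$10^{-9}$) so inactive subnetworks can be greyed out; formats are DOT,
GraphML and node-link JSON.  `condenseLinearChains()` collapses maximal
paths whose interior nodes have total degree two into single dashed
edges, preserving branch points and endpoints — the usual way long
unbranched pathways are summarized in such diagrams.

# Dead-end reduction

A non-boundary metabolite is a *dead end* when, under the directions
admissible for the current bounds (a reversible reaction confined to
$[0, u]$ counts as forward-only), it has no admissible producer, no
admissible consumer, or only a single touching reaction.  The third
case covers an isolated reversible reaction: a lone reaction cannot
balance a metabolite it carries, since $S_{mj} v_j = 0$ forces
$v_j = 0$.  In all three cases every touching reaction provably carries
zero flux in every steady state, so those reactions are blocked and the
sweep repeats until a fixpoint — at most one sweep per metabolite.
Applying the resulting report (`reduceScenario()`) pins blocked
reactions to $[0,0]$, with one guard: a blocked reaction whose explicit
scenario bounds exclude zero is left untouched, because the scenario is
then infeasible and pinning would wrongly repair it.  Reduction
precedes every optimization by default (`reduce = TRUE`) and, by the
soundness argument above, never changes an optimum; the test suite
verifies this across all fixtures and seeded random models.

# Solvers and numerical choices

All linear programs go through one solver layer.  The default back-end
is a bounded-variable two-phase revised primal simplex written for this
package, with dense refactorization every iteration (the networks here
are small after reduction, and refactorizing avoids basis drift),
Dantzig pricing with a Bland's-rule fallback after $5(n+m)+50$
iterations to exclude cycling, a $10^{-9}$ reduced-cost tolerance, a
$10^{-7}$ phase-1 feasibility threshold, and infinite bounds handled
natively.  Its distinguishing feature is **basis warm starting**: FVA
and MFM sweep hundreds of LPs that differ only in the cost vector, so
the optimal basis of one solve is primal-feasible for the next and
phase 1 is skipped entirely.  A warm start is accepted only after the
stored basis passes a feasibility check and never changes the optimum —
warm and cold paths are compared to $10^{-6}$ in the tests.  A second,
independently implemented dense simplex (from pracma) is exposed
as `backend = "pracma"` purely so results can be cross-validated
between implementations.

Quadratic programs (MOMA) are solved by a primal active-set method over
the box constraints, written for this package: starting from the
feasibility-phase point, each iteration projects onto the affine set of
the equalities plus currently pinned variables via an exact SVD
least-squares solve of the KKT system (tolerant of the redundant rows
that conserved moieties put into $S$), steps as far as the boxes allow,
and pins or releases bounds by their Lagrange multipliers.  The method
is exact for the identity-weighted MOMA objective and robust at the
degenerate vertices that knockouts produce, where many bounds are
active at once.  Returned points are verified against
$\lVert S v\rVert_\infty \le 10^{-6}$ and the bounds before being
accepted; an off-the-shelf dual active-set solver serves as an
independent cross-check in the tests on well-conditioned instances.

Back-ends that cannot represent infinities receive $\pm 10^6$ as a
documented finite stand-in; internally bounds stay IEEE infinite.

# What the fixtures and the generator emulate

The named fixtures are desk-scale stand-ins for genome-scale models:
a linear chain (`TOY_LIN`, optimum 10), a branched network
(`TOY_BRANCH`), a 2:1 yield step (`TOY_YIELD`, optimum 5), a network
killed by an unconsumable by-product (`TOY_DEAD`, optimum 0), a
reversible isomerization (`TOY_REV`), and `PREPHENATE_BRANCH`, a
six-reaction chain feeding a branch-point metabolite drained by two
pathways in fixed biomass proportions (0.0576 : 0.6624).  The last is
sized so the branch metabolite turns over 0.72 flux units split 8%/92%
between the phenylalanine and TDA (tropodithietic acid) branches at the
optimum — the partitioning pattern reported for the marine bacterium
*Phaeobacter inhibens*, whose antibacterial TDA production competes
with biomass for prephenate; engineering the published magnitudes into
the fixture lets the worked example double as documentation.

`randomModel()` generates property-test inputs: a guaranteed-feasible
backbone (uptake capped at 10 → linear chain → objective sink) plus
random internal reactions with substrate coefficient 1–2 and product
coefficient 1, 20% of them reversible (reversible extras are kept 1:1
so no direction amplifies mass, keeping every objective bounded).  Each
model is reproducible per seed and leaves the global RNG untouched.
These inputs exercise warm starts, reductions, degenerate optima and
internal cycles, but they do **not** emulate genome-scale features —
compartments, cofactor coupling, hundreds of exchanges, biomass
equations with dozens of precursors — so passing tests demonstrate
algorithmic correctness, not biological realism, and real-model
behavior (e.g. solver times, degeneracy patterns) will differ in
degree.  Default problem sizes used by the suite and the acceptance
script (6–8 metabolites, 10–14 reactions, 20 models) were chosen as the
smallest sizes that still produce branch points, cycles and dead ends.

# Curation utilities

*Name normalization* replaces metabolite ids/names by recommended names
from a user-supplied two-column synonym table, matching
case-insensitively after whitespace normalization — deliberately
dictionary-based, no fuzzy matching, because silent near-matches are
exactly the class of error the tool exists to surface.  When two
formerly distinct metabolites collapse to one name their rows are
merged; coefficients cancelling to zero are dropped with a logged
warning.  The mapping sends recommended names to themselves, making the
operation idempotent.

*Plausibility checks* run four deterministic tests: growth with all
declared exchange imports closed (a "free lunch" — the import direction
of every exchange reaction the scenario explicitly bounds is shut, so
an undeclared source reaction that still sustains the objective is
flagged); duplicate reactions (identical stoichiometry up to sign and
scaling, detected by canonicalized column signatures); dead-end
listing; and unbounded objectives.  Findings are ordered by code then
subject.

*Directionality assignment* applies a symmetric threshold rule to
supplied reaction Gibbs energies (treated as already transformed to the
conditions of interest, since no standard-state convention is imposed):
below $-30$ kJ/mol irreversible forward, above $+30$ kJ/mol reversed
and irreversible, inside the band reversible.  The 30 kJ/mol default
half-width is an order-of-magnitude choice — large enough that
typical measurement and transformation uncertainty does not flip a
direction — and is exposed as a parameter.

# Interchange formats

The plain-text dialect is one reaction per line
(`id : 2 A + B -> C`, `<->` for reversible, an empty side for
exchanges, `boundary : ...` for boundary metabolites, `#` comments)
with scenarios as `OBJ max bio` / `LB r -inf` / `UB r 10` directives.
SBML is written as L3v1 with fbc version 2 (bounds as parameters, the
objective as an fbc objective) and read for both L3+fbc and legacy L2
documents, including COBRA-style kinetic-law bound parameters; the
reader resolves elements by local name so namespace-prefix variants all
parse.  Validation of written SBML is structural — the document is
re-parsed and round-tripped through the importer in the tests — rather
than delegated to an external consistency checker.  JSON follows the
single-objective subset of the COBRA dialect; a negative lower bound
marks a reaction reversible, and multi-objective files are rejected
rather than silently truncated.

# Known limitations

Reported flux vectors are single optima of possibly degenerate LPs (see
above).  Gene–protein–reaction logic is out of scope: knockouts are
reaction-level.  There is no MILP layer (no strain-design
optimization), no thermodynamic-feasibility constraints beyond the
directionality heuristic, and no gap-filling.  The dense simplex is
sized for reduced desk- to genome-scale models, not for numerical
edge cases like badly scaled coefficients spanning many orders of
magnitude; models of that kind should be rescaled first.
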