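# fluxnode

Constraint-based analysis of genome-scale metabolic networks in R, with
a metabolite-centric focus.

## The problem

Constraint-based modeling predicts steady-state flux distributions of a
metabolic network from its stoichiometry alone.  With `S` the
stoichiometric matrix (rows = metabolites, columns = reactions) and `v`
the flux vector (mmol gCDW⁻¹ h⁻¹), every analysis in this package works
inside the feasible set

    S v = 0,   lb ≤ v ≤ ub

and differs only in what it optimizes:

* **FBA** — maximize/minimize one objective flux (typically biomass) by
  linear programming.
* **FVA** — per reaction, the minimal and maximal flux while the
  objective is held at a fraction γ (default 0.95) of its optimum,
  computed with warm-started LPs that share a single problem instance.
* **MOMA** — after a perturbation (e.g. a knockout), the feasible flux
  vector closest (squared Euclidean distance over all reactions) to a
  reference wild-type distribution, by quadratic programming.
* **MFM (metabolite flux minimization)** — the package's
  metabolite-centric counterpart of FVA: after splitting reversible
  reactions so all fluxes are nonnegative, the total *producing* flux of
  each metabolite m, `p_m(v) = Σ_j max(S_mj, 0) v_j`, is minimized under
  the γ-constrained objective.  `p_m = 0` means the metabolite is
  dispensable at that growth level; `p_m > 0` marks it essential.
* **Split-ratio analysis** — for one realized flux state, each
  metabolite's turnover and the percentage contribution of every
  producing and consuming reaction; the numbers behind bipartite
  network diagrams of branch points.
* **Iterative dead-end reduction** — metabolites that cannot be both
  produced and consumed under the current bounds force all their
  reactions to zero flux; removing them iteratively shrinks every
  optimization without changing its optimum.

Models are read and written as human-readable reaction lists with
detached scenario files, SBML (L2 and L3 + fbc), and COBRA-style JSON.
Curation utilities cover synonym-based metabolite-name normalization,
automated plausibility checks (growth without substrate, duplicate
reactions, dead ends, unbounded objectives), and directionality
assignment from reaction Gibbs energies.

## A worked example

```r
library(fluxnode)

## A six-reaction chain feeding a branch point: prephenate is drained
## by the phenylalanine branch and the TDA branch in fixed biomass
## proportions.
fx <- makeFixture("PREPHENATE_BRANCH")
fx$model
#> MetabolicModel with 5 metabolites (0 boundary) and 6 reactions (0 reversible)

fd <- fba(fx$model, fx$scenario)
objectiveValue(fd)
#> [1] 1

sr <- splitRatios(fx$model, fd)
subset(as.data.frame(resultTable(sr)), metabolite == "prephenate")
#>   metabolite turnover reaction direction   flux percent
#> 5 prephenate     0.72     ppaS  producer 0.7200     100
#> 6 prephenate     0.72     pheA  consumer 0.0576       8
#> 7 prephenate     0.72     tdaS  consumer 0.6624      92
```

At the optimum the branch-point metabolite turns over 0.72 flux units;
8% is drawn by the phenylalanine branch and 92% by the TDA branch —
exactly the kind of partitioning question split-ratio analysis exists
to answer.

Metabolite essentiality on the simple branch model:

```r
tb <- makeFixture("TOY_BRANCH")
resultTable(mfm(tb$model, tb$scenario, fraction = 0.95))
#> DataFrame with 3 rows and 3 columns
#>    metabolite   minFlux essential
#> 1           A       9.5      TRUE
#> 2           B       9.5      TRUE
#> 3           C       0.0     FALSE
```

With the objective held at 95% of its optimum, metabolites A and B must
still carry at least 9.5 flux units of production, while C can be
bypassed entirely (non-essential).

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fluxnode.R", package="fluxnode"))')" \
    fba model.rxn scenario.scen -o fluxes.tsv
```

Subcommands: `convert fba fva moma mfm splitratio deadends graph check
verify-names directionality batch fixture`.

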