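#' @include solver.R reduction.R
NULL

## Shared setup: resolve bounds (optionally after dead-end reduction) and
## locate the objective column.
.prepareProblem <- function(model, scen, reduce, requireObjective = TRUE) {
    obj <- objective(scen)
    if (requireObjective && !length(obj)) {
        stop("scenario has no objective; set one with scenario()")
    }
    if (length(obj) && !obj$reaction %in% reactions(model)$id) {
        stop("objective reaction not in model: ", obj$reaction)
    }
    if (reduce) {
        scen <- reduceScenario(model, scen, findDeadEnds(model, scen))
    }
    bounds <- resolveBounds(model, scen)
    list(
        scen = scen, bounds = bounds,
        S = stoichiometricMatrix(model),
        rids = reactions(model)$id,
        obj = obj
    )
}

.emptyDistribution <- function(status, metadata = list()) {
    new("FluxDistribution", fluxes = numeric(0),
        objectiveValue = NA_real_, status = status, metadata = metadata)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the scenario's objective flux subject to the
#' steady-state constraint \eqn{S v = 0} and the resolved flux bounds.
#' Iterative dead-end reduction is applied first by default; it shrinks
#' the problem without changing the optimum.
#'
#' @param model A [MetabolicModel-class].
#' @param scen A [Scenario-class] with an objective.
#' @param reduce Apply dead-end preprocessing first?
#' @param backend LP back-end passed to [solveLP()].
#' @return A [FluxDistribution-class]; status \code{"infeasible"} or
#'   \code{"unbounded"} when the scenario admits no optimum.
#'
#' @examples
#' toy <- makeFixture("TOY_LIN")
#' objectiveValue(fba(toy$model, toy$scenario))
#' @export
fba <- function(model, scen, reduce = TRUE, backend = "simplex") {
    p <- .prepareProblem(model, scen, reduce)
    cost <- as.numeric(p$rids == p$obj$reaction)
    res <- solveLP(cost, p$S, numeric(nrow(p$S)), p$bounds$lower,
                   p$bounds$upper, p$obj$direction, backend = backend)
    meta <- list(solver = backend, reduced = reduce,
                 objective = p$obj$reaction, direction = p$obj$direction)
    if (res$status != "optimal") {
        return(.emptyDistribution(res$status, meta))
    }
    new("FluxDistribution",
        fluxes = stats::setNames(res$x, p$rids),
        objectiveValue = res$objective, status = "optimal",
        metadata = meta)
}

#' Flux variability analysis with warm-started linear programs
#'
#' Constrains the objective flux to at least (for maximization; at most
#' for minimization) a fraction \eqn{\gamma} of its optimum, then finds
#' the minimal and maximal flux of each requested reaction with two
#' linear programs per reaction.  All solves share one problem instance:
#' the optimal basis of each LP warm-starts the next, which is the
#' mechanism that makes sweeps over whole genome-scale models fast.  The
#' results are identical to a naive cold-start loop.
#'
#' @param model A [MetabolicModel-class].
#' @param scen A [Scenario-class] with an objective.
#' @param fraction Objective fraction \eqn{\gamma \in (0, 1]}; use
#'   \code{NULL} to drop the objective constraint entirely (plain flux
#'   ranges of the scenario's feasible set).
#' @param reactionIds Subset of reactions to analyse (default: all).
#' @param reduce Apply dead-end preprocessing first?
#' @param warm Use warm starts (disable only to cross-check; results are
#'   identical either way).
#' @return A [VariabilityResult-class].  Reactions whose flux is
#'   unbounded in a direction report \code{-Inf}/\code{Inf}.
#'
#' @examples
#' toy <- makeFixture("TOY_BRANCH")
#' resultTable(fva(toy$model, toy$scenario, fraction = 0.95))
#' @export
fva <- function(model, scen, fraction = 0.95, reactionIds = NULL,
                reduce = TRUE, warm = TRUE) {
    if (!is.null(fraction) &&
        (!is.numeric(fraction) || fraction <= 0 || fraction > 1)) {
        stop("fraction must lie in (0, 1]")
    }
    p <- .prepareProblem(model, scen, reduce,
                         requireObjective = !is.null(fraction))
    lower <- p$bounds$lower
    upper <- p$bounds$upper
    if (!is.null(fraction)) {
        ref <- fba(model, p$scen, reduce = FALSE)
        if (solverStatus(ref) != "optimal") {
            stop("FBA is ", solverStatus(ref),
                 "; flux variability is undefined")
        }
        z <- objectiveValue(ref)
        jo <- p$obj$reaction
        if (p$obj$direction == "max") {
            lower[jo] <- max(lower[jo], fraction * z)
        } else {
            upper[jo] <- min(upper[jo], fraction * z)
        }
    }
    ids <- if (is.null(reactionIds)) p$rids else reactionIds
    unknown <- setdiff(ids, p$rids)
    if (length(unknown)) {
        stop("unknown reactions: ", paste(unknown, collapse = ", "))
    }
    mn <- mx <- stats::setNames(rep(NA_real_, length(ids)), ids)
    state <- NULL
    for (id in ids) {
        cost <- as.numeric(p$rids == id)
        for (dir in c("min", "max")) {
            res <- solveLP(cost, p$S, numeric(nrow(p$S)), lower, upper,
                           dir, warmStart = if (warm) state else NULL)
            if (res$status == "optimal") {
                state <- res$state
                val <- res$objective
            } else if (res$status == "unbounded") {
                val <- if (dir == "min") -Inf else Inf
            } else {
                stop("variability subproblem infeasible for ", id,
                     " (this cannot happen when the reference FBA is feasible)")
            }
            if (dir == "min") mn[id] <- val else mx[id] <- val
        }
    }
    new("VariabilityResult",
        ranges = DataFrame(reaction = ids, minFlux = unname(mn),
                           maxFlux = unname(mx)),
        fraction = if (is.null(fraction)) NA_real_ else fraction,
        metadata = list(solver = "simplex", warm = warm, reduced = reduce))
}

#' Minimization of metabolic adjustment (MOMA)
#'
#' Finds the flux distribution of a perturbed scenario that is closest
#' (squared Euclidean distance over all reactions) to a reference
#' wild-type distribution, by quadratic programming.  Optionally the
#' variable boxes are first tightened to the perturbed model's flux
#' variability ranges (no objective-fraction constraint), which shrinks
#' the QP without changing its optimum.
#'
#' @param model A [MetabolicModel-class].
#' @param perturbedScen The perturbed [Scenario-class] (e.g. a knockout).
#' @param wildtype A [FluxDistribution-class] covering every reaction of
#'   the model, typically from [fba()] on the unperturbed scenario.
#' @param fvaReduce Tighten bounds to perturbed-model FVA ranges first?
#' @param reduce Apply dead-end preprocessing first?
#' @return A [FluxDistribution-class]; \code{objectiveValue} is the flux
#'   of the scenario's objective reaction in the adjusted state (when an
#'   objective is set), and \code{metadata$squaredDistance} holds the
#'   minimized squared distance to the wild type.
#'
#' @examples
#' toy <- makeFixture("TOY_BRANCH")
#' wt <- fba(toy$model, toy$scenario)
#' adjusted <- moma(toy$model, knockoutScenario(toy$scenario, "r1"), wt)
#' adjusted@metadata$squaredDistance
#' @export
moma <- function(model, perturbedScen, wildtype, fvaReduce = FALSE,
                 reduce = TRUE) {
    rids <- reactions(model)$id
    if (!all(rids %in% names(fluxes(wildtype)))) {
        stop("wildtype distribution must cover every reaction of the model")
    }
    w <- fluxes(wildtype)[rids]
    scen <- perturbedScen
    if (reduce) {
        scen <- reduceScenario(model, scen, findDeadEnds(model, scen))
    }
    bounds <- resolveBounds(model, scen)
    lower <- bounds$lower
    upper <- bounds$upper
    S0 <- stoichiometricMatrix(model)
    feas <- solveLP(numeric(length(rids)), S0, numeric(nrow(S0)),
                    lower, upper, "min")
    if (feas$status != "optimal") {
        return(.emptyDistribution("infeasible", list(
            solver = "pracma-qp", fvaReduce = fvaReduce, reduced = reduce
        )))
    }
    if (fvaReduce) {
        vr <- fva(model, scen, fraction = NULL, reduce = FALSE, warm = TRUE)
        rg <- resultTable(vr)
        lower <- pmax(lower, stats::setNames(rg$minFlux, rg$reaction)[rids])
        upper <- pmin(upper, stats::setNames(rg$maxFlux, rg$reaction)[rids])
    }
    S <- stoichiometricMatrix(model)
    n <- length(rids)
    ## the optimum lies within ||v - w|| <= ||x0 - w|| for any feasible
    ## x0, so the boxes can be shrunk to that ball: this keeps the QP
    ## numerically small without touching the optimum
    x0 <- stats::setNames(feas$x, rids)
    r <- sqrt(sum((x0 - w)^2))
    lower <- pmax(lower, w - r - 1)
    upper <- pmin(upper, w + r + 1)
    res <- solveQP(diag(2, n), -2 * w, S, numeric(nrow(S)), lower, upper)
    meta <- list(solver = "pracma-qp", fvaReduce = fvaReduce,
                 reduced = reduce)
    if (res$status != "optimal") {
        return(.emptyDistribution(res$status, meta))
    }
    v <- stats::setNames(res$x, rids)
    dist2 <- sum((v - w)^2)
    obj <- objective(perturbedScen)
    meta$squaredDistance <- dist2
    new("FluxDistribution",
        fluxes = v,
        objectiveValue = if (length(obj)) unname(v[obj$reaction]) else
            NA_real_,
        status = "optimal", metadata = meta)
}

#' Derive a knockout scenario
#'
#' @param scen A [Scenario-class].
#' @param reactionIds Reactions to pin to zero flux.
#' @return The scenario with those reactions bounded to \eqn{[0, 0]}.
#' @export
knockoutScenario <- function(scen, reactionIds) {
    lb <- scen@lowerBound
    ub <- scen@upperBound
    lb[reactionIds] <- 0
    ub[reactionIds] <- 0
    new("Scenario", lowerBound = lb, upperBound = ub,
        objectiveReaction = scen@objectiveReaction,
        objectiveDirection = scen@objectiveDirection)
}

#' Single-reaction knockout scan
#'
#' Re-evaluates the objective after pinning each listed reaction to zero
#' flux, by FBA or MOMA (MOMA uses the unperturbed FBA solution as the
#' wild type).  The input scenario is never modified.
#'
#' @param model A [MetabolicModel-class].
#' @param scen A [Scenario-class] with an objective.
#' @param reactionIds Reactions to knock out (default: all).
#' @param method \code{"fba"} or \code{"moma"}.
#' @param reduce Apply dead-end preprocessing inside each evaluation?
#' @return A [S4Vectors::DataFrame] with columns \code{reaction},
#'   \code{status}, \code{objective}.
#'
#' @examples
#' toy <- makeFixture("TOY_BRANCH")
#' knockoutScan(toy$model, toy$scenario, c("r1", "r2"))
#' @export
knockoutScan <- function(model, scen, reactionIds = NULL,
                         method = c("fba", "moma"), reduce = TRUE) {
    method <- match.arg(method)
    rids <- reactions(model)$id
    if (is.null(reactionIds)) reactionIds <- rids
    unknown <- setdiff(reactionIds, rids)
    if (length(unknown)) {
        stop("unknown reactions: ", paste(unknown, collapse = ", "))
    }
    wildtype <- if (method == "moma") fba(model, scen, reduce = reduce)
    rows <- lapply(reactionIds, function(r) {
        ko <- knockoutScenario(scen, r)
        fd <- if (method == "fba") {
            fba(model, ko, reduce = reduce)
        } else {
            moma(model, ko, wildtype, reduce = reduce)
        }
        list(status = solverStatus(fd), objective = objectiveValue(fd))
    })
    DataFrame(
        reaction = reactionIds,
        status = vapply(rows, `[[`, character(1), "status"),
        objective = vapply(rows, `[[`, numeric(1), "objective")
    )
}

#' Batch FBA over many scenarios
#'
#' Runs an independent FBA per scenario; failures (infeasible scenarios,
#' missing objectives) are recorded per row and never abort the batch.
#'
#' @param model A [MetabolicModel-class].
#' @param scenarios Named list of [Scenario-class] objects.
#' @param reduce Apply dead-end preprocessing per scenario?
#' @return List with \code{table} (a [S4Vectors::DataFrame]: scenario,
#'   status, objective) and \code{distributions} (list of
#'   [FluxDistribution-class] or \code{NULL} per scenario).
#'
#' @examples
#' toy <- makeFixture("TOY_LIN")
#' low <- scenario("bio", upperBounds = c(upt = 4))
#' batchFBA(toy$model, list(full = toy$scenario, low = low))$table
#' @export
batchFBA <- function(model, scenarios, reduce = TRUE) {
    if (!length(scenarios)) {
        return(list(
            table = DataFrame(scenario = character(0),
                              status = character(0),
                              objective = numeric(0)),
            distributions = list()
        ))
    }
    nms <- names(scenarios)
    if (is.null(nms) || any(!nzchar(nms))) {
        nms <- paste0("scenario_", seq_along(scenarios))
    }
    dists <- vector("list", length(scenarios))
    status <- character(length(scenarios))
    objv <- rep(NA_real_, length(scenarios))
    for (i in seq_along(scenarios)) {
        fd <- tryCatch(fba(model, scenarios[[i]], reduce = reduce),
                       error = function(e) e)
        if (inherits(fd, "error")) {
            status[i] <- "error"
        } else {
            dists[[i]] <- fd
            status[i] <- solverStatus(fd)
            objv[i] <- objectiveValue(fd)
        }
    }
    names(dists) <- nms
    list(
        table = DataFrame(scenario = nms, status = status, objective = objv),
        distributions = dists
    )
}

#' Compare two flux distributions
#'
#' Produces per-reaction paired fluxes and differences (the data behind a
#' comparative scatter plot) and counts reactions whose fluxes differ by
#' more than the tolerance.
#'
#' @param a,b [FluxDistribution-class] objects over the same reactions.
#' @param tol Difference magnitude below which fluxes count as equal.
#' @return List with \code{table} ([S4Vectors::DataFrame]: reaction,
#'   fluxA, fluxB, difference), \code{nDiffering}, and \code{tolerance}.
#'
#' @examples
#' toy <- makeFixture("TOY_BRANCH")
#' wt <- fba(toy$model, toy$scenario)
#' compareFluxes(wt, wt)$nDiffering
#' @export
compareFluxes <- function(a, b, tol = 1e-6) {
    fa <- fluxes(a)
    fb <- fluxes(b)
    if (!setequal(names(fa), names(fb))) {
        stop("flux distributions cover different reaction sets")
    }
    ids <- names(fa)
    diff <- unname(fa[ids] - fb[ids])
    list(
        table = DataFrame(reaction = ids, fluxA = unname(fa[ids]),
                          fluxB = unname(fb[ids]), difference = diff),
        nDiffering = sum(abs(diff) > tol),
        tolerance = tol
    )
}
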