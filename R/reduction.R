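#' @include model-core.R
NULL

#' Iterative dead-end metabolite analysis
#'
#' A non-boundary metabolite is a dead end when, under the reaction
#' directions admissible for the current bounds, it can only be produced,
#' only be consumed, or is touched by a single reaction overall (a lone
#' reaction, reversible or not, cannot balance a metabolite it carries a
#' nonzero coefficient for: \eqn{S_{mj} v_j = 0} forces \eqn{v_j = 0}).
#' All reactions touching a dead-end metabolite provably carry zero flux
#' in every steady state, so they are blocked (bounds forced to zero) and
#' the analysis repeats until a fixpoint.  Used standalone as a model
#' report and as preprocessing that shrinks every optimization problem
#' without changing its optimum.
#'
#' @param model A [MetabolicModel-class].
#' @param scen A [Scenario-class]; its bounds decide admissible
#'   directions (a reversible reaction confined to \eqn{[0, u]} counts as
#'   forward-only).
#' @param tol Bound magnitude below which a direction counts as closed.
#' @return A [DeadEndReport-class].
#'
#' @examples
#' toy <- makeFixture("TOY_DEAD")
#' findDeadEnds(toy$model, toy$scenario)
#' @export
findDeadEnds <- function(model, scen = scenario(), tol = 1e-9) {
    bounds <- resolveBounds(model, scen)
    lower <- bounds$lower
    upper <- bounds$upper
    S <- stoichiometricMatrix(model)           # non-boundary rows only
    mids <- rownames(S)
    rids <- reactions(model)$id
    aliveMet <- rep(TRUE, length(mids))
    aliveRxn <- stats::setNames(upper > tol | lower < -tol, rids)
    iterations <- list()
    repeat {
        canFwd <- upper > tol
        canBwd <- lower < -tol
        dead <- character()
        for (i in which(aliveMet)) {
            row <- S[i, ]
            touch <- which(row != 0 & (canFwd | canBwd))
            if (length(touch) == 0L) { dead <- c(dead, mids[i]); next }
            producers <- any(row[touch] > 0 & canFwd[touch]) ||
                any(row[touch] < 0 & canBwd[touch])
            consumers <- any(row[touch] < 0 & canFwd[touch]) ||
                any(row[touch] > 0 & canBwd[touch])
            if (!producers || !consumers || length(touch) == 1L) {
                dead <- c(dead, mids[i])
            }
        }
        if (!length(dead)) break
        blocked <- character()
        for (m in dead) {
            row <- S[match(m, mids), ]
            hit <- rids[row != 0 & (canFwd | canBwd)]
            blocked <- union(blocked, hit)
        }
        blocked <- sort(blocked)
        lower[blocked] <- 0
        upper[blocked] <- 0
        aliveMet[match(dead, mids)] <- FALSE
        iterations[[length(iterations) + 1L]] <- list(
            deadMetabolites = sort(dead),
            blockedReactions = blocked
        )
        if (length(iterations) > length(mids)) {
            stop("dead-end analysis failed to terminate")  # cannot happen
        }
    }
    new("DeadEndReport",
        iterations = iterations,
        totalBlocked = sort(unique(as.character(unlist(
            lapply(iterations, `[[`, "blockedReactions")
        )))),
        totalDead = sort(unique(as.character(unlist(
            lapply(iterations, `[[`, "deadMetabolites")
        ))))
    )
}

#' Apply a dead-end report to a scenario
#'
#' Returns a copy of the scenario in which every blocked reaction is
#' pinned to \eqn{[0, 0]}; all other bounds are untouched.  Because
#' blocked reactions are flux-zero in every steady state, the reduced
#' scenario has exactly the same feasible flux distributions.
#'
#' @param model The model the report was computed on.
#' @param scen The [Scenario-class] to reduce.
#' @param report A [DeadEndReport-class] from [findDeadEnds()].
#' @return The reduced [Scenario-class].
#' @export
reduceScenario <- function(model, scen, report) {
    unknown <- setdiff(report@totalBlocked, reactions(model)$id)
    if (length(unknown)) {
        stop("dead-end report references unknown reactions: ",
             paste(unknown, collapse = ", "))
    }
    if (!length(report@totalBlocked)) {
        return(scen)
    }
    lb <- scen@lowerBound
    ub <- scen@upperBound
    for (r in report@totalBlocked) {
        ## a blocked reaction is provably flux-zero in every steady
        ## state; if the scenario explicitly excludes zero flux the
        ## scenario is infeasible, and pinning to [0,0] would wrongly
        ## repair it -- leave such bounds alone so the optimizer still
        ## reports infeasibility
        lbr <- if (r %in% names(lb)) lb[[r]] else NA_real_
        ubr <- if (r %in% names(ub)) ub[[r]] else NA_real_
        if ((!is.na(lbr) && lbr > 0) || (!is.na(ubr) && ubr < 0)) next
        lb[r] <- 0
        ub[r] <- 0
    }
    new("Scenario",
        lowerBound = lb, upperBound = ub,
        objectiveReaction = scen@objectiveReaction,
        objectiveDirection = scen@objectiveDirection
    )
}
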