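#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Matrix dgCMatrix
NULL

#' MetabolicModel: a stoichiometric reaction network
#'
#' The central data container of the package: an ordered collection of
#' metabolites, an ordered collection of reactions, and the sparse
#' stoichiometric matrix that ties them together.  Negative coefficients
#' denote substrates, positive coefficients products.  Metabolites flagged
#' as \code{boundary} are exempt from the steady-state constraint
#' \eqn{S v = 0} and obtain no row in [stoichiometricMatrix()].
#'
#' @slot metabolites A [S4Vectors::DataFrame] with columns \code{id}
#'   (unique, non-empty, no whitespace), \code{name} (free text, defaults
#'   to the id) and \code{boundary} (logical).
#' @slot reactions A [S4Vectors::DataFrame] with columns \code{id}
#'   (unique), \code{reversible} (logical), \code{deltaG} (numeric,
#'   kJ/mol, \code{NA} when unknown) and \code{annotation} (character).
#' @slot stoichiometry A sparse \code{dgCMatrix} with one row per
#'   metabolite and one column per reaction, in slot order; dimnames carry
#'   the ids.
#'
#' @seealso [parseReactionFile()], [stoichiometricMatrix()], [fba()]
#' @export
setClass("MetabolicModel",
    slots = c(
        metabolites = "DataFrame",
        reactions = "DataFrame",
        stoichiometry = "dgCMatrix"
    )
)

setValidity("MetabolicModel", function(object) {
    msgs <- character()
    met <- object@metabolites
    rxn <- object@reactions
    S <- object@stoichiometry
    for (col in c("id", "name", "boundary")) {
        if (!col %in% colnames(met)) {
            msgs <- c(msgs, sprintf("metabolites lack column '%s'", col))
        }
    }
    for (col in c("id", "reversible", "deltaG", "annotation")) {
        if (!col %in% colnames(rxn)) {
            msgs <- c(msgs, sprintf("reactions lack column '%s'", col))
        }
    }
    if (length(msgs)) {
        return(msgs)
    }
    if (anyDuplicated(met$id)) {
        msgs <- c(msgs, "metabolite ids must be unique")
    }
    if (anyDuplicated(rxn$id)) {
        msgs <- c(msgs, "reaction ids must be unique")
    }
    if (any(!nzchar(met$id)) || any(grepl("[[:space:]]", met$id))) {
        msgs <- c(msgs, "metabolite ids must be non-empty tokens without whitespace")
    }
    if (any(!nzchar(rxn$id)) || any(grepl("[[:space:]]", rxn$id))) {
        msgs <- c(msgs, "reaction ids must be non-empty tokens without whitespace")
    }
    if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn)) {
        msgs <- c(msgs, "stoichiometry dimensions must match metabolite/reaction counts")
    } else if (nrow(met) > 0 && !identical(rownames(S), as.character(met$id))) {
        msgs <- c(msgs, "stoichiometry rownames must equal metabolite ids")
    } else if (nrow(rxn) > 0 && !identical(colnames(S), as.character(rxn$id))) {
        msgs <- c(msgs, "stoichiometry colnames must equal reaction ids")
    }
    if (length(msgs)) msgs else TRUE
})

#' Scenario: simulation constraints detached from the model
#'
#' A scenario holds per-reaction flux bounds and the objective
#' specification for one simulation, separate from the network itself so
#' that the same model can be simulated under many conditions.  Bounds are
#' sparse: reactions without an entry fall back to reversibility-derived
#' defaults (irreversible \eqn{[0, \infty)}, reversible
#' \eqn{(-\infty, \infty)}) when the scenario is applied to a model.
#'
#' @slot lowerBound Named numeric vector of explicit lower bounds
#'   (\code{-Inf} allowed).
#' @slot upperBound Named numeric vector of explicit upper bounds
#'   (\code{Inf} allowed).
#' @slot objectiveReaction Character of length 0 or 1: the reaction whose
#'   flux is optimized.
#' @slot objectiveDirection \code{"max"} or \code{"min"}.
#'
#' @seealso [parseScenarioFile()], [resolveBounds()], [fba()]
#' @export
setClass("Scenario",
    slots = c(
        lowerBound = "numeric",
        upperBound = "numeric",
        objectiveReaction = "character",
        objectiveDirection = "character"
    )
)

setValidity("Scenario", function(object) {
    msgs <- character()
    if (length(object@objectiveReaction) > 1) {
        msgs <- c(msgs, "at most one objective reaction is supported")
    }
    if (!object@objectiveDirection %in% c("max", "min")) {
        msgs <- c(msgs, "objective direction must be 'max' or 'min'")
    }
    if (length(object@lowerBound) && is.null(names(object@lowerBound))) {
        msgs <- c(msgs, "lower bounds must be named by reaction id")
    }
    if (length(object@upperBound) && is.null(names(object@upperBound))) {
        msgs <- c(msgs, "upper bounds must be named by reaction id")
    }
    ## note: lower <= upper is deliberately NOT checked here; scenarios
    ## are validated against a model at application time (resolveBounds),
    ## so contradictory files parse and fail only when used
    if (length(msgs)) msgs else TRUE
})

#' FluxDistribution: one steady-state flux vector
#'
#' The result of a single optimization: a flux value per reaction (by
#' convention in mmol per gram cell dry weight per hour), the achieved
#' objective value, and the solver status.  Fluxes are only present when
#' the status is \code{"optimal"}.
#'
#' @slot fluxes Named numeric vector, one entry per reaction.
#' @slot objectiveValue Objective at the optimum (\code{NA} otherwise).
#' @slot status One of \code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}.
#' @slot metadata List of provenance entries (solver, objective fraction,
#'   preprocessing applied, ...).
#'
#' @seealso [fba()], [moma()], [splitRatios()]
#' @export
setClass("FluxDistribution",
    slots = c(
        fluxes = "numeric",
        objectiveValue = "numeric",
        status = "character",
        metadata = "list"
    )
)

setValidity("FluxDistribution", function(object) {
    msgs <- character()
    if (!object@status %in% c("optimal", "infeasible", "unbounded")) {
        msgs <- c(msgs, "status must be optimal, infeasible or unbounded")
    }
    if (object@status == "optimal" && length(object@fluxes) == 0) {
        msgs <- c(msgs, "optimal distributions must carry fluxes")
    }
    if (object@status != "optimal" && length(object@fluxes) > 0) {
        msgs <- c(msgs, "non-optimal distributions must not carry fluxes")
    }
    if (length(object@fluxes) && is.null(names(object@fluxes))) {
        msgs <- c(msgs, "fluxes must be named by reaction id")
    }
    if (length(msgs)) msgs else TRUE
})

#' VariabilityResult: flux ranges from flux variability analysis
#'
#' Per-reaction minimal and maximal fluxes attainable while the objective
#' is held at a fraction \eqn{\gamma} of its optimum.
#'
#' @slot ranges A [S4Vectors::DataFrame] with columns \code{reaction},
#'   \code{minFlux}, \code{maxFlux}.
#' @slot fraction The objective fraction \eqn{\gamma \in (0, 1]} used, or
#'   \code{NA} when no objective constraint was applied.
#' @slot metadata Provenance list.
#'
#' @seealso [fva()]
#' @export
setClass("VariabilityResult",
    slots = c(
        ranges = "DataFrame",
        fraction = "numeric",
        metadata = "list"
    )
)

setValidity("VariabilityResult", function(object) {
    msgs <- character()
    rg <- object@ranges
    need <- c("reaction", "minFlux", "maxFlux")
    if (!all(need %in% colnames(rg))) {
        return("ranges must have columns reaction, minFlux, maxFlux")
    }
    if (nrow(rg) && any(rg$minFlux > rg$maxFlux + 1e-9, na.rm = TRUE)) {
        msgs <- c(msgs, "minFlux must not exceed maxFlux")
    }
    if (length(msgs)) msgs else TRUE
})

#' DeadEndReport: iterations of dead-end metabolite detection
#'
#' Records which metabolites were identified as dead ends and which
#' reactions were blocked in each sweep of the iterative analysis, plus
#' the union of all blocked reactions.
#'
#' @slot iterations List; element i is a list with character vectors
#'   \code{deadMetabolites} and \code{blockedReactions} found in sweep i.
#' @slot totalBlocked Character vector: union of all blocked reactions.
#' @slot totalDead Character vector: union of all dead-end metabolites.
#'
#' @seealso [findDeadEnds()], [reduceScenario()]
#' @export
setClass("DeadEndReport",
    slots = c(
        iterations = "list",
        totalBlocked = "character",
        totalDead = "character"
    )
)

setValidity("DeadEndReport", function(object) {
    allBlocked <- unlist(lapply(object@iterations, `[[`, "blockedReactions"))
    allDead <- unlist(lapply(object@iterations, `[[`, "deadMetabolites"))
    msgs <- character()
    if (anyDuplicated(allBlocked)) {
        msgs <- c(msgs, "iteration blocked-reaction sets must be disjoint")
    }
    if (anyDuplicated(allDead)) {
        msgs <- c(msgs, "iteration dead-metabolite sets must be disjoint")
    }
    if (!setequal(allBlocked, object@totalBlocked)) {
        msgs <- c(msgs, "totalBlocked must be the union over iterations")
    }
    if (length(msgs)) msgs else TRUE
})

#' MetaboliteFluxReport: minimal producing fluxes per metabolite
#'
#' Output of metabolite flux minimization: for each non-boundary
#' metabolite, the smallest total producing flux compatible with the
#' objective held at a fraction \eqn{\gamma} of its optimum.  A metabolite
#' whose minimal producing flux exceeds the tolerance is essential for
#' that level of objective attainment.
#'
#' @slot table [S4Vectors::DataFrame] with columns \code{metabolite},
#'   \code{minFlux} (mmol gCDW\eqn{^{-1}} h\eqn{^{-1}}), \code{essential}.
#' @slot fraction Objective fraction \eqn{\gamma} used.
#' @slot tolerance Essentiality threshold on the minimal flux.
#'
#' @seealso [mfm()], [essentialPartition()], [rankMetabolites()]
#' @export
setClass("MetaboliteFluxReport",
    slots = c(
        table = "DataFrame",
        fraction = "numeric",
        tolerance = "numeric"
    )
)

setValidity("MetaboliteFluxReport", function(object) {
    tb <- object@table
    need <- c("metabolite", "minFlux", "essential")
    if (!all(need %in% colnames(tb))) {
        return("table must have columns metabolite, minFlux, essential")
    }
    if (nrow(tb) && any(tb$minFlux < -1e-9, na.rm = TRUE)) {
        return("minimal producing fluxes must be nonnegative")
    }
    TRUE
})

#' SplitRatioTable: producer/consumer decomposition at metabolite nodes
#'
#' For one realized flux state, each metabolite's turnover (total
#' producing flux) and the decomposition of production and consumption
#' into contributing reactions, as absolute fluxes and percentages.
#'
#' @slot table [S4Vectors::DataFrame] with columns \code{metabolite},
#'   \code{turnover}, \code{reaction}, \code{direction}
#'   (\code{"producer"}/\code{"consumer"}), \code{flux}, \code{percent}.
#' @slot metadata Provenance list (solver, objective fraction, tolerance).
#'
#' @seealso [splitRatios()], [exportBipartiteGraph()]
#' @export
setClass("SplitRatioTable",
    slots = c(
        table = "DataFrame",
        metadata = "list"
    )
)

setValidity("SplitRatioTable", function(object) {
    tb <- object@table
    need <- c("metabolite", "turnover", "reaction", "direction", "flux", "percent")
    if (!all(need %in% colnames(tb))) {
        return("table must have columns metabolite, turnover, reaction, direction, flux, percent")
    }
    if (nrow(tb) && !all(tb$direction %in% c("producer", "consumer"))) {
        return("direction must be 'producer' or 'consumer'")
    }
    TRUE
})

#' PlausibilityReport: findings of the automated model checks
#'
#' @slot findings [S4Vectors::DataFrame] with columns \code{severity}
#'   (\code{"error"}/\code{"warning"}), \code{code}, \code{subject},
#'   \code{message}, ordered by code then subject for determinism.
#'
#' @seealso [checkPlausibility()]
#' @export
setClass("PlausibilityReport",
    slots = c(findings = "DataFrame")
)

setValidity("PlausibilityReport", function(object) {
    fd <- object@findings
    need <- c("severity", "code", "subject", "message")
    if (!all(need %in% colnames(fd))) {
        return("findings must have columns severity, code, subject, message")
    }
    if (nrow(fd) && !all(fd$severity %in% c("error", "warning"))) {
        return("severity must be 'error' or 'warning'")
    }
    TRUE
})
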