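#' @include flux-analysis.R
NULL

#' Producing-flux coefficient vector of a metabolite
#'
#' On a model whose reactions are all irreversible (see
#' [toIrreversible()]), the total producing flux of a metabolite
#' \eqn{m} is the linear form \eqn{p_m(v) = \sum_j \max(S_{mj}, 0)
#' \, v_j}: only positive stoichiometric entries contribute, and because
#' all fluxes are nonnegative the form itself is nonnegative.  This
#' linearity is what turns per-metabolite flux minimization into a plain
#' linear program.
#'
#' @param splitModel A [MetabolicModel-class] with no reversible
#'   reactions (e.g. \code{toIrreversible(model)$model}).
#' @param metabolite A non-boundary metabolite id.
#' @return Named numeric coefficient vector over the model's reactions.
#'
#' @examples
#' toy <- makeFixture("TOY_LIN")
#' sp <- toIrreversible(toy$model)
#' producingFluxCoefficients(sp$model, "B")
#' @export
producingFluxCoefficients <- function(splitModel, metabolite) {
    if (any(reactions(splitModel)$reversible)) {
        stop("model still contains reversible reactions; apply toIrreversible() first")
    }
    met <- metabolites(splitModel)
    i <- match(metabolite, met$id)
    if (is.na(i)) stop("unknown metabolite: ", metabolite)
    if (met$boundary[i]) {
        stop("metabolite is boundary; producing flux is undefined: ",
             metabolite)
    }
    row <- splitModel@stoichiometry[i, ]
    stats::setNames(pmax(as.numeric(row), 0), reactions(splitModel)$id)
}

#' Metabolite flux minimization (MFM)
#'
#' The metabolite-centric counterpart of flux variability analysis.
#' After a standard FBA, the objective flux is constrained to a fraction
#' \eqn{\gamma} of its optimum (default 95\%), reversible reactions are
#' split so every flux is nonnegative, and for each metabolite the total
#' producing flux \eqn{p_m(v)} is successively minimized by linear
#' programming.  A metabolite whose minimum is zero is dispensable at
#' that level of objective attainment; a positive minimum marks it
#' essential.  As in [fva()], all LPs share one problem instance and
#' warm-start each other.
#'
#' @param model A [MetabolicModel-class].
#' @param scen A [Scenario-class] with an objective.
#' @param fraction Objective fraction \eqn{\gamma \in (0, 1]}.
#' @param metaboliteIds Subset of non-boundary metabolites (default: all).
#' @param reduce Apply dead-end preprocessing first?
#' @param warm Use warm starts (identical results either way).
#' @param tolerance Essentiality threshold on the minimal producing flux.
#' @return A [MetaboliteFluxReport-class].
#'
#' @examples
#' toy <- makeFixture("TOY_BRANCH")
#' resultTable(mfm(toy$model, toy$scenario, fraction = 0.95))
#' @export
mfm <- function(model, scen, fraction = 0.95, metaboliteIds = NULL,
                reduce = TRUE, warm = TRUE, tolerance = 1e-9) {
    if (!is.numeric(fraction) || length(fraction) != 1 ||
        fraction <= 0 || fraction > 1) {
        stop("fraction must lie in (0, 1]")
    }
    p <- .prepareProblem(model, scen, reduce)
    ref <- fba(model, p$scen, reduce = FALSE)
    if (solverStatus(ref) != "optimal") {
        stop("FBA is ", solverStatus(ref),
             "; metabolite flux minimization is undefined")
    }
    z <- objectiveValue(ref)

    sp <- toIrreversible(model)
    bounds <- splitBounds(p$bounds, sp$mapping)
    srids <- reactions(sp$model)$id
    Ssplit <- stoichiometricMatrix(sp$model)

    ## net objective flux held at >= gamma*z (max) / <= gamma*z (min)
    ## via one extra row with a signed slack variable
    arow <- stats::setNames(numeric(length(srids)), srids)
    k <- match(p$obj$reaction, sp$mapping$original)
    arow[sp$mapping$forward[k]] <- 1
    if (!is.na(sp$mapping$backward[k])) arow[sp$mapping$backward[k]] <- -1
    A <- rbind(as.matrix(Ssplit), arow)
    A <- cbind(A, c(numeric(nrow(Ssplit)), -1))   # slack column
    bvec <- c(numeric(nrow(Ssplit)), fraction * z)
    if (p$obj$direction == "max") {
        slackL <- 0; slackU <- Inf
    } else {
        slackL <- -Inf; slackU <- 0
    }
    lower <- c(bounds$lower, slackL)
    upper <- c(bounds$upper, slackU)

    met <- metabolites(model)
    ids <- if (is.null(metaboliteIds)) met$id[!met$boundary] else metaboliteIds
    unknown <- setdiff(ids, met$id)
    if (length(unknown)) {
        stop("unknown metabolites: ", paste(unknown, collapse = ", "))
    }
    if (any(met$boundary[match(ids, met$id)])) {
        stop("boundary metabolites have no producing flux: ",
             paste(ids[met$boundary[match(ids, met$id)]], collapse = ", "))
    }
    minFlux <- stats::setNames(rep(NA_real_, length(ids)), ids)
    state <- NULL
    for (m in ids) {
        cost <- c(producingFluxCoefficients(sp$model, m), 0)
        res <- solveLP(cost, A, bvec, lower, upper, "min",
                       warmStart = if (warm) state else NULL)
        if (res$status != "optimal") {
            stop("producing-flux minimization ", res$status, " for ", m)
        }
        state <- res$state
        minFlux[m] <- max(0, res$objective)   # clip solver noise at zero
    }
    new("MetaboliteFluxReport",
        table = DataFrame(metabolite = ids, minFlux = unname(minFlux),
                          essential = unname(minFlux) > tolerance),
        fraction = fraction, tolerance = tolerance)
}

#' Partition metabolites into essential and non-essential
#'
#' A metabolite is non-essential when its minimal producing flux does not
#' exceed the tolerance: the objective level can be sustained without
#' producing it at all.
#'
#' @param report A [MetaboliteFluxReport-class] from [mfm()].
#' @param tolerance Threshold on the minimal producing flux (defaults to
#'   the report's own tolerance).
#' @return List with character vectors \code{essential} and
#'   \code{nonEssential}; together they exhaust the report.
#' @export
essentialPartition <- function(report, tolerance = report@tolerance) {
    tb <- resultTable(report)
    ess <- tb$minFlux > tolerance
    list(
        essential = as.character(tb$metabolite[ess]),
        nonEssential = as.character(tb$metabolite[!ess])
    )
}

#' Rank metabolites by minimal producing flux
#'
#' @param report A [MetaboliteFluxReport-class].
#' @return A [S4Vectors::DataFrame] with columns \code{metabolite},
#'   \code{minFlux}, sorted by decreasing flux; ties broken
#'   lexicographically by metabolite id for determinism.
#' @export
rankMetabolites <- function(report) {
    tb <- resultTable(report)
    ord <- order(-tb$minFlux, tb$metabolite)
    DataFrame(metabolite = as.character(tb$metabolite[ord]),
              minFlux = tb$minFlux[ord])
}

#' Split-ratio analysis at metabolite nodes
#'
#' Decomposes one realized flux state at each metabolite: the
#' contribution of reaction \eqn{j} is \eqn{S_{mj} v_j}; positive
#' contributions are production, negative ones consumption (a reversible
#' reaction contributes per the sign of its net flux).  Turnover is the
#' total producing flux, percentages are contributions relative to total
#' production (producers) or total consumption (consumers), and at
#' steady state the two totals coincide for non-boundary metabolites.
#'
#' @param model A [MetabolicModel-class].
#' @param fluxDist A steady-state [FluxDistribution-class] over the
#'   model's reactions (e.g. from [fba()]).
#' @param metaboliteIds Metabolites to analyse (default: all non-boundary
#'   metabolites).
#' @param tol Contributions with magnitude at or below this are omitted.
#' @return A [SplitRatioTable-class].  Metabolites with zero turnover
#'   contribute no rows; per-metabolite turnover (including zeros) is in
#'   \code{metadata(x)$turnover}.
#'
#' @examples
#' toy <- makeFixture("PREPHENATE_BRANCH")
#' sr <- splitRatios(toy$model, fba(toy$model, toy$scenario))
#' subset(as.data.frame(resultTable(sr)), metabolite == "prephenate")
#' @export
splitRatios <- function(model, fluxDist, metaboliteIds = NULL, tol = 1e-9) {
    if (solverStatus(fluxDist) != "optimal") {
        stop("flux distribution is ", solverStatus(fluxDist))
    }
    v <- fluxes(fluxDist)
    rids <- reactions(model)$id
    if (!all(rids %in% names(v))) {
        stop("flux distribution must cover every reaction of the model")
    }
    v <- v[rids]
    S <- stoichiometricMatrix(model)
    resid <- if (nrow(S)) max(abs(as.numeric(S %*% v))) else 0
    if (resid > 1e-6) {
        stop("fluxes violate steady state (residual ", format(resid), ")")
    }
    met <- metabolites(model)
    ids <- if (is.null(metaboliteIds)) met$id[!met$boundary] else metaboliteIds
    unknown <- setdiff(ids, met$id)
    if (length(unknown)) {
        stop("unknown metabolites: ", paste(unknown, collapse = ", "))
    }
    Sfull <- model@stoichiometry
    rows <- list()
    turnover <- stats::setNames(numeric(length(ids)), ids)
    for (m in ids) {
        contrib <- as.numeric(Sfull[match(m, met$id), ]) * v
        names(contrib) <- rids
        prod <- contrib[contrib > tol]
        cons <- -contrib[contrib < -tol]
        to <- sum(prod)
        turnover[m] <- to
        if (length(prod)) {
            rows[[length(rows) + 1L]] <- DataFrame(
                metabolite = m, turnover = to, reaction = names(prod),
                direction = "producer", flux = unname(prod),
                percent = 100 * unname(prod) / to
            )
        }
        if (length(cons)) {
            rows[[length(rows) + 1L]] <- DataFrame(
                metabolite = m, turnover = to, reaction = names(cons),
                direction = "consumer", flux = unname(cons),
                percent = 100 * unname(cons) / sum(cons)
            )
        }
    }
    tb <- if (length(rows)) do.call(rbind, rows) else DataFrame(
        metabolite = character(0), turnover = numeric(0),
        reaction = character(0), direction = character(0),
        flux = numeric(0), percent = numeric(0)
    )
    new("SplitRatioTable", table = tb, metadata = list(
        turnover = turnover, tolerance = tol,
        provenance = fluxDist@metadata
    ))
}
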