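#' @include model-core.R
NULL

#' Import a COBRA-style JSON model
#'
#' Reads the single-objective subset of the de-facto standard COBRA JSON
#' dialect: top-level \code{metabolites} and \code{reactions} arrays,
#' each reaction with a \code{metabolites} coefficient map,
#' \code{lower_bound}, \code{upper_bound} and
#' \code{objective_coefficient}.  A negative lower bound marks the
#' reaction reversible; the single reaction with a nonzero objective
#' coefficient becomes the scenario's (maximization) objective.
#'
#' @param pathOrText A file path or a JSON string.
#' @return List with elements \code{model} and \code{scenario}.
#'
#' @examples
#' txt <- '{"metabolites": [{"id": "A"}],
#'          "reactions": [{"id": "upt", "metabolites": {"A": 1},
#'                         "lower_bound": 0, "upper_bound": 10,
#'                         "objective_coefficient": 1}]}'
#' convertJSON(txt)$model
#' @export
convertJSON <- function(pathOrText) {
    doc <- jsonlite::fromJSON(pathOrText, simplifyVector = FALSE)
    if (is.null(doc$reactions)) {
        stop("JSON model lacks a 'reactions' key")
    }
    metNames <- character(0)
    for (m in doc$metabolites) {
        if (!is.null(m$id)) {
            metNames[m$id] <- if (!is.null(m$name)) m$name else m$id
        }
    }
    specs <- list()
    lb <- numeric(0)
    ub <- numeric(0)
    objRxn <- character(0)
    for (r in doc$reactions) {
        if (is.null(r$id)) stop("reaction without an 'id' in JSON model")
        st <- vapply(r$metabolites, as.numeric, numeric(1))
        st <- st[st != 0]
        lo <- if (!is.null(r$lower_bound)) as.numeric(r$lower_bound) else 0
        hi <- if (!is.null(r$upper_bound)) as.numeric(r$upper_bound) else Inf
        specs[[r$id]] <- list(
            stoich = st, reversible = lo < 0,
            annotation = if (!is.null(r$gene_reaction_rule) &&
                             nzchar(r$gene_reaction_rule)) {
                r$gene_reaction_rule
            } else {
                NA_character_
            }
        )
        lb[r$id] <- lo
        ub[r$id] <- hi
        oc <- if (!is.null(r$objective_coefficient)) {
            as.numeric(r$objective_coefficient)
        } else {
            0
        }
        if (oc != 0) objRxn <- c(objRxn, r$id)
    }
    if (length(objRxn) > 1L) {
        stop("multiple nonzero objective coefficients; ",
             "multi-objective models are not supported")
    }
    model <- metabolicModel(specs, metaboliteNames = metNames)
    scen <- new("Scenario", lowerBound = lb, upperBound = ub,
                objectiveReaction = objRxn, objectiveDirection = "max")
    list(model = model, scenario = scen)
}

#' Export a model and scenario as COBRA-style JSON
#'
#' @param model A [MetabolicModel-class].
#' @param scen A [Scenario-class].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writeCobraJSON <- function(model, scen, file) {
    bounds <- resolveBounds(model, scen)
    met <- metabolites(model)
    rxn <- reactions(model)
    obj <- objective(scen)
    cap <- function(v) pmin(pmax(v, -BIG_BOUND), BIG_BOUND)
    mets <- lapply(seq_len(nrow(met)), function(i) {
        list(id = met$id[i], name = met$name[i], compartment = "default")
    })
    rxns <- lapply(seq_len(nrow(rxn)), function(j) {
        st <- model@stoichiometry[, j]
        st <- st[st != 0]
        list(
            id = rxn$id[j],
            metabolites = as.list(st),
            lower_bound = cap(bounds$lower[[rxn$id[j]]]),
            upper_bound = cap(bounds$upper[[rxn$id[j]]]),
            objective_coefficient =
                if (length(obj) && obj$reaction == rxn$id[j]) 1 else 0
        )
    })
    jsonlite::write_json(
        list(id = "model", metabolites = mets, reactions = rxns),
        file, auto_unbox = TRUE, digits = NA
    )
    invisible(file)
}
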