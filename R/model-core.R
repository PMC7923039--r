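#' @include AllGenerics.R
NULL

## Finite stand-in for infinite bounds handed to back-ends that cannot
## take IEEE infinities (documented constant; internally bounds stay Inf).
BIG_BOUND <- 1e6

#' Construct a metabolic model from reaction stoichiometries
#'
#' Low-level constructor used by the file readers and the fixture
#' generator.  Metabolites are registered in order of first mention;
#' boundary metabolites are exempt from the steady-state constraint.
#'
#' @param reactions Named list; one element per reaction, each a list with
#'   \code{stoich} (named numeric: metabolite id to signed coefficient,
#'   negative = substrate), \code{reversible} (logical, default
#'   \code{FALSE}), optional \code{deltaG} (kJ/mol) and \code{annotation}.
#' @param boundary Character vector of metabolite ids to flag as boundary.
#' @param metaboliteNames Optional named character: metabolite id to
#'   display name (defaults to the id).
#' @return A validated [MetabolicModel-class].
#'
#' @examples
#' m <- metabolicModel(list(
#'     upt = list(stoich = c(A = 1)),
#'     conv = list(stoich = c(A = -1, B = 1)),
#'     bio = list(stoich = c(B = -1))
#' ))
#' nReactions(m)
#' @export
metabolicModel <- function(reactions, boundary = character(),
                           metaboliteNames = character()) {
    stopifnot(is.list(reactions))
    rids <- names(reactions)
    if (is.null(rids) || any(!nzchar(rids))) {
        stop("every reaction must be named")
    }
    if (anyDuplicated(rids)) {
        stop("duplicate reaction id: ", rids[duplicated(rids)][1L])
    }
    mids <- character()
    for (r in reactions) {
        st <- r$stoich
        if (length(st)) {
            if (is.null(names(st)) || any(!nzchar(names(st)))) {
                stop("stoichiometries must be named by metabolite id")
            }
            if (any(st == 0)) {
                stop("stoichiometric coefficients must be nonzero")
            }
            mids <- c(mids, setdiff(names(st), mids))
        }
    }
    mids <- c(mids, setdiff(boundary, mids))
    nm <- length(mids)
    nr <- length(reactions)
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (j in seq_len(nr)) {
        st <- reactions[[j]]$stoich
        if (length(st)) {
            ii <- c(ii, match(names(st), mids))
            jj <- c(jj, rep.int(j, length(st)))
            xx <- c(xx, as.numeric(st))
        }
    }
    S <- Matrix::sparseMatrix(
        i = ii, j = jj, x = xx, dims = c(nm, nr),
        dimnames = list(mids, rids)
    )
    nms <- mids
    hit <- match(mids, names(metaboliteNames))
    nms[!is.na(hit)] <- metaboliteNames[hit[!is.na(hit)]]
    pick <- function(field, default) {
        vapply(reactions, function(r) {
            v <- r[[field]]
            if (is.null(v)) default else v
        }, default)
    }
    new("MetabolicModel",
        metabolites = DataFrame(
            id = mids, name = nms, boundary = mids %in% boundary
        ),
        reactions = DataFrame(
            id = rids,
            reversible = pick("reversible", FALSE),
            deltaG = pick("deltaG", NA_real_),
            annotation = pick("annotation", NA_character_)
        ),
        stoichiometry = methods::as(S, "CsparseMatrix")
    )
}

#' Construct a simulation scenario
#'
#' @param objective Reaction id to optimize (length 0 for none yet).
#' @param direction \code{"max"} or \code{"min"}.
#' @param lowerBounds,upperBounds Named numeric vectors of explicit
#'   bounds; reactions without an entry use reversibility-derived defaults
#'   when the scenario is applied to a model.
#' @return A validated [Scenario-class].
#'
#' @examples
#' scn <- scenario("bio", upperBounds = c(upt = 10))
#' objective(scn)
#' @export
scenario <- function(objective = character(), direction = "max",
                     lowerBounds = numeric(), upperBounds = numeric()) {
    new("Scenario",
        lowerBound = lowerBounds, upperBound = upperBounds,
        objectiveReaction = as.character(objective),
        objectiveDirection = direction
    )
}

#' @describeIn metabolicModel Stoichiometry of one reaction as a named
#'   numeric vector (substrates negative).
#' @param model A [MetabolicModel-class].
#' @param reaction A reaction id.
#' @export
reactionStoichiometry <- function(model, reaction) {
    j <- match(reaction, reactions(model)$id)
    if (is.na(j)) stop("unknown reaction: ", reaction)
    col <- model@stoichiometry[, j]
    col[col != 0]
}

## ---- accessor methods -----------------------------------------------------

#' @rdname model-accessors
#' @export
setMethod("metabolites", "MetabolicModel", function(object, ...) {
    object@metabolites
})

#' @rdname model-accessors
#' @export
setMethod("reactions", "MetabolicModel", function(object, ...) {
    object@reactions
})

#' @rdname model-accessors
#' @export
setMethod("nMetabolites", "MetabolicModel", function(object) {
    nrow(object@metabolites)
})

#' @rdname model-accessors
#' @export
setMethod("nReactions", "MetabolicModel", function(object) {
    nrow(object@reactions)
})

#' @rdname model-accessors
#' @param includeBoundary Keep rows for boundary metabolites?  They are
#'   dropped by default because boundary metabolites carry no steady-state
#'   constraint.
#' @export
setMethod("stoichiometricMatrix", "MetabolicModel",
    function(object, includeBoundary = FALSE) {
        S <- object@stoichiometry
        if (!includeBoundary && any(object@metabolites$boundary)) {
            S <- S[!object@metabolites$boundary, , drop = FALSE]
        }
        S
    }
)

#' @rdname scenario-accessors
#' @export
setMethod("objective", "Scenario", function(object) {
    if (length(object@objectiveReaction) == 0) {
        return(list())
    }
    list(
        reaction = object@objectiveReaction,
        direction = object@objectiveDirection
    )
})

#' @rdname result-accessors
#' @export
setMethod("fluxes", "FluxDistribution", function(object) object@fluxes)

#' @rdname result-accessors
#' @export
setMethod("objectiveValue", "FluxDistribution", function(object) {
    object@objectiveValue
})

#' @rdname result-accessors
#' @export
setMethod("solverStatus", "FluxDistribution", function(object) object@status)

#' @rdname result-accessors
#' @export
setMethod("resultTable", "VariabilityResult", function(object) object@ranges)

#' @rdname result-accessors
#' @export
setMethod("resultTable", "MetaboliteFluxReport", function(object) object@table)

#' @rdname result-accessors
#' @export
setMethod("resultTable", "SplitRatioTable", function(object) object@table)

#' @rdname result-accessors
#' @export
setMethod("resultTable", "PlausibilityReport", function(object) {
    object@findings
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "MetabolicModel", function(object) {
    cat(sprintf(
        "MetabolicModel with %d metabolites (%d boundary) and %d reactions (%d reversible)\n",
        nMetabolites(object), sum(object@metabolites$boundary),
        nReactions(object), sum(object@reactions$reversible)
    ))
})

setMethod("show", "Scenario", function(object) {
    obj <- objective(object)
    cat("Scenario:",
        if (length(obj)) sprintf("%s %s;", obj$direction, obj$reaction)
        else "no objective;",
        sprintf(
            "%d explicit lower, %d explicit upper bounds\n",
            length(object@lowerBound), length(object@upperBound)
        ))
})

setMethod("show", "FluxDistribution", function(object) {
    cat(sprintf(
        "FluxDistribution (%s): objective %s over %d reactions\n",
        object@status, format(object@objectiveValue), length(object@fluxes)
    ))
})

setMethod("show", "VariabilityResult", function(object) {
    cat(sprintf(
        "VariabilityResult over %d reactions (objective fraction %s)\n",
        nrow(object@ranges),
        if (is.na(object@fraction)) "none" else format(object@fraction)
    ))
})

setMethod("show", "DeadEndReport", function(object) {
    cat(sprintf(
        "DeadEndReport: %d iterations, %d dead-end metabolites, %d blocked reactions\n",
        length(object@iterations), length(object@totalDead),
        length(object@totalBlocked)
    ))
})

setMethod("show", "MetaboliteFluxReport", function(object) {
    cat(sprintf(
        "MetaboliteFluxReport (gamma = %s): %d metabolites, %d essential\n",
        format(object@fraction), nrow(object@table),
        sum(object@table$essential)
    ))
})

setMethod("show", "SplitRatioTable", function(object) {
    cat(sprintf(
        "SplitRatioTable: %d producer/consumer entries over %d metabolites\n",
        nrow(object@table), length(unique(object@table$metabolite))
    ))
})

setMethod("show", "PlausibilityReport", function(object) {
    fd <- object@findings
    cat(sprintf(
        "PlausibilityReport: %d errors, %d warnings\n",
        sum(fd$severity == "error"), sum(fd$severity == "warning")
    ))
})

## ---- bounds resolution ----------------------------------------------------

#' Resolve a scenario against a model into full bound vectors
#'
#' Applies reversibility-derived defaults (irreversible \eqn{[0, Inf)},
#' reversible \eqn{(-Inf, Inf)}) and overlays the scenario's explicit
#' bounds.  This is the single place where the deferred scenario
#' invariants are enforced: unknown reaction ids and lower bounds above
#' upper bounds raise errors here, at application time.
#'
#' @param model A [MetabolicModel-class].
#' @param scen A [Scenario-class].
#' @return List with named numeric vectors \code{lower} and \code{upper},
#'   one entry per reaction of the model.
#' @export
resolveBounds <- function(model, scen) {
    rxn <- reactions(model)
    lower <- ifelse(rxn$reversible, -Inf, 0)
    upper <- rep(Inf, nrow(rxn))
    names(lower) <- names(upper) <- rxn$id
    unknown <- setdiff(
        c(names(scen@lowerBound), names(scen@upperBound)), rxn$id
    )
    if (length(unknown)) {
        stop("scenario bounds reference unknown reactions: ",
             paste(unknown, collapse = ", "))
    }
    lower[names(scen@lowerBound)] <- scen@lowerBound
    upper[names(scen@upperBound)] <- scen@upperBound
    bad <- names(lower)[lower > upper]
    if (length(bad)) {
        stop("lower bound exceeds upper bound for: ",
             paste(bad, collapse = ", "))
    }
    list(lower = lower, upper = upper)
}

## ---- irreversible split ---------------------------------------------------

#' Split reversible reactions into irreversible forward/backward pairs
#'
#' Every reaction flagged reversible is replaced by an irreversible
#' forward copy (same stoichiometry, suffix \code{__fwd}) and a backward
#' copy (negated stoichiometry, suffix \code{__bwd}); irreversible
#' reactions are kept unchanged.  The net flux of an original reversible
#' reaction is recovered as \eqn{v = v_{fwd} - v_{bwd}}.  The split makes
#' all fluxes nonnegative, which is what renders a metabolite's total
#' producing flux a linear function of the flux vector (the precondition
#' of metabolite flux minimization).
#'
#' @param model A [MetabolicModel-class].
#' @return List with elements \code{model} (the split model, all
#'   reactions irreversible) and \code{mapping}: a [S4Vectors::DataFrame]
#'   with columns \code{original}, \code{forward}, \code{backward}
#'   (\code{backward} is \code{NA} for reactions that were not split).
#'
#' @examples
#' toy <- makeFixture("TOY_REV")
#' sp <- toIrreversible(toy$model)
#' nReactions(sp$model)
#' @export
toIrreversible <- function(model) {
    rxn <- reactions(model)
    S <- model@stoichiometry
    specs <- list()
    orig <- character(); fwd <- character(); bwd <- character()
    for (j in seq_len(nrow(rxn))) {
        st <- S[, j]
        st <- st[st != 0]
        id <- rxn$id[j]
        if (rxn$reversible[j]) {
            fid <- paste0(id, "__fwd")
            bid <- paste0(id, "__bwd")
            specs[[fid]] <- list(stoich = st, reversible = FALSE,
                                 annotation = rxn$annotation[j])
            specs[[bid]] <- list(stoich = -st, reversible = FALSE,
                                 annotation = rxn$annotation[j])
            orig <- c(orig, id); fwd <- c(fwd, fid); bwd <- c(bwd, bid)
        } else {
            specs[[id]] <- list(stoich = st, reversible = FALSE,
                                deltaG = rxn$deltaG[j],
                                annotation = rxn$annotation[j])
            orig <- c(orig, id); fwd <- c(fwd, id); bwd <- c(bwd, NA_character_)
        }
    }
    split <- metabolicModel(
        specs,
        boundary = metabolites(model)$id[metabolites(model)$boundary],
        metaboliteNames = stats::setNames(
            metabolites(model)$name, metabolites(model)$id
        )
    )
    list(
        model = split,
        mapping = DataFrame(original = orig, forward = fwd, backward = bwd)
    )
}

#' Map a flux vector of a split model back to net fluxes
#'
#' @param splitFluxes Named numeric over the split model's reactions.
#' @param mapping The mapping returned by [toIrreversible()].
#' @return Named numeric over the original reaction ids
#'   (\eqn{v = v_{fwd} - v_{bwd}}).
#' @export
netFluxes <- function(splitFluxes, mapping) {
    v <- splitFluxes[mapping$forward]
    back <- !is.na(mapping$backward)
    v[back] <- v[back] - splitFluxes[mapping$backward[back]]
    stats::setNames(as.numeric(v), mapping$original)
}

#' Translate scenario bounds onto a split model
#'
#' Given resolved bounds of the original model, produces bounds for the
#' irreversible split: a reaction with bounds \eqn{[l, u]} maps to forward
#' bounds \eqn{[\max(0, l), \max(0, u)]} and backward bounds
#' \eqn{[\max(0, -u), \max(0, -l)]}, so the reachable net fluxes are
#' unchanged.
#'
#' @param bounds List \code{lower}/\code{upper} from [resolveBounds()].
#' @param mapping Mapping from [toIrreversible()].
#' @return List \code{lower}/\code{upper} over the split reaction ids.
#' @export
splitBounds <- function(bounds, mapping) {
    ids <- c(mapping$forward, mapping$backward[!is.na(mapping$backward)])
    lower <- stats::setNames(numeric(length(ids)), ids)
    upper <- lower
    for (k in seq_len(nrow(mapping))) {
        l <- bounds$lower[[mapping$original[k]]]
        u <- bounds$upper[[mapping$original[k]]]
        f <- mapping$forward[k]
        if (is.na(mapping$backward[k])) {
            if (l < 0) {
                stop("negative lower bound on irreversible reaction '",
                     mapping$original[k],
                     "': mark it reversible to allow backward flux")
            }
            lower[f] <- l; upper[f] <- u
        } else {
            b <- mapping$backward[k]
            lower[f] <- max(0, l); upper[f] <- max(0, u)
            lower[b] <- max(0, -u); upper[b] <- max(0, -l)
        }
    }
    list(lower = lower, upper = upper)
}
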