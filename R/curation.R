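#' @include flux-analysis.R
NULL

## Canonical key for dictionary matching: trimmed, internal whitespace
## collapsed, case-folded.  No fuzzy matching.
.nameKey <- function(x) {
    tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

.modelSpecs <- function(model) {
    rxn <- reactions(model)
    lapply(stats::setNames(seq_len(nrow(rxn)), rxn$id), function(j) {
        st <- model@stoichiometry[, j]
        st <- st[st != 0]
        list(stoich = st, reversible = rxn$reversible[j],
             deltaG = rxn$deltaG[j], annotation = rxn$annotation[j])
    })
}

#' Load a synonym table from a two-column TSV
#'
#' Column 1: synonym, column 2: recommended name.  Recommended names are
#' added as identity entries so the mapping is idempotent; conflicting
#' entries (one synonym, two recommended names) raise an error.
#'
#' @param file Path to the TSV (no header).
#' @return Named character vector: canonical synonym key to recommended
#'   name.
#' @export
loadSynonymTable <- function(file) {
    tb <- utils::read.table(file, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "#")
    if (ncol(tb) < 2L) stop("synonym table needs two tab-separated columns")
    syn <- .nameKey(tb[[1L]])
    rec <- trimws(tb[[2L]])
    tab <- stats::setNames(rec, syn)
    tab[.nameKey(rec)] <- rec     # recommended names map to themselves
    dup <- split(unname(tab), names(tab))
    bad <- names(dup)[vapply(dup, function(v) length(unique(v)) > 1, logical(1))]
    if (length(bad)) {
        stop("synonym maps to multiple recommended names: ",
             paste(bad, collapse = ", "))
    }
    tab[!duplicated(names(tab))]
}

#' Normalize metabolite names against a synonym dictionary
#'
#' Every metabolite whose id or display name matches a synonym
#' (case-insensitively, after whitespace normalization) is renamed to the
#' recommended name.  When two formerly distinct metabolites collapse to
#' one recommended name their network nodes are merged: stoichiometric
#' rows are summed, and coefficients that cancel to zero are removed with
#' a logged warning.  Misspelled or synonymous metabolites otherwise
#' count as separate nodes, which silently disconnects pathways; this
#' check exists to catch exactly that.
#'
#' @param model A [MetabolicModel-class].
#' @param table Named character from [loadSynonymTable()] (or built in
#'   code: canonical synonym key to recommended name).
#' @return List with \code{model} (renamed/merged) and \code{log}, a
#'   [S4Vectors::DataFrame] with columns \code{event}
#'   (\code{rename}/\code{merge}/\code{coefficient_dropped}), \code{old},
#'   \code{new}.
#'
#' @examples
#' toy <- makeFixture("TOY_LIN")
#' normalizeNames(toy$model, c(a = "alpha"))$log
#' @export
normalizeNames <- function(model, table) {
    met <- metabolites(model)
    if (!length(table)) {
        return(list(model = model, log = DataFrame(
            event = character(0), old = character(0), new = character(0)
        )))
    }
    names(table) <- .nameKey(names(table))
    lookup <- function(id, nm) {
        k <- .nameKey(id)
        if (k %in% names(table)) return(table[[k]])
        k <- .nameKey(nm)
        if (k %in% names(table)) return(table[[k]])
        NA_character_
    }
    newName <- met$name
    newId <- met$id
    ev <- character(0); old <- character(0); nw <- character(0)
    for (i in seq_len(nrow(met))) {
        rec <- lookup(met$id[i], met$name[i])
        if (!is.na(rec)) {
            recId <- gsub("[[:space:]]+", "_", rec)
            if (recId != met$id[i]) {
                ev <- c(ev, "rename"); old <- c(old, met$id[i])
                nw <- c(nw, recId)
            }
            newId[i] <- recId
            newName[i] <- rec
        }
    }
    merged <- unique(newId[duplicated(newId)])
    for (m in merged) {
        ev <- c(ev, "merge")
        old <- c(old, paste(met$id[newId == m], collapse = "+"))
        nw <- c(nw, m)
    }
    specs <- .modelSpecs(model)
    rename <- stats::setNames(newId, met$id)
    for (r in names(specs)) {
        st <- specs[[r]]$stoich
        if (!length(st)) next
        names(st) <- rename[names(st)]
        agg <- tapply(st, names(st), sum)[unique(names(st))]
        st <- stats::setNames(as.numeric(agg), names(agg))
        zero <- abs(st) < 1e-12
        if (any(zero)) {
            for (z in names(st)[zero]) {
                ev <- c(ev, "coefficient_dropped")
                old <- c(old, paste(r, z, sep = ":"))
                nw <- c(nw, z)
                warning("merge cancels coefficient of '", z,
                        "' in reaction '", r, "'")
            }
            st <- st[!zero]
        }
        specs[[r]]$stoich <- st
    }
    keep <- !duplicated(newId)
    bnd <- stats::setNames(met$boundary, newId)[newId[keep]]
    out <- metabolicModel(
        specs,
        boundary = newId[keep][bnd],
        metaboliteNames = stats::setNames(newName[keep], newId[keep])
    )
    list(model = out, log = DataFrame(event = ev, old = old, new = nw))
}

## Exchange reactions have all coefficients of one sign (or one empty side).
.isExchange <- function(model) {
    apply(as.matrix(model@stoichiometry != 0) *
              sign(as.matrix(model@stoichiometry)), 2L, function(col) {
        s <- col[col != 0]
        length(s) == 0L || all(s > 0) || all(s < 0)
    })
}

#' Automated plausibility checks for a metabolic model
#'
#' Runs four deterministic checks and collects the findings:
#' \describe{
#'   \item{free_lunch (error)}{With every exchange reaction's import
#'     direction closed, the objective optimum must be zero; growth
#'     without any substrate indicates an inconsistent network.}
#'   \item{duplicate_reaction (warning)}{Reactions whose stoichiometries
#'     are identical up to scaling and sign.}
#'   \item{dead_end (warning)}{Dead-end metabolites (delegated to
#'     [findDeadEnds()]).}
#'   \item{unbounded_objective (warning)}{The scenario's objective is
#'     unbounded.}
#' }
#'
#' @param model A [MetabolicModel-class].
#' @param scen A [Scenario-class]; checks needing an objective are
#'   skipped (with a \code{no_objective} warning) when it has none.
#' @return A [PlausibilityReport-class]; findings are ordered by code
#'   then subject.
#'
#' @examples
#' toy <- makeFixture("TOY_DEAD")
#' resultTable(checkPlausibility(toy$model, toy$scenario))
#' @export
checkPlausibility <- function(model, scen = scenario()) {
    sev <- character(0); code <- character(0)
    subj <- character(0); msg <- character(0)
    add <- function(s, c2, su, m) {
        sev <<- c(sev, s); code <<- c(code, c2)
        subj <<- c(subj, su); msg <<- c(msg, m)
    }
    rxn <- reactions(model)
    hasObj <- length(objective(scen)) > 0

    ## (a) free lunch: close the import direction of every declared
    ## exchange (those the scenario explicitly bounds); the objective
    ## must then be zero.  An undeclared source reaction that can still
    ## sustain the objective is exactly the inconsistency this catches.
    if (hasObj) {
        exch <- which(.isExchange(model))
        declared <- union(names(scen@lowerBound), names(scen@upperBound))
        lb <- scen@lowerBound; ub <- scen@upperBound
        for (j in exch) {
            id <- rxn$id[j]
            if (!id %in% declared) next
            col <- model@stoichiometry[, j]
            s <- sign(col[col != 0])
            if (!length(s) || all(s > 0)) ub[id] <- 0 else lb[id] <- 0
        }
        closed <- new("Scenario", lowerBound = lb, upperBound = ub,
                      objectiveReaction = scen@objectiveReaction,
                      objectiveDirection = scen@objectiveDirection)
        fd <- tryCatch(fba(model, closed), error = function(e) NULL)
        if (!is.null(fd) && solverStatus(fd) == "optimal" &&
            abs(objectiveValue(fd)) > 1e-6) {
            add("error", "free_lunch", objective(scen)$reaction, sprintf(
                "objective reaches %.6g with all exchange imports closed (growth without substrate)",
                objectiveValue(fd)
            ))
        }
        if (!is.null(fd) && solverStatus(fd) == "unbounded") {
            add("error", "free_lunch", objective(scen)$reaction,
                "objective unbounded with all exchange imports closed")
        }
    } else {
        add("warning", "no_objective", "scenario",
            "scenario has no objective; free-lunch and boundedness checks skipped")
    }

    ## (b) duplicate reactions up to sign/scaling
    sigOf <- function(j) {
        col <- model@stoichiometry[, j]
        nz <- which(col != 0)
        if (!length(nz)) return("empty")
        v <- col[nz] / col[nz[1L]]
        paste(nz, signif(v, 10), collapse = ";")
    }
    sigs <- vapply(seq_len(nrow(rxn)), sigOf, character(1))
    for (s in unique(sigs[duplicated(sigs) & sigs != "empty"])) {
        grp <- rxn$id[sigs == s]
        add("warning", "duplicate_reaction", paste(grp, collapse = "+"),
            "reactions share the same stoichiometry up to sign/scaling")
    }

    ## (c) dead ends
    de <- findDeadEnds(model, scen)
    for (m in de@totalDead) {
        add("warning", "dead_end", m,
            "metabolite cannot be both produced and consumed; its reactions are flux-zero")
    }

    ## (d) unbounded objective
    if (hasObj) {
        fd <- tryCatch(fba(model, scen), error = function(e) NULL)
        if (!is.null(fd) && solverStatus(fd) == "unbounded") {
            add("warning", "unbounded_objective", objective(scen)$reaction,
                "objective flux is unbounded under the scenario")
        }
    }
    ord <- order(code, subj)
    new("PlausibilityReport", findings = DataFrame(
        severity = sev[ord], code = code[ord],
        subject = subj[ord], message = msg[ord]
    ))
}

#' Assign reaction directionality from Gibbs free energies
#'
#' Applies a symmetric threshold rule to supplied reaction Gibbs
#' energies (treated as already transformed to the conditions of
#' interest): strongly negative reactions become irreversible forward,
#' strongly positive reactions are reversed (stoichiometry negated) and
#' made irreversible, and reactions within the threshold band become
#' reversible.  Reactions without a value are untouched.
#'
#' @param model A [MetabolicModel-class].
#' @param deltaG Named numeric: reaction id to Gibbs energy in kJ/mol.
#' @param threshold Band half-width in kJ/mol (default 30).
#' @return List with \code{model} (directions applied, energies stored)
#'   and \code{log}, a [S4Vectors::DataFrame] with columns
#'   \code{reaction}, \code{deltaG}, \code{action}.
#'
#' @examples
#' toy <- makeFixture("TOY_REV")
#' assignDirectionality(toy$model, c(iso = -50))$log
#' @export
assignDirectionality <- function(model, deltaG, threshold = 30) {
    rxn <- reactions(model)
    unknown <- setdiff(names(deltaG), rxn$id)
    if (length(unknown)) {
        stop("Gibbs energies for unknown reactions: ",
             paste(unknown, collapse = ", "))
    }
    specs <- .modelSpecs(model)
    action <- character(length(deltaG))
    for (k in seq_along(deltaG)) {
        id <- names(deltaG)[k]
        g <- deltaG[[k]]
        specs[[id]]$deltaG <- g
        if (g < -threshold) {
            specs[[id]]$reversible <- FALSE
            action[k] <- "irreversible_forward"
        } else if (g > threshold) {
            specs[[id]]$stoich <- -specs[[id]]$stoich
            specs[[id]]$reversible <- FALSE
            action[k] <- "reversed_irreversible"
        } else {
            specs[[id]]$reversible <- TRUE
            action[k] <- "reversible"
        }
    }
    met <- metabolites(model)
    out <- metabolicModel(
        specs, boundary = met$id[met$boundary],
        metaboliteNames = stats::setNames(met$name, met$id)
    )
    list(model = out, log = DataFrame(
        reaction = names(deltaG), deltaG = unname(deltaG), action = action
    ))
}
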