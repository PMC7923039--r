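#' @include model-core.R
NULL

## Reaction-list dialect
## ---------------------
##   id : lhs -> rhs          irreversible
##   id : lhs <-> rhs         reversible
##   boundary : m1 m2 ...     flag metabolites as boundary
## Each side is `coef met` terms joined by '+'; the coefficient is an
## optional positive real (default 1); an empty side marks an exchange.
## '#' starts a comment; blank lines are ignored.

.parseSide <- function(side, lineNo) {
    side <- trimws(side)
    if (!nzchar(side)) {
        return(numeric(0))
    }
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1L]])
    out <- numeric(0)
    for (tm in terms) {
        if (!nzchar(tm)) {
            stop("line ", lineNo, ": empty term in reaction side")
        }
        parts <- strsplit(tm, "[[:space:]]+")[[1L]]
        if (length(parts) == 1L) {
            coef <- 1
            mid <- parts
        } else if (length(parts) == 2L) {
            coef <- suppressWarnings(as.numeric(parts[1L]))
            if (is.na(coef) || coef <= 0) {
                stop("line ", lineNo, ": non-numeric or non-positive ",
                     "coefficient '", parts[1L], "'")
            }
            mid <- parts[2L]
        } else {
            stop("line ", lineNo, ": malformed term '", tm, "'")
        }
        out[mid] <- (if (mid %in% names(out)) out[[mid]] else 0) + coef
    }
    out
}

#' Read a model from the plain-text reaction dialect
#'
#' One reaction per non-comment line, \code{id : substrates -> products}
#' (\code{<->} for reversible reactions, an empty side for exchanges);
#' metabolites are registered in order of first mention.  An optional
#' \code{boundary : id ...} line flags boundary metabolites.
#'
#' @param text Character: either a file path or the dialect text itself
#'   (anything containing a newline or a colon is treated as text).
#' @return A [MetabolicModel-class].
#'
#' @examples
#' m <- parseReactionFile("upt : -> A\nconv : 2 A -> B\nbio : B ->")
#' nReactions(m)
#' @export
parseReactionFile <- function(text) {
    lines <- if (length(text) == 1L && !grepl("[\n:]", text) &&
                 file.exists(text)) {
        readLines(text, warn = FALSE)
    } else {
        unlist(strsplit(paste(text, collapse = "\n"), "\n"))
    }
    specs <- list()
    boundary <- character()
    for (i in seq_along(lines)) {
        line <- sub("#.*$", "", lines[i])
        line <- trimws(line)
        if (!nzchar(line)) next
        colon <- regexpr(":", line, fixed = TRUE)
        if (colon < 0) {
            stop("line ", i, ": expected 'id : reaction' (no ':' found)")
        }
        id <- trimws(substr(line, 1L, colon - 1L))
        body <- trimws(substr(line, colon + 1L, nchar(line)))
        if (!nzchar(id) || grepl("[[:space:]]", id)) {
            stop("line ", i, ": invalid reaction id '", id, "'")
        }
        if (tolower(id) == "boundary") {
            boundary <- union(boundary, strsplit(body, "[[:space:]]+")[[1L]])
            next
        }
        if (id %in% names(specs)) {
            stop("line ", i, ": duplicate reaction id '", id, "'")
        }
        reversible <- grepl("<->", body, fixed = TRUE)
        arrow <- if (reversible) "<->" else "->"
        if (!grepl(arrow, body, fixed = TRUE)) {
            stop("line ", i, ": no '->' or '<->' separator")
        }
        sides <- strsplit(body, arrow, fixed = TRUE)[[1L]]
        if (length(sides) > 2L) {
            stop("line ", i, ": more than one arrow")
        }
        lhs <- .parseSide(if (length(sides) >= 1L) sides[1L] else "", i)
        rhs <- .parseSide(if (length(sides) == 2L) sides[2L] else "", i)
        st <- numeric(0)
        for (m in names(lhs)) st[m] <- -lhs[[m]]
        for (m in names(rhs)) {
            st[m] <- (if (m %in% names(st)) st[[m]] else 0) + rhs[[m]]
        }
        st <- st[st != 0]
        specs[[id]] <- list(stoich = st, reversible = reversible)
    }
    metabolicModel(specs, boundary = boundary)
}

.formatSide <- function(st) {
    if (!length(st)) {
        return("")
    }
    paste(vapply(names(st), function(m) {
        if (st[[m]] == 1) m else paste(format(st[[m]]), m)
    }, character(1)), collapse = " + ")
}

#' Write a model in the plain-text reaction dialect
#'
#' Inverse of [parseReactionFile()]: re-reading the output yields a
#' structurally identical model (same ids, stoichiometries,
#' reversibilities and boundary flags).
#'
#' @param model A [MetabolicModel-class].
#' @param file Optional output path; omitted, the text is returned.
#' @return The dialect text, invisibly when written to a file.
#' @export
writeReactionFile <- function(model, file = NULL) {
    rxn <- reactions(model)
    met <- metabolites(model)
    lines <- "# reaction list"
    for (j in seq_len(nrow(rxn))) {
        st <- model@stoichiometry[, j]
        st <- st[st != 0]
        lhs <- -st[st < 0]
        rhs <- st[st > 0]
        lines <- c(lines, sprintf(
            "%s : %s %s %s", rxn$id[j], .formatSide(lhs),
            if (rxn$reversible[j]) "<->" else "->", .formatSide(rhs)
        ))
    }
    if (any(met$boundary)) {
        lines <- c(lines, paste(
            "boundary :", paste(met$id[met$boundary], collapse = " ")
        ))
    }
    text <- paste(lines, collapse = "\n")
    if (is.null(file)) {
        return(text)
    }
    writeLines(lines, file)
    invisible(text)
}

#' Read a scenario from the plain-text parameter dialect
#'
#' Line-oriented directives detached from the model itself:
#' \code{OBJ max|min reaction}, \code{LB reaction value},
#' \code{UB reaction value}; \code{-inf}/\code{inf} are accepted as
#' values and \code{#} starts a comment.  Bounds of unmentioned reactions
#' fall back to reversibility-derived defaults when the scenario is
#' applied to a model; contradictory bounds and a missing objective are
#' likewise only detected at application time.
#'
#' @param text File path or dialect text (as in [parseReactionFile()]).
#' @return A [Scenario-class].
#'
#' @examples
#' parseScenarioFile("OBJ max bio\nUB upt 10")
#' @export
parseScenarioFile <- function(text) {
    lines <- if (length(text) == 1L && !grepl("\n", text) &&
                 file.exists(text)) {
        readLines(text, warn = FALSE)
    } else {
        unlist(strsplit(paste(text, collapse = "\n"), "\n"))
    }
    lb <- numeric(0)
    ub <- numeric(0)
    objRxn <- character(0)
    objDir <- "max"
    parseVal <- function(tok, i) {
        if (tolower(tok) %in% c("inf", "+inf")) return(Inf)
        if (tolower(tok) == "-inf") return(-Inf)
        v <- suppressWarnings(as.numeric(tok))
        if (is.na(v)) stop("line ", i, ": non-numeric bound '", tok, "'")
        v
    }
    for (i in seq_along(lines)) {
        line <- trimws(sub("#.*$", "", lines[i]))
        if (!nzchar(line)) next
        tok <- strsplit(line, "[[:space:]]+")[[1L]]
        key <- toupper(tok[1L])
        if (key == "OBJ") {
            if (length(tok) != 3L || !tolower(tok[2L]) %in% c("max", "min")) {
                stop("line ", i, ": expected 'OBJ max|min <reaction>'")
            }
            if (length(objRxn)) {
                stop("line ", i, ": duplicate objective line")
            }
            objDir <- tolower(tok[2L])
            objRxn <- tok[3L]
        } else if (key %in% c("LB", "UB")) {
            if (length(tok) != 3L) {
                stop("line ", i, ": expected '", key, " <reaction> <value>'")
            }
            v <- parseVal(tok[3L], i)
            if (key == "LB") lb[tok[2L]] <- v else ub[tok[2L]] <- v
        } else {
            stop("line ", i, ": unknown directive '", tok[1L], "'")
        }
    }
    new("Scenario", lowerBound = lb, upperBound = ub,
        objectiveReaction = objRxn, objectiveDirection = objDir)
}

#' Write a scenario in the plain-text parameter dialect
#'
#' @param scen A [Scenario-class].
#' @param file Optional output path.
#' @return The dialect text, invisibly when written.
#' @export
writeScenarioFile <- function(scen, file = NULL) {
    fmtVal <- function(v) {
        if (v == Inf) "inf" else if (v == -Inf) "-inf" else format(v)
    }
    lines <- "# scenario"
    obj <- objective(scen)
    if (length(obj)) {
        lines <- c(lines, paste("OBJ", obj$direction, obj$reaction))
    }
    for (r in names(scen@lowerBound)) {
        lines <- c(lines, paste("LB", r, fmtVal(scen@lowerBound[[r]])))
    }
    for (r in names(scen@upperBound)) {
        lines <- c(lines, paste("UB", r, fmtVal(scen@upperBound[[r]])))
    }
    text <- paste(lines, collapse = "\n")
    if (is.null(file)) {
        return(text)
    }
    writeLines(lines, file)
    invisible(text)
}
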