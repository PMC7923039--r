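#' @include model-core.R
NULL

## SBML doubles use INF/-INF/NaN spellings.
.sbmlNum <- function(x) {
    if (is.na(x)) return(NA_real_)
    if (x == "INF") return(Inf)
    if (x == "-INF") return(-Inf)
    suppressWarnings(as.numeric(x))
}

.sbmlFmt <- function(v) {
    if (v == Inf) "INF" else if (v == -Inf) "-INF" else
        format(v, digits = 17)
}

## Attribute lookup tolerant of namespace prefixes (fbc:foo vs foo).
.attrAny <- function(node, names) {
    at <- xml2::xml_attrs(node)
    for (nm in names) {
        if (nm %in% names(at)) return(at[[nm]])
    }
    NA_character_
}

#' Export a model and scenario as SBML Level 3 with the fbc extension
#'
#' Writes an SBML L3v1 document using fbc version 2 for flux bounds and
#' the objective.  Species carry the boundary flag as
#' \code{boundaryCondition}; every reaction references bound parameters
#' resolved from the scenario (reversibility-derived defaults apply to
#' reactions without explicit bounds).
#'
#' @param model A [MetabolicModel-class].
#' @param scen A [Scenario-class] (may lack an objective).
#' @param file Output path.
#' @return The path, invisibly.
#'
#' @examples
#' toy <- makeFixture("TOY_LIN")
#' f <- tempfile(fileext = ".xml")
#' exportSBML(toy$model, toy$scenario, f)
#' @export
exportSBML <- function(model, scen, file) {
    bounds <- resolveBounds(model, scen)
    met <- metabolites(model)
    rxn <- reactions(model)
    obj <- objective(scen)

    esc <- function(x) {
        x <- gsub("&", "&amp;", x, fixed = TRUE)
        x <- gsub("<", "&lt;", x, fixed = TRUE)
        gsub(">", "&gt;", x, fixed = TRUE)
    }
    out <- c(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
        paste0(
            "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
            "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
            "level=\"3\" version=\"1\" fbc:required=\"false\">"
        ),
        "  <model id=\"model\" fbc:strict=\"false\">",
        "    <listOfCompartments>",
        "      <compartment id=\"default\" constant=\"true\"/>",
        "    </listOfCompartments>",
        "    <listOfSpecies>"
    )
    for (i in seq_len(nrow(met))) {
        out <- c(out, sprintf(
            paste0(
                "      <species id=\"%s\" name=\"%s\" compartment=\"default\" ",
                "boundaryCondition=\"%s\" hasOnlySubstanceUnits=\"false\" ",
                "constant=\"false\"/>"
            ),
            esc(met$id[i]), esc(met$name[i]),
            if (met$boundary[i]) "true" else "false"
        ))
    }
    out <- c(out, "    </listOfSpecies>", "    <listOfParameters>")
    pname <- function(j, side) sprintf("bnd_%s_%s", side, rxn$id[j])
    for (j in seq_len(nrow(rxn))) {
        out <- c(out, sprintf(
            "      <parameter id=\"%s\" value=\"%s\" constant=\"true\"/>",
            pname(j, "lo"), .sbmlFmt(bounds$lower[[rxn$id[j]]])
        ), sprintf(
            "      <parameter id=\"%s\" value=\"%s\" constant=\"true\"/>",
            pname(j, "up"), .sbmlFmt(bounds$upper[[rxn$id[j]]])
        ))
    }
    out <- c(out, "    </listOfParameters>", "    <listOfReactions>")
    for (j in seq_len(nrow(rxn))) {
        st <- model@stoichiometry[, j]
        st <- st[st != 0]
        out <- c(out, sprintf(
            paste0(
                "      <reaction id=\"%s\" reversible=\"%s\" fast=\"false\" ",
                "fbc:lowerFluxBound=\"%s\" fbc:upperFluxBound=\"%s\">"
            ),
            esc(rxn$id[j]), if (rxn$reversible[j]) "true" else "false",
            pname(j, "lo"), pname(j, "up")
        ))
        subs <- -st[st < 0]
        prods <- st[st > 0]
        if (length(subs)) {
            out <- c(out, "        <listOfReactants>", vapply(
                names(subs), function(m) sprintf(
                    paste0("          <speciesReference species=\"%s\" ",
                           "stoichiometry=\"%s\" constant=\"true\"/>"),
                    esc(m), format(subs[[m]], digits = 17)
                ), character(1)
            ), "        </listOfReactants>")
        }
        if (length(prods)) {
            out <- c(out, "        <listOfProducts>", vapply(
                names(prods), function(m) sprintf(
                    paste0("          <speciesReference species=\"%s\" ",
                           "stoichiometry=\"%s\" constant=\"true\"/>"),
                    esc(m), format(prods[[m]], digits = 17)
                ), character(1)
            ), "        </listOfProducts>")
        }
        out <- c(out, "      </reaction>")
    }
    out <- c(out, "    </listOfReactions>")
    if (length(obj)) {
        out <- c(out,
            "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
            sprintf(
                "      <fbc:objective fbc:id=\"obj\" fbc:type=\"%s\">",
                if (obj$direction == "max") "maximize" else "minimize"
            ),
            "        <fbc:listOfFluxObjectives>",
            sprintf(
                paste0("          <fbc:fluxObjective fbc:reaction=\"%s\" ",
                       "fbc:coefficient=\"1\"/>"),
                esc(obj$reaction)
            ),
            "        </fbc:listOfFluxObjectives>",
            "      </fbc:objective>",
            "    </fbc:listOfObjectives>"
        )
    }
    out <- c(out, "  </model>", "</sbml>")
    writeLines(out, file)
    ## structural self-check: the written document must parse back
    xml2::read_xml(file)
    invisible(file)
}

#' Import a model and scenario from SBML
#'
#' Reads SBML Level 2 and Level 3 documents; flux bounds and the active
#' objective are taken from the fbc extension when present, or from
#' COBRA-style kinetic-law parameters (\code{LOWER_BOUND},
#' \code{UPPER_BOUND}, \code{OBJECTIVE_COEFFICIENT}) in legacy Level 2
#' files.  Species with \code{boundaryCondition="true"} become boundary
#' metabolites; without bound information a reaction falls back to the
#' reversibility-derived defaults.
#'
#' @param file Path to an SBML document.
#' @return List with elements \code{model} ([MetabolicModel-class]) and
#'   \code{scenario} ([Scenario-class]).  When the document names no
#'   objective the scenario has none, with a warning.
#' @export
importSBML <- function(file) {
    doc <- tryCatch(xml2::read_xml(file), error = function(e) {
        stop("cannot read SBML: ", conditionMessage(e))
    })
    xml2::xml_ns_strip(doc)

    spNodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
    if (!length(spNodes)) stop("SBML document contains no species")
    mids <- xml2::xml_attr(spNodes, "id")
    mnames <- xml2::xml_attr(spNodes, "name")
    mnames[is.na(mnames)] <- mids[is.na(mnames)]
    boundary <- xml2::xml_attr(spNodes, "boundaryCondition") %in% "true"

    ## fbc bound parameters live in listOfParameters
    parNodes <- xml2::xml_find_all(doc, ".//model/listOfParameters/parameter")
    parVal <- stats::setNames(
        vapply(xml2::xml_attr(parNodes, "value"), .sbmlNum, numeric(1)),
        xml2::xml_attr(parNodes, "id")
    )

    rxNodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
    if (!length(rxNodes)) stop("SBML document contains no reactions")
    specs <- list()
    lb <- numeric(0)
    ub <- numeric(0)
    objRxn <- character(0)
    objDir <- "max"
    for (nd in rxNodes) {
        id <- xml2::xml_attr(nd, "id")
        rev <- !identical(xml2::xml_attr(nd, "reversible"), "false")
        st <- numeric(0)
        for (sr in xml2::xml_find_all(nd, "./listOfReactants/speciesReference")) {
            m <- xml2::xml_attr(sr, "species")
            coef <- .sbmlNum(xml2::xml_attr(sr, "stoichiometry"))
            if (is.na(coef)) coef <- 1
            st[m] <- (if (m %in% names(st)) st[[m]] else 0) - coef
        }
        for (sr in xml2::xml_find_all(nd, "./listOfProducts/speciesReference")) {
            m <- xml2::xml_attr(sr, "species")
            coef <- .sbmlNum(xml2::xml_attr(sr, "stoichiometry"))
            if (is.na(coef)) coef <- 1
            st[m] <- (if (m %in% names(st)) st[[m]] else 0) + coef
        }
        st <- st[st != 0]
        specs[[id]] <- list(stoich = st, reversible = rev)
        loRef <- .attrAny(nd, c("fbc:lowerFluxBound", "lowerFluxBound"))
        upRef <- .attrAny(nd, c("fbc:upperFluxBound", "upperFluxBound"))
        if (!is.na(loRef) && loRef %in% names(parVal)) lb[id] <- parVal[[loRef]]
        if (!is.na(upRef) && upRef %in% names(parVal)) ub[id] <- parVal[[upRef]]
        ## legacy L2 kinetic-law bounds
        for (pp in xml2::xml_find_all(nd, ".//kineticLaw//parameter")) {
            pid <- xml2::xml_attr(pp, "id")
            pv <- .sbmlNum(xml2::xml_attr(pp, "value"))
            if (identical(pid, "LOWER_BOUND")) lb[id] <- pv
            if (identical(pid, "UPPER_BOUND")) ub[id] <- pv
            if (identical(pid, "OBJECTIVE_COEFFICIENT") &&
                !is.na(pv) && pv != 0) {
                objRxn <- c(objRxn, id)
            }
        }
    }
    ## fbc objective
    actObj <- xml2::xml_find_first(
        doc, ".//*[local-name()='listOfObjectives']"
    )
    if (!inherits(actObj, "xml_missing")) {
        objNode <- xml2::xml_find_first(
            doc, ".//*[local-name()='objective']"
        )
        typ <- .attrAny(objNode, c("fbc:type", "type"))
        if (identical(typ, "minimize")) objDir <- "min"
        fo <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
        objRxn <- unique(c(objRxn, vapply(
            fo, function(x) .attrAny(x, c("fbc:reaction", "reaction")),
            character(1)
        )))
    }
    if (length(objRxn) > 1L) {
        stop("multi-reaction objectives are not supported")
    }
    if (!length(objRxn)) {
        warning("SBML document names no objective; scenario has none")
    }
    model <- metabolicModel(
        specs,
        boundary = mids[boundary],
        metaboliteNames = stats::setNames(mnames, mids)
    )
    scen <- new("Scenario", lowerBound = lb, upperBound = ub,
                objectiveReaction = objRxn, objectiveDirection = objDir)
    list(model = model, scenario = scen)
}
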