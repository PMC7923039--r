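#' @include metabolite-centric.R
NULL

#' Build and export the bipartite metabolite/reaction graph
#'
#' Renders one flux state as a bipartite graph: metabolite nodes
#' (labelled with their turnover) and reaction nodes, connected by edges
#' directed along the realized flux and labelled with split-ratio
#' percentages.  Nodes and edges whose flux does not exceed
#' \code{activeTolerance} are flagged inactive, so a drawing can grey out
#' the unused part of the network.
#'
#' @param model A [MetabolicModel-class].
#' @param fluxDist A steady-state [FluxDistribution-class].
#' @param ratios A [SplitRatioTable-class] computed from the same fluxes
#'   (default: computed on the fly).
#' @param format \code{"dot"}, \code{"graphml"} or \code{"json"}.
#' @param file Output path; when \code{NULL} the igraph object is
#'   returned without writing.
#' @param activeTolerance Flux magnitude at or below which an element is
#'   inactive.
#' @return The annotated \pkg{igraph} graph, invisibly when written.
#'
#' @examples
#' toy <- makeFixture("TOY_LIN")
#' g <- exportBipartiteGraph(toy$model, fba(toy$model, toy$scenario))
#' igraph::vcount(g)
#' @export
exportBipartiteGraph <- function(model, fluxDist, ratios = NULL,
                                 format = c("dot", "graphml", "json"),
                                 file = NULL, activeTolerance = 1e-9) {
    format <- match.arg(format)
    if (is.null(ratios)) {
        ratios <- splitRatios(model, fluxDist,
                              metaboliteIds = metabolites(model)$id)
    }
    v <- fluxes(fluxDist)[reactions(model)$id]
    met <- metabolites(model)
    rxn <- reactions(model)
    S <- model@stoichiometry
    turnover <- ratios@metadata$turnover
    rtab <- resultTable(ratios)

    nodes <- data.frame(
        name = c(met$id, rxn$id),
        type = rep(c("metabolite", "reaction"), c(nrow(met), nrow(rxn))),
        turnover = c(as.numeric(turnover[met$id]), rep(NA_real_, nrow(rxn))),
        flux = c(rep(NA_real_, nrow(met)), unname(v)),
        active = c(
            ifelse(is.na(turnover[met$id]), FALSE,
                   turnover[met$id] > activeTolerance),
            abs(v) > activeTolerance
        ),
        stringsAsFactors = FALSE
    )
    lookupPercent <- function(m, r, dir) {
        hit <- rtab$metabolite == m & rtab$reaction == r & rtab$direction == dir
        if (any(hit)) rtab$percent[which(hit)[1L]] else NA_real_
    }
    from <- character(); to <- character()
    eflux <- numeric(); epct <- numeric(); eact <- logical()
    for (j in seq_len(nrow(rxn))) {
        col <- S[, j]
        touch <- which(col != 0)
        vj <- v[j]
        sgn <- if (!is.na(vj) && vj < 0) -1 else 1
        for (i in touch) {
            contrib <- col[i] * vj
            m <- met$id[i]
            if (sgn * col[i] < 0) {       # consumed: metabolite -> reaction
                from <- c(from, m); to <- c(to, rxn$id[j])
                epct <- c(epct, lookupPercent(m, rxn$id[j], "consumer"))
            } else {                      # produced: reaction -> metabolite
                from <- c(from, rxn$id[j]); to <- c(to, m)
                epct <- c(epct, lookupPercent(m, rxn$id[j], "producer"))
            }
            eflux <- c(eflux, abs(contrib))
            eact <- c(eact, abs(contrib) > activeTolerance)
        }
    }
    g <- igraph::graph_from_data_frame(
        data.frame(from = from, to = to, flux = eflux, percent = epct,
                   active = eact, condensed = FALSE,
                   stringsAsFactors = FALSE),
        directed = TRUE, vertices = nodes
    )
    if (is.null(file)) {
        return(g)
    }
    writeGraphFile(g, file, format)
    invisible(g)
}

#' @describeIn exportBipartiteGraph Write an annotated bipartite graph to
#'   DOT, GraphML or a node-link JSON document.
#' @param g An \pkg{igraph} graph from [exportBipartiteGraph()] or
#'   [condenseLinearChains()].
#' @export
writeGraphFile <- function(g, file, format = c("dot", "graphml", "json")) {
    format <- match.arg(format)
    if (format == "graphml") {
        igraph::write_graph(g, file, format = "graphml")
        return(invisible(file))
    }
    vdf <- igraph::as_data_frame(g, what = "vertices")
    edf <- igraph::as_data_frame(g, what = "edges")
    if (format == "json") {
        jsonlite::write_json(
            list(nodes = vdf, links = edf), file,
            dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
        )
        return(invisible(file))
    }
    ## DOT: metabolites as ellipses labelled with turnover, reactions as
    ## boxes; inactive elements greyed; edges labelled with percentages
    q <- function(x) sprintf("\"%s\"", gsub("\"", "\\\\\"", x))
    lines <- c("digraph fluxstate {", "  rankdir=LR;")
    for (i in seq_len(nrow(vdf))) {
        isMet <- vdf$type[i] == "metabolite"
        lab <- if (isMet && !is.na(vdf$turnover[i])) {
            sprintf("%s\\n%.4g", vdf$name[i], vdf$turnover[i])
        } else {
            vdf$name[i]
        }
        lines <- c(lines, sprintf(
            "  %s [label=%s, shape=%s, class=%s%s];",
            q(vdf$name[i]), q(lab),
            if (isMet) "ellipse" else "box",
            vdf$type[i],
            if (!vdf$active[i]) ", color=grey, fontcolor=grey" else ""
        ))
    }
    for (i in seq_len(nrow(edf))) {
        lab <- if (!is.na(edf$percent[i])) {
            sprintf("%.3g%%", edf$percent[i])
        } else {
            ""
        }
        style <- if (isTRUE(edf$condensed[i])) "dashed"
            else if (!edf$active[i]) "dotted" else "solid"
        lines <- c(lines, sprintf(
            "  %s -> %s [label=%s, style=%s%s];",
            q(edf$from[i]), q(edf$to[i]), q(lab), style,
            if (!edf$active[i]) ", color=grey" else ""
        ))
    }
    lines <- c(lines, "}")
    writeLines(lines, file)
    invisible(file)
}

#' Condense linear chains of a bipartite flux graph
#'
#' Maximal paths whose interior nodes all have total degree two are
#' replaced by a single condensed edge carrying the chain's flux, so
#' long unbranched pathways collapse to one arrow while branch points
#' and endpoints stay put.
#'
#' @param g An \pkg{igraph} bipartite flux graph from
#'   [exportBipartiteGraph()].
#' @return The condensed graph; condensed edges carry
#'   \code{condensed = TRUE} and a \code{chain} attribute listing the
#'   collapsed node names.
#'
#' @examples
#' toy <- makeFixture("TOY_LIN")
#' g <- exportBipartiteGraph(toy$model, fba(toy$model, toy$scenario))
#' igraph::ecount(condenseLinearChains(g))
#' @export
condenseLinearChains <- function(g) {
    deg <- igraph::degree(g, mode = "all")
    interior <- names(deg)[deg == 2]
    if (!length(interior)) {
        return(g)
    }
    sub <- igraph::induced_subgraph(g, interior)
    comps <- igraph::components(sub)
    newEdges <- list()
    drop <- character()
    for (cid in seq_len(comps$no)) {
        members <- names(comps$membership)[comps$membership == cid]
        subDeg <- igraph::degree(sub, v = members, mode = "all")
        ends <- members[subDeg <= 1]
        if (!length(ends)) next                      # pure cycle: keep
        ## order members along the path by walking from one end
        first <- ends[1L]
        ordered <- first
        repeat {
            nb <- setdiff(
                names(igraph::neighbors(sub, ordered[length(ordered)],
                                        mode = "all")),
                ordered
            )
            if (!length(nb)) break
            ordered <- c(ordered, nb[1L])
        }
        extOf <- function(nodeName) {
            setdiff(names(igraph::neighbors(g, nodeName, mode = "all")),
                    members)
        }
        a <- extOf(ordered[1L])
        b <- extOf(ordered[length(ordered)])
        if (!length(a) || !length(b)) next           # dangling: keep
        ## orientation: does flux run a -> chain or chain -> a?
        firstEdge <- igraph::get_edge_ids(g, c(a[1L], ordered[1L]))
        forward <- firstEdge != 0
        fluxVals <- igraph::edge_attr(
            g, "flux", igraph::incident(g, ordered[1L], mode = "all")
        )
        newEdges[[length(newEdges) + 1L]] <- list(
            from = if (forward) a[1L] else b[1L],
            to = if (forward) b[1L] else a[1L],
            flux = fluxVals[1L],
            chain = paste(ordered, collapse = ",")
        )
        drop <- c(drop, members)
    }
    if (!length(newEdges)) {
        return(g)
    }
    g2 <- igraph::delete_vertices(g, drop)
    for (e in newEdges) {
        g2 <- igraph::add_edges(
            g2, c(e$from, e$to),
            attr = list(flux = e$flux, percent = NA_real_,
                        active = e$flux > 1e-9, condensed = TRUE,
                        chain = e$chain)
        )
    }
    g2
}
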