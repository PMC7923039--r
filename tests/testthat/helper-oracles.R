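# Shared helpers: infinity-aware comparison and independent brute-force
# oracles for the variability-type analyses.  The oracles re-derive each
# quantity with per-target cold solves through the independent pracma
# back-end, sharing no loop code with fva()/mfm().

expect_flux_equal <- function(a, b, tol = 1e-6) {
    bothInf <- is.infinite(a) & is.infinite(b) & sign(a) == sign(b)
    expect_true(all(bothInf | abs(a - b) <= tol),
                label = paste("max deviation",
                              max(abs(a - b)[!bothInf], 0, na.rm = TRUE)))
}

# Cold per-reaction flux ranges via the independent LP back-end.
oracleFVA <- function(model, scen, fraction, backend = "pracma") {
    bounds <- resolveBounds(model, scen)
    S <- stoichiometricMatrix(model)
    rids <- reactions(model)$id
    obj <- objective(scen)
    ref <- fba(model, scen, reduce = FALSE, backend = backend)
    z <- objectiveValue(ref)
    lower <- bounds$lower
    upper <- bounds$upper
    if (obj$direction == "max") {
        lower[obj$reaction] <- max(lower[obj$reaction], fraction * z)
    } else {
        upper[obj$reaction] <- min(upper[obj$reaction], fraction * z)
    }
    t(vapply(rids, function(id) {
        cost <- as.numeric(rids == id)
        c(
            solveLP(cost, S, numeric(nrow(S)), lower, upper, "min",
                    backend = backend)$objective,
            solveLP(cost, S, numeric(nrow(S)), lower, upper, "max",
                    backend = backend)$objective
        )
    }, numeric(2)))
}

# Cold per-metabolite minimal producing fluxes via the independent LP
# back-end on the irreversible split.
oracleMFM <- function(model, scen, fraction, backend = "pracma") {
    bounds <- resolveBounds(model, scen)
    sp <- toIrreversible(model)
    sb <- splitBounds(bounds, sp$mapping)
    S <- stoichiometricMatrix(sp$model)
    srids <- reactions(sp$model)$id
    obj <- objective(scen)
    z <- objectiveValue(fba(model, scen, reduce = FALSE, backend = backend))
    arow <- stats::setNames(numeric(length(srids)), srids)
    k <- match(obj$reaction, sp$mapping$original)
    arow[sp$mapping$forward[k]] <- 1
    if (!is.na(sp$mapping$backward[k])) arow[sp$mapping$backward[k]] <- -1
    A <- cbind(rbind(as.matrix(S), arow), c(numeric(nrow(S)), -1))
    bvec <- c(numeric(nrow(S)), fraction * z)
    lower <- c(sb$lower, if (obj$direction == "max") 0 else -Inf)
    upper <- c(sb$upper, if (obj$direction == "max") Inf else 0)
    met <- metabolites(model)
    ids <- met$id[!met$boundary]
    vapply(stats::setNames(ids, ids), function(m) {
        cost <- c(producingFluxCoefficients(sp$model, m), 0)
        max(0, solveLP(cost, A, bvec, lower, upper, "min",
                       backend = backend)$objective)
    }, numeric(1))
}

# Deterministic battery of random models used by the property tests.
randomSuite <- function(n = 20, nMet = 6, nRxn = 10) {
    lapply(seq_len(n), function(s) randomModel(nMet, nRxn, seed = s))
}
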