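test_that("reaction dialect parses counts, reversibility and errors", {
    m <- parseReactionFile("upt : -> A\nconv : 2 A -> B\nbio : B ->")
    expect_equal(nMetabolites(m), 2L)
    expect_equal(nReactions(m), 3L)
    expect_false(any(reactions(m)$reversible))
    expect_equal(reactionStoichiometry(m, "conv"), c(A = -2, B = 1))

    rev <- parseReactionFile("iso : A <-> B")
    expect_true(reactions(rev)$reversible)
    expect_equal(reactionStoichiometry(rev, "iso"), c(A = -1, B = 1))

    expect_error(parseReactionFile("bad_line_without_separator"), "line 1")
    expect_error(parseReactionFile("r : A -x> B"), "line 1")
    expect_error(parseReactionFile("r : q A -> B"), "line 1")
    expect_error(parseReactionFile("r : A -> B\nr : A -> C"), "duplicate")
})

test_that("reaction file writing round-trips and handles degenerate cases", {
    for (nm in c("TOY_LIN", "TOY_BRANCH", "TOY_YIELD", "TOY_REV",
                 "PREPHENATE_BRANCH")) {
        fx <- makeFixture(nm)
        txt <- writeReactionFile(fx$model)
        m2 <- parseReactionFile(txt)
        expect_identical(writeReactionFile(m2), txt, info = nm)
        expect_equal(nReactions(m2), nReactions(fx$model), info = nm)
        expect_equal(reactions(m2)$reversible, reactions(fx$model)$reversible,
                     info = nm)
    }
    expect_match(writeReactionFile(makeFixture("TOY_YIELD")$model), "2 A")
    empty <- metabolicModel(stats::setNames(list(), character(0)))
    expect_match(writeReactionFile(empty), "^#")
    ## boundary flags survive the round trip
    mb <- metabolicModel(list(r = list(stoich = c(A = -1, B = 1))),
                         boundary = "A")
    m2 <- parseReactionFile(writeReactionFile(mb))
    expect_true(metabolites(m2)$boundary[metabolites(m2)$id == "A"])
})

test_that("scenario dialect parses directives and defers validation", {
    s <- parseScenarioFile("OBJ max bio\nUB upt 10")
    expect_equal(objective(s), list(reaction = "bio", direction = "max"))
    expect_equal(s@upperBound, c(upt = 10))

    toy <- makeFixture("TOY_LIN")
    bad <- parseScenarioFile("OBJ max bio\nLB conv 5\nUB conv 2")
    expect_error(resolveBounds(toy$model, bad), "exceeds")

    empty <- parseScenarioFile("# nothing here\n# at all")
    expect_length(objective(empty), 0)
    expect_error(fba(toy$model, empty), "objective")

    expect_error(parseScenarioFile("OBJ max a\nOBJ max b"), "duplicate")
    expect_error(parseScenarioFile("FOO x 1"), "unknown directive")
    expect_equal(parseScenarioFile("LB r -inf")@lowerBound, c(r = -Inf))
})

test_that("stoichiometric matrix realizes the steady-state structure", {
    toy <- makeFixture("TOY_LIN")
    S <- stoichiometricMatrix(toy$model)
    expect_equal(dim(S), c(2L, 3L))
    expect_equal(as.numeric(S["A", ]), c(1, -1, 0))
    expect_equal(as.numeric(S["B", ]), c(0, 1, -1))

    mb <- metabolicModel(list(r = list(stoich = c(A = -1, B = 1))),
                         boundary = "A")
    expect_equal(rownames(stoichiometricMatrix(mb)), "B")
    expect_equal(dim(stoichiometricMatrix(mb, includeBoundary = TRUE)),
                 c(2L, 1L))

    empty <- metabolicModel(stats::setNames(list(), character(0)))
    expect_equal(dim(stoichiometricMatrix(empty)), c(0L, 0L))
})

test_that("irreversible split doubles reversibles and preserves feasibility", {
    tr <- makeFixture("TOY_REV")
    sp <- toIrreversible(tr$model)
    expect_equal(nReactions(sp$model), 4L)
    expect_false(any(reactions(sp$model)$reversible))
    expect_equal(sum(!is.na(sp$mapping$backward)), 1L)

    tl <- makeFixture("TOY_LIN")
    spl <- toIrreversible(tl$model)
    expect_equal(reactions(spl$model)$id, reactions(tl$model)$id)
    expect_equal(spl$mapping$forward, spl$mapping$original)

    ## any feasible flux of the split model maps back to a feasible flux
    ## of the original with the same objective flux
    for (s in 1:5) {
        rs <- randomModel(5, 9, seed = s)
        sp <- toIrreversible(rs$model)
        bounds <- splitBounds(resolveBounds(rs$model, rs$scenario),
                              sp$mapping)
        S <- stoichiometricMatrix(sp$model)
        srids <- reactions(sp$model)$id
        set.seed(1000 + s)
        cost <- stats::rnorm(length(srids))
        res <- solveLP(cost, S, numeric(nrow(S)), bounds$lower,
                       pmin(bounds$upper, 50), "max")
        expect_equal(res$status, "optimal")
        v <- netFluxes(stats::setNames(res$x, srids), sp$mapping)
        S0 <- stoichiometricMatrix(rs$model)
        expect_lt(max(abs(as.numeric(S0 %*% v[colnames(S0)]))), 1e-8)
        b0 <- resolveBounds(rs$model, rs$scenario)
        expect_true(all(v >= b0$lower[names(v)] - 1e-8))
        expect_true(all(v <= b0$upper[names(v)] + 1e-8))
    }
})

test_that("model construction enforces its invariants", {
    expect_error(metabolicModel(list(r = list(stoich = c(A = 0)))),
                 "nonzero")
    expect_error(
        metabolicModel(list(list(stoich = c(A = 1)))),
        "named"
    )
    ## contradictory bounds survive construction (deferred validation)
    ## and only fail when applied to a model
    contra <- scenario("bio", lowerBounds = c(conv = 2),
                       upperBounds = c(conv = 1))
    expect_error(
        resolveBounds(makeFixture("TOY_LIN")$model, contra), "exceeds"
    )
    expect_error(
        resolveBounds(makeFixture("TOY_LIN")$model,
                      scenario("bio", upperBounds = c(nope = 1))),
        "unknown"
    )
})
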