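test_that("FBA recovers the documented fixture optima", {
    expected <- c(TOY_LIN = 10, TOY_YIELD = 5, TOY_DEAD = 0,
                  TOY_BRANCH = 10, TOY_REV = 10, PREPHENATE_BRANCH = 1)
    for (nm in names(expected)) {
        fx <- makeFixture(nm)
        fd <- fba(fx$model, fx$scenario)
        expect_equal(solverStatus(fd), "optimal", info = nm)
        expect_equal(objectiveValue(fd), unname(expected[nm]),
                     tolerance = 1e-6, info = nm)
        S <- stoichiometricMatrix(fx$model)
        expect_lt(max(abs(as.numeric(S %*% fluxes(fd)[colnames(S)]))), 1e-6)
    }
})

test_that("FBA reports infeasibility and missing objectives", {
    tl <- makeFixture("TOY_LIN")
    infeasible <- scenario("bio", lowerBounds = c(bio = 5),
                           upperBounds = c(upt = 2))
    expect_equal(solverStatus(fba(tl$model, infeasible)), "infeasible")
    expect_error(fba(tl$model, scenario()), "objective")
    expect_error(fba(tl$model, scenario("ghost")), "not in model")
})

test_that("FBA optimum is invariant under reaction reordering and splitting", {
    tb <- makeFixture("TOY_BRANCH")
    specs <- rev(lapply(
        stats::setNames(seq_len(nReactions(tb$model)),
                        reactions(tb$model)$id),
        function(j) list(stoich = {
            st <- tb$model@stoichiometry[, j]; st[st != 0]
        })
    ))
    shuffled <- metabolicModel(specs)
    expect_equal(objectiveValue(fba(shuffled, tb$scenario)), 10,
                 tolerance = 1e-9)
    for (nm in c("TOY_REV", "TOY_BRANCH")) {
        fx <- makeFixture(nm)
        sp <- toIrreversible(fx$model)
        b <- splitBounds(resolveBounds(fx$model, fx$scenario), sp$mapping)
        scenSplit <- new("Scenario", lowerBound = b$lower,
                         upperBound = b$upper,
                         objectiveReaction = sp$mapping$forward[
                             match(objective(fx$scenario)$reaction,
                                   sp$mapping$original)],
                         objectiveDirection = "max")
        expect_equal(objectiveValue(fba(sp$model, scenSplit)),
                     objectiveValue(fba(fx$model, fx$scenario)),
                     tolerance = 1e-6, info = nm)
    }
})

test_that("FVA brackets the documented ranges and validates gamma", {
    tb <- makeFixture("TOY_BRANCH")
    v1 <- resultTable(fva(tb$model, tb$scenario, fraction = 1.0))
    r2 <- v1[v1$reaction == "r2", ]
    expect_equal(c(r2$minFlux, r2$maxFlux), c(0, 0), tolerance = 1e-6)

    v95 <- resultTable(fva(tb$model, tb$scenario, fraction = 0.95))
    expect_equal(v95$minFlux[v95$reaction == "r2"], 0, tolerance = 1e-6)
    expect_equal(v95$maxFlux[v95$reaction == "r2"], 0.5, tolerance = 1e-6)
    expect_equal(v95$minFlux[v95$reaction == "exB"], 9.5, tolerance = 1e-6)
    expect_equal(v95$maxFlux[v95$reaction == "exB"], 10, tolerance = 1e-6)

    expect_error(fva(tb$model, tb$scenario, fraction = 0), "\\(0, 1]")
    expect_error(fva(tb$model, tb$scenario, fraction = 1.2), "\\(0, 1]")
    expect_error(fva(tb$model, tb$scenario, reactionIds = "nope"),
                 "unknown")
})

test_that("FVA intervals contain the constrained FBA flux and tighten with gamma", {
    for (rs in randomSuite(5)) {
        v95 <- resultTable(fva(rs$model, rs$scenario, fraction = 0.95))
        v100 <- resultTable(fva(rs$model, rs$scenario, fraction = 1.0))
        expect_true(all(v95$minFlux <= v95$maxFlux + 1e-9))
        ## tightening gamma never widens an interval
        expect_true(all(v100$minFlux >= v95$minFlux - 1e-6))
        expect_true(all(v100$maxFlux <= v95$maxFlux + 1e-6))
        ## the gamma-constrained FBA solution lies inside every interval
        fd <- fba(rs$model, rs$scenario)
        v <- fluxes(fd)[v100$reaction]
        expect_true(all(v >= v100$minFlux - 1e-6 & v <= v100$maxFlux + 1e-6))
    }
})

test_that("warm-started FVA equals the independent cold oracle", {
    for (nm in c("TOY_LIN", "TOY_BRANCH", "TOY_YIELD", "TOY_REV",
                 "PREPHENATE_BRANCH")) {
        fx <- makeFixture(nm)
        got <- resultTable(fva(fx$model, fx$scenario, fraction = 0.95,
                               reduce = FALSE))
        want <- oracleFVA(fx$model, fx$scenario, 0.95)
        expect_flux_equal(got$minFlux, want[got$reaction, 1L])
        expect_flux_equal(got$maxFlux, want[got$reaction, 2L])
    }
    for (rs in randomSuite(20)) {
        warm <- resultTable(fva(rs$model, rs$scenario, warm = TRUE))
        cold <- resultTable(fva(rs$model, rs$scenario, warm = FALSE))
        expect_flux_equal(warm$minFlux, cold$minFlux)
        expect_flux_equal(warm$maxFlux, cold$maxFlux)
    }
})

test_that("MOMA returns the wild type under an identity perturbation", {
    tb <- makeFixture("TOY_BRANCH")
    wt <- fba(tb$model, tb$scenario)
    same <- moma(tb$model, tb$scenario, wt)
    expect_equal(solverStatus(same), "optimal")
    expect_lt(same@metadata$squaredDistance, 1e-9)
    expect_equal(fluxes(same), fluxes(wt), tolerance = 1e-6)
})

test_that("MOMA after a knockout reaches the QP optimum", {
    ## hand KKT on TOY_BRANCH with r1 knocked out: the only free
    ## direction is u = upt = r2 = exC, minimizing
    ## (u-10)^2 + u^2 + u^2 + const  =>  u = 10/3, squared distance
    ## 100 (r1) + 100 (exB) + (10/3-10)^2 + 2*(10/3)^2 = 800/3
    tb <- makeFixture("TOY_BRANCH")
    wt <- fba(tb$model, tb$scenario)
    ko <- knockoutScenario(tb$scenario, "r1")
    adj <- moma(tb$model, ko, wt)
    u <- 10 / 3
    expect_equal(fluxes(adj)[c("upt", "r1", "r2", "exB", "exC")],
                 c(upt = u, r1 = 0, r2 = u, exB = 0, exC = u),
                 tolerance = 1e-5)
    expect_equal(adj@metadata$squaredDistance, 800 / 3, tolerance = 1e-5)

    ## FVA-based box reduction never changes the optimum
    adjR <- moma(tb$model, ko, wt, fvaReduce = TRUE)
    expect_equal(fluxes(adjR), fluxes(adj), tolerance = 1e-6)
    for (rs in randomSuite(5)) {
        wtR <- fba(rs$model, rs$scenario)
        koR <- knockoutScenario(rs$scenario, "chain1")
        a <- moma(rs$model, koR, wtR)
        b <- moma(rs$model, koR, wtR, fvaReduce = TRUE)
        expect_equal(solverStatus(a), solverStatus(b))
        if (solverStatus(a) == "optimal") {
            expect_equal(a@metadata$squaredDistance,
                         b@metadata$squaredDistance, tolerance = 1e-6)
        }
    }
    ## infeasible perturbations are reported as such
    bad <- knockoutScenario(
        scenario("exB", lowerBounds = c(exB = 1), upperBounds = c(upt = 10)),
        "upt"
    )
    expect_equal(solverStatus(moma(tb$model, bad, wt)), "infeasible")
    expect_error(
        moma(tb$model, tb$scenario, fba(makeFixture("TOY_LIN")$model,
                                        makeFixture("TOY_LIN")$scenario)),
        "cover"
    )
})

test_that("knockout scans follow the chain logic", {
    tb <- makeFixture("TOY_BRANCH")
    sc <- knockoutScan(tb$model, tb$scenario, c("r1", "r2", "upt"))
    expect_equal(sc$objective[sc$reaction == "r1"], 0, tolerance = 1e-6)
    expect_equal(sc$objective[sc$reaction == "r2"], 10, tolerance = 1e-6)
    expect_equal(sc$objective[sc$reaction == "upt"], 0, tolerance = 1e-6)
    expect_error(knockoutScan(tb$model, tb$scenario, "nope"), "unknown")

    ## knocking out an already-blocked reaction changes nothing
    td <- makeFixture("TOY_DEAD")
    scd <- knockoutScan(td$model, td$scenario, "conv")
    expect_equal(scd$objective, 0, tolerance = 1e-9)

    ## MOMA-based scan: the exB component collapses with r1
    scm <- knockoutScan(tb$model, tb$scenario, "r1", method = "moma")
    expect_equal(scm$objective, 0, tolerance = 1e-6)
})

test_that("batch FBA isolates failures per scenario", {
    tl <- makeFixture("TOY_LIN")
    res <- batchFBA(tl$model, list(
        full = tl$scenario,
        low = scenario("bio", upperBounds = c(upt = 4)),
        broken = scenario("bio", lowerBounds = c(bio = 5),
                          upperBounds = c(upt = 2)),
        noObj = scenario()
    ))
    tb <- res$table
    expect_equal(tb$objective[tb$scenario == "full"], 10, tolerance = 1e-6)
    expect_equal(tb$objective[tb$scenario == "low"], 4, tolerance = 1e-6)
    expect_equal(tb$status[tb$scenario == "broken"], "infeasible")
    expect_equal(tb$status[tb$scenario == "noObj"], "error")
    expect_equal(nrow(batchFBA(tl$model, list())$table), 0L)
})

test_that("flux comparisons count and localize differences", {
    tb <- makeFixture("TOY_BRANCH")
    wt <- fba(tb$model, tb$scenario)
    expect_equal(compareFluxes(wt, wt)$nDiffering, 0L)

    shifted <- new("FluxDistribution",
                   fluxes = replace(fluxes(wt), "r2",
                                    fluxes(wt)[["r2"]] + 2),
                   objectiveValue = objectiveValue(wt),
                   status = "optimal", metadata = list())
    cmp <- compareFluxes(wt, shifted)
    expect_equal(cmp$nDiffering, 1L)
    expect_equal(cmp$table$difference[cmp$table$reaction == "r2"], -2)

    adj <- moma(tb$model, knockoutScenario(tb$scenario, "r1"), wt)
    cmp2 <- compareFluxes(wt, adj)
    expect_setequal(
        as.character(cmp2$table$reaction[abs(cmp2$table$difference) > 1e-6]),
        c("upt", "r1", "r2", "exB", "exC")
    )
    other <- fba(makeFixture("TOY_LIN")$model,
                 makeFixture("TOY_LIN")$scenario)
    expect_error(compareFluxes(wt, other), "different reaction sets")
})
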