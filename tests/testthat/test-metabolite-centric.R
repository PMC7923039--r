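test_that("producing-flux coefficients pick only positive stoichiometry", {
    tl <- makeFixture("TOY_LIN")
    sp <- toIrreversible(tl$model)
    co <- producingFluxCoefficients(sp$model, "B")
    expect_equal(co, c(upt = 0, conv = 1, bio = 0))

    ty <- makeFixture("TOY_YIELD")
    spy <- toIrreversible(ty$model)
    expect_equal(producingFluxCoefficients(spy$model, "B")[["conv"]], 1)
    expect_equal(producingFluxCoefficients(spy$model, "A")[["upt"]], 1)

    tr <- makeFixture("TOY_REV")
    spr <- toIrreversible(tr$model)
    cr <- producingFluxCoefficients(spr$model, "B")
    expect_equal(cr[["iso__fwd"]], 1)
    expect_equal(cr[["iso__bwd"]], 0)

    expect_error(producingFluxCoefficients(spr$model, "nope"), "unknown")
    mb <- metabolicModel(list(r = list(stoich = c(A = -1, B = 1))),
                         boundary = "A")
    expect_error(producingFluxCoefficients(mb, "A"), "boundary")
    expect_error(producingFluxCoefficients(tr$model, "B"), "reversible")
})

test_that("MFM reproduces the hand-derived branch essentialities", {
    tb <- makeFixture("TOY_BRANCH")
    rep <- mfm(tb$model, tb$scenario, fraction = 0.95)
    tbv <- resultTable(rep)
    got <- stats::setNames(tbv$minFlux, tbv$metabolite)
    expect_equal(got[["C"]], 0, tolerance = 1e-6)
    expect_equal(got[["B"]], 9.5, tolerance = 1e-6)
    expect_equal(got[["A"]], 9.5, tolerance = 1e-6)

    tl <- makeFixture("TOY_LIN")
    full <- resultTable(mfm(tl$model, tl$scenario, fraction = 1.0))
    expect_equal(full$minFlux, c(10, 10), tolerance = 1e-6)

    expect_error(mfm(tb$model, tb$scenario, fraction = 1.5), "\\(0, 1]")
    expect_error(mfm(tb$model, tb$scenario, fraction = 0), "\\(0, 1]")
})

test_that("warm-started MFM equals the independent cold oracle", {
    for (nm in c("TOY_LIN", "TOY_BRANCH", "TOY_YIELD", "TOY_REV",
                 "PREPHENATE_BRANCH")) {
        fx <- makeFixture(nm)
        got <- resultTable(mfm(fx$model, fx$scenario, fraction = 0.95,
                               reduce = FALSE))
        want <- oracleMFM(fx$model, fx$scenario, 0.95)
        expect_flux_equal(got$minFlux, unname(want[got$metabolite]))
    }
    for (rs in randomSuite(20)) {
        warm <- resultTable(mfm(rs$model, rs$scenario, warm = TRUE))
        cold <- resultTable(mfm(rs$model, rs$scenario, warm = FALSE))
        expect_flux_equal(warm$minFlux, cold$minFlux)
    }
})

test_that("relaxing the objective never raises a minimal producing flux", {
    gammas <- c(1.0, 0.95, 0.10)
    cases <- c(list(makeFixture("TOY_BRANCH")), randomSuite(5))
    for (fx in cases) {
        reps <- lapply(gammas, function(g) {
            resultTable(mfm(fx$model, fx$scenario, fraction = g))
        })
        for (k in 2:length(gammas)) {
            expect_true(all(reps[[k]]$minFlux <= reps[[k - 1L]]$minFlux + 1e-6))
            nonEss <- vapply(reps[c(k - 1L, k)], function(tb) {
                sum(tb$minFlux <= 1e-9)
            }, numeric(1))
            expect_gte(nonEss[2L], nonEss[1L])
        }
    }
})

test_that("producing flux is nonnegative over the split feasible set", {
    for (rs in randomSuite(5)) {
        tb <- resultTable(mfm(rs$model, rs$scenario))
        expect_true(all(tb$minFlux >= -1e-9))
    }
})

test_that("essential partition and ranking follow the report", {
    tb <- makeFixture("TOY_BRANCH")
    rep <- mfm(tb$model, tb$scenario, fraction = 0.95)
    part <- essentialPartition(rep)
    expect_equal(part$nonEssential, "C")
    expect_setequal(part$essential, c("A", "B"))
    expect_setequal(c(part$essential, part$nonEssential),
                    as.character(resultTable(rep)$metabolite))

    ## huge tolerance: everything non-essential
    expect_length(essentialPartition(rep, tolerance = 100)$essential, 0L)

    rk <- rankMetabolites(rep)
    expect_equal(as.character(rk$metabolite), c("A", "B", "C"))
    expect_equal(rk$minFlux, c(9.5, 9.5, 0), tolerance = 1e-6)

    emptyRep <- new("MetaboliteFluxReport",
                    table = S4Vectors::DataFrame(
                        metabolite = character(0), minFlux = numeric(0),
                        essential = logical(0)),
                    fraction = 0.95, tolerance = 1e-9)
    expect_equal(nrow(rankMetabolites(emptyRep)), 0L)
})

test_that("split ratios decompose the branch fixture as documented", {
    tb <- makeFixture("TOY_BRANCH")
    v <- new("FluxDistribution",
             fluxes = c(upt = 10, r1 = 6, r2 = 4, exB = 6, exC = 4),
             objectiveValue = 6, status = "optimal", metadata = list())
    sr <- resultTable(splitRatios(tb$model, v))
    A <- as.data.frame(sr[sr$metabolite == "A", ])
    expect_equal(A$percent[A$reaction == "r1"], 60, tolerance = 1e-9)
    expect_equal(A$percent[A$reaction == "r2"], 40, tolerance = 1e-9)
    expect_equal(A$percent[A$reaction == "upt"], 100, tolerance = 1e-9)
    expect_equal(unique(A$turnover), 10, tolerance = 1e-9)

    tl <- makeFixture("TOY_LIN")
    srl <- resultTable(splitRatios(tl$model, fba(tl$model, tl$scenario)))
    expect_true(all(abs(srl$percent - 100) < 1e-9))
    expect_true(all(abs(srl$turnover - 10) < 1e-9))
})

test_that("the prephenate-style branch splits 8/92 at turnover 0.72", {
    px <- makeFixture("PREPHENATE_BRANCH")
    sr <- splitRatios(px$model, fba(px$model, px$scenario))
    tb <- as.data.frame(resultTable(sr))
    pp <- tb[tb$metabolite == "prephenate", ]
    expect_equal(unique(pp$turnover), 0.72, tolerance = 1e-9)
    cons <- pp[pp$direction == "consumer", ]
    expect_equal(sort(cons$percent), c(8, 92), tolerance = 1e-6)
    expect_equal(cons$flux[cons$reaction == "pheA"], 0.0576,
                 tolerance = 1e-9)
    expect_equal(cons$flux[cons$reaction == "tdaS"], 0.6624,
                 tolerance = 1e-9)
})

test_that("split ratios conserve mass and sum to 100 percent", {
    cases <- c(
        lapply(c("TOY_LIN", "TOY_BRANCH", "TOY_YIELD", "TOY_REV",
                 "PREPHENATE_BRANCH"), makeFixture),
        randomSuite(10)
    )
    for (fx in cases) {
        fd <- fba(fx$model, fx$scenario)
        if (solverStatus(fd) != "optimal") next
        sr <- splitRatios(fx$model, fd)
        tb <- resultTable(sr)
        for (m in unique(tb$metabolite)) {
            sub <- tb[tb$metabolite == m, ]
            prod <- sum(sub$flux[sub$direction == "producer"])
            cons <- sum(sub$flux[sub$direction == "consumer"])
            expect_equal(prod, cons, tolerance = 1e-6)
            for (d in unique(sub$direction)) {
                expect_equal(sum(sub$percent[sub$direction == d]), 100,
                             tolerance = 1e-6)
            }
        }
        ## zero-turnover metabolites simply have no rows
        to <- sr@metadata$turnover
        expect_true(all(!(names(to)[to <= 1e-9] %in% tb$metabolite)))
    }
    ## non-steady-state fluxes are rejected
    tl <- makeFixture("TOY_LIN")
    bad <- new("FluxDistribution",
               fluxes = c(upt = 10, conv = 3, bio = 10),
               objectiveValue = 10, status = "optimal", metadata = list())
    expect_error(splitRatios(tl$model, bad), "steady state")
})

test_that("bipartite export flags inactive subnetworks and parses back", {
    tl <- makeFixture("TOY_LIN")
    g <- exportBipartiteGraph(tl$model, fba(tl$model, tl$scenario))
    expect_equal(igraph::vcount(g), 5L)
    expect_true(all(igraph::V(g)$active))
    expect_setequal(unique(igraph::V(g)$type), c("metabolite", "reaction"))

    tb <- makeFixture("TOY_BRANCH")
    fd <- fba(tb$model, tb$scenario)     # all carbon through r1
    gb <- exportBipartiteGraph(tb$model, fd)
    act <- stats::setNames(igraph::V(gb)$active, igraph::V(gb)$name)
    expect_false(act[["r2"]])
    expect_false(act[["C"]])
    expect_true(act[["r1"]])

    d <- withr::local_tempfile(fileext = ".dot")
    writeGraphFile(gb, d, "dot")
    txt <- readLines(d)
    expect_equal(sum(grepl("shape=", txt)), igraph::vcount(gb))
    expect_equal(sum(grepl("->", txt, fixed = TRUE)), igraph::ecount(gb))

    gm <- withr::local_tempfile(fileext = ".graphml")
    writeGraphFile(gb, gm, "graphml")
    back <- igraph::read_graph(gm, format = "graphml")
    expect_equal(igraph::vcount(back), igraph::vcount(gb))
    expect_equal(igraph::ecount(back), igraph::ecount(gb))

    js <- withr::local_tempfile(fileext = ".json")
    writeGraphFile(gb, js, "json")
    doc <- jsonlite::fromJSON(js)
    expect_equal(nrow(doc$nodes), igraph::vcount(gb))
    expect_error(writeGraphFile(gb, d, "svg"), "arg")
})

test_that("linear chains condense to single edges around branch points", {
    tl <- makeFixture("TOY_LIN")
    g <- exportBipartiteGraph(tl$model, fba(tl$model, tl$scenario))
    gc1 <- condenseLinearChains(g)
    expect_equal(igraph::vcount(gc1), 2L)
    expect_setequal(igraph::V(gc1)$name, c("upt", "bio"))
    expect_equal(igraph::ecount(gc1), 1L)
    expect_true(igraph::E(gc1)$condensed)
    expect_equal(igraph::E(gc1)$flux, 10)

    tb <- makeFixture("TOY_BRANCH")
    gb <- exportBipartiteGraph(tb$model, fba(tb$model, tb$scenario))
    gc2 <- condenseLinearChains(gb)
    expect_true("A" %in% igraph::V(gc2)$name)   # branch point survives

    ## no interior degree-2 nodes: identity
    star <- igraph::make_star(4, mode = "out")
    igraph::V(star)$name <- c("hub", "a", "b", "c")
    igraph::E(star)$flux <- 1
    expect_equal(igraph::vcount(condenseLinearChains(star)), 4L)
})
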