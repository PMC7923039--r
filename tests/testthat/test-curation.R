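test_that("synonym normalization renames, merges and stays idempotent", {
    m <- parseReactionFile(paste(
        "r1 : dextrose -> pyr",
        "r2 : glucose -> pyr",
        "upt1 : -> dextrose",
        "upt2 : -> glucose",
        "ex : pyr ->",
        sep = "\n"
    ))
    tab <- c(glucose = "D-glucose", dextrose = "D-glucose",
             "d-glucose" = "D-glucose")
    res <- normalizeNames(m, tab)
    lg <- as.data.frame(res$log)
    expect_equal(sum(lg$event == "rename"), 2L)
    expect_equal(sum(lg$event == "merge"), 1L)
    met <- metabolites(res$model)
    expect_true("D-glucose" %in% met$id)
    expect_false(any(c("glucose", "dextrose") %in% met$id))
    ## merged node now connects both uptakes to both conversions
    fd <- fba(res$model, scenario("ex", upperBounds = c(upt1 = 3, upt2 = 4)))
    expect_equal(objectiveValue(fd), 7, tolerance = 1e-6)

    ## idempotent
    res2 <- normalizeNames(res$model, tab)
    expect_identical(writeReactionFile(res2$model),
                     writeReactionFile(res$model))
    expect_equal(sum(res2$log$event == "rename"), 0L)

    ## empty table: identity
    res3 <- normalizeNames(m, character(0))
    expect_identical(writeReactionFile(res3$model), writeReactionFile(m))
    expect_equal(nrow(res3$log), 0L)

    ## case-only synonym is still renamed
    res4 <- normalizeNames(parseReactionFile("r : GLUCOSE -> x\nex : x ->"),
                           c(glucose = "D-glucose"))
    expect_true("D-glucose" %in% metabolites(res4$model)$id)
})

test_that("merges cancelling a coefficient are dropped with a warning", {
    m <- parseReactionFile("r1 : a -> b\nupt : -> a\nex : b ->")
    tab <- c(a = "X", b = "X")
    expect_warning(res <- normalizeNames(m, tab), "cancels")
    expect_true("coefficient_dropped" %in% res$log$event)
    expect_length(reactionStoichiometry(res$model, "r1"), 0L)
})

test_that("synonym tables reject ambiguity and map recommended to itself", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("glucose\tD-glucose", "dextrose\tD-glucose"), f)
    tab <- loadSynonymTable(f)
    expect_equal(unname(tab[["d-glucose"]]), "D-glucose")
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("glc\tD-glucose", "glc\tL-glucose"), f2)
    expect_error(loadSynonymTable(f2), "multiple")
})

test_that("plausibility checks find the planted defects", {
    ## a closed chain has no free lunch
    tl <- makeFixture("TOY_LIN")
    expect_equal(nrow(resultTable(checkPlausibility(tl$model,
                                                    tl$scenario))), 0L)

    ## an undeclared generator sustains the objective from nothing
    mFree <- parseReactionFile(
        "gen : -> B\nbio : B ->\nupt : -> A\nuse : A -> B"
    )
    rep <- resultTable(checkPlausibility(
        mFree, scenario("bio", upperBounds = c(upt = 10))
    ))
    expect_true(any(rep$code == "free_lunch" & rep$severity == "error"))

    ## duplicated stoichiometry up to scaling
    mDup <- parseReactionFile(paste(
        "upt : -> A", "r : A -> B", "r_dup : 2 A -> 2 B", "ex : B ->",
        sep = "\n"
    ))
    repD <- resultTable(checkPlausibility(
        mDup, scenario("ex", upperBounds = c(upt = 10))
    ))
    expect_true(any(repD$code == "duplicate_reaction" &
                        grepl("r\\+r_dup", repD$subject)))

    ## dead ends are listed
    td <- makeFixture("TOY_DEAD")
    repT <- resultTable(checkPlausibility(td$model, td$scenario))
    expect_setequal(repT$subject[repT$code == "dead_end"], c("A", "B", "D"))

    ## findings are deterministically ordered
    expect_false(is.unsorted(order(repD$code, repD$subject)))

    ## no objective: checks needing one are skipped with a warning entry
    repN <- resultTable(checkPlausibility(td$model, scenario()))
    expect_true(any(repN$code == "no_objective"))
})

test_that("directionality assignment follows the threshold rule", {
    tr <- makeFixture("TOY_REV")
    ## strongly exergonic: forward only
    r1 <- assignDirectionality(tr$model, c(iso = -50))
    expect_false(reactions(r1$model)$reversible[
        reactions(r1$model)$id == "iso"])
    expect_equal(reactionStoichiometry(r1$model, "iso"), c(A = -1, B = 1))

    ## strongly endergonic: reversed and irreversible
    r2 <- assignDirectionality(tr$model, c(iso = 50))
    expect_equal(reactionStoichiometry(r2$model, "iso"), c(A = 1, B = -1))
    expect_false(reactions(r2$model)$reversible[
        reactions(r2$model)$id == "iso"])
    expect_equal(as.character(r2$log$action), "reversed_irreversible")

    ## within the band: reversible
    tl <- makeFixture("TOY_LIN")
    r3 <- assignDirectionality(tl$model, c(conv = 0))
    expect_true(reactions(r3$model)$reversible[
        reactions(r3$model)$id == "conv"])
    ## untouched reactions keep their direction
    expect_false(reactions(r3$model)$reversible[
        reactions(r3$model)$id == "bio"])
    ## relaxing to reversible only enlarges the feasible set
    expect_equal(objectiveValue(fba(r3$model, tl$scenario)), 10,
                 tolerance = 1e-9)

    expect_error(assignDirectionality(tl$model, c(ghost = -50)), "unknown")
})
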