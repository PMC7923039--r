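#' @include io-rxn.R io-sbml.R io-json.R
NULL

#' Named desk-scale model fixtures
#'
#' Deterministic toy models with documented optima, so every analysis in
#' the package can be exercised without downloading anything:
#' \describe{
#'   \item{TOY_LIN}{Linear chain uptake \eqn{\to} A \eqn{\to} B \eqn{\to}
#'     sink, uptake capped at 10; FBA optimum 10.}
#'   \item{TOY_BRANCH}{Branch at A into B (the objective sink) and C;
#'     optimum 10 with all carbon through B.}
#'   \item{TOY_YIELD}{As TOY_LIN but the conversion consumes 2 A per B;
#'     optimum 5.}
#'   \item{TOY_DEAD}{The conversion co-produces an unconsumable
#'     metabolite D, so the whole chain is dead; optimum 0.}
#'   \item{TOY_REV}{The conversion step is reversible.}
#'   \item{PREPHENATE_BRANCH}{A six-reaction chain feeding a branch-point
#'     metabolite (prephenate) whose two consumers drain it in fixed
#'     biomass proportions, tuned so the optimum realizes a turnover of
#'     0.72 flux units split 8\%/92\% between the phenylalanine and TDA
#'     branches.}
#' }
#'
#' @param name Fixture name (see above).
#' @return List with elements \code{model} and \code{scenario}.
#'
#' @examples
#' toy <- makeFixture("TOY_YIELD")
#' objectiveValue(fba(toy$model, toy$scenario))
#' @export
makeFixture <- function(name = c("TOY_LIN", "TOY_BRANCH", "TOY_YIELD",
                                 "TOY_DEAD", "TOY_REV",
                                 "PREPHENATE_BRANCH")) {
    name <- match.arg(name)
    switch(name,
        TOY_LIN = list(
            model = metabolicModel(list(
                upt = list(stoich = c(A = 1)),
                conv = list(stoich = c(A = -1, B = 1)),
                bio = list(stoich = c(B = -1))
            )),
            scenario = scenario("bio", upperBounds = c(upt = 10))
        ),
        TOY_BRANCH = list(
            model = metabolicModel(list(
                upt = list(stoich = c(A = 1)),
                r1 = list(stoich = c(A = -1, B = 1)),
                r2 = list(stoich = c(A = -1, C = 1)),
                exB = list(stoich = c(B = -1)),
                exC = list(stoich = c(C = -1))
            )),
            scenario = scenario("exB", upperBounds = c(upt = 10))
        ),
        TOY_YIELD = list(
            model = metabolicModel(list(
                upt = list(stoich = c(A = 1)),
                conv = list(stoich = c(A = -2, B = 1)),
                bio = list(stoich = c(B = -1))
            )),
            scenario = scenario("bio", upperBounds = c(upt = 10))
        ),
        TOY_DEAD = list(
            model = metabolicModel(list(
                upt = list(stoich = c(A = 1)),
                conv = list(stoich = c(A = -1, B = 1, D = 1)),
                bio = list(stoich = c(B = -1))
            )),
            scenario = scenario("bio", upperBounds = c(upt = 10))
        ),
        TOY_REV = list(
            model = metabolicModel(list(
                upt = list(stoich = c(A = 1)),
                iso = list(stoich = c(A = -1, B = 1), reversible = TRUE),
                bio = list(stoich = c(B = -1))
            )),
            scenario = scenario("bio", upperBounds = c(upt = 10))
        ),
        PREPHENATE_BRANCH = list(
            ## glucose -> PEP -> prephenate; prephenate splits into the
            ## phenylalanine and TDA branches, drained by biomass in
            ## proportions 0.0576 : 0.6624 so the branch point carries a
            ## turnover of 0.72 split 8% / 92% at the optimum.
            model = metabolicModel(list(
                upt = list(stoich = c(glc = 1)),
                glyc = list(stoich = c(glc = -1, pep = 1)),
                ppaS = list(stoich = c(pep = -1, prephenate = 1)),
                pheA = list(stoich = c(prephenate = -1, phe = 1)),
                tdaS = list(stoich = c(prephenate = -1, tda = 1)),
                bio = list(stoich = c(phe = -0.0576, tda = -0.6624))
            )),
            scenario = scenario("bio", upperBounds = c(upt = 0.72))
        )
    )
}

#' Random feasible toy models for property tests
#'
#' Generates a guaranteed-feasible backbone chain (one uptake, a linear
#' conversion chain, one objective sink, uptake capped at 10) plus extra
#' random internal reactions: one substrate with coefficient 1 or 2, one
#' product with coefficient 1, 20\% reversible.  Extra reactions never
#' amplify mass, so the objective stays bounded, and the backbone keeps
#' every generated model feasible with optimum at least 10.
#' Reproducible per seed; the global RNG state is left untouched.
#'
#' @param nMetabolites Number of chain metabolites (at least 2).
#' @param nReactions Total reactions; must be at least
#'   \code{nMetabolites + 2} (the backbone needs
#'   \code{nMetabolites + 1}).
#' @param seed Integer seed.
#' @return List with elements \code{model} and \code{scenario}.
#'
#' @examples
#' rm1 <- randomModel(5, 9, seed = 1)
#' objectiveValue(fba(rm1$model, rm1$scenario))
#' @export
randomModel <- function(nMetabolites, nReactions, seed) {
    if (nMetabolites < 2) stop("need at least 2 metabolites")
    if (nReactions < nMetabolites + 2) {
        stop("need nReactions >= nMetabolites + 2")
    }
    oldSeed <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
    } else {
        NULL
    }
    on.exit({
        if (is.null(oldSeed)) {
            if (exists(".Random.seed", envir = globalenv())) {
                rm(".Random.seed", envir = globalenv())
            }
        } else {
            assign(".Random.seed", oldSeed, envir = globalenv())
        }
    })
    set.seed(seed)
    mets <- paste0("m", seq_len(nMetabolites))
    specs <- list(upt = list(stoich = stats::setNames(1, mets[1L])))
    for (i in seq_len(nMetabolites - 1L)) {
        specs[[paste0("chain", i)]] <- list(
            stoich = stats::setNames(c(-1, 1), mets[c(i, i + 1L)])
        )
    }
    specs$bio <- list(stoich = stats::setNames(-1, mets[nMetabolites]))
    nExtra <- nReactions - (nMetabolites + 1L)
    for (k in seq_len(nExtra)) {
        repeat {
            sm <- sample(mets, 1L)
            pm <- sample(setdiff(mets, sm), 1L)
            if (sm != pm) break
        }
        rev <- stats::runif(1) < 0.2
        ## reversible extras stay 1:1 so no direction amplifies mass;
        ## irreversible extras may consume 2 per product
        coef <- if (rev) 1 else sample(c(1, 2), 1L)
        specs[[paste0("x", k)]] <- list(
            stoich = stats::setNames(c(-coef, 1), c(sm, pm)),
            reversible = rev
        )
    }
    list(
        model = metabolicModel(specs),
        scenario = scenario("bio", upperBounds = c(upt = 10))
    )
}

#' Fetch a deposited genome-scale model (requires network access)
#'
#' Downloads one of the two deposited models from the metabolic-model
#' repository at \code{mmtb.brenda-enzymes.org}, sniffs the format (SBML,
#' COBRA JSON, or the plain reaction dialect), converts it to the plain
#' dialect and records an MD5 checksum.  Never used by the test suite;
#' all desk-scale needs are met by [makeFixture()] and [randomModel()].
#'
#' @param which \code{"iMG481"} or \code{"iPin571"}.
#' @param dest Destination directory.
#' @return Invisible list with the written \code{.rxn} path and the
#'   checksum of the raw download.
#' @export
fetchPublishedModel <- function(which = c("iMG481", "iPin571"),
                                dest = ".") {
    which <- match.arg(which)
    url <- switch(which,
        iMG481 = "https://mmtb.brenda-enzymes.org/models/view/11",
        iPin571 = "https://mmtb.brenda-enzymes.org/models/view/12"
    )
    raw <- file.path(dest, paste0(which, ".download"))
    ok <- tryCatch(
        utils::download.file(url, raw, quiet = TRUE, mode = "wb") == 0,
        error = function(e) FALSE, warning = function(w) FALSE
    )
    if (!ok || !file.exists(raw)) {
        stop("could not download ", which, " from ", url,
             "; download the model manually and use importSBML()/",
             "convertJSON()/parseReactionFile() on the file")
    }
    head <- readChar(raw, 512L, useBytes = TRUE)
    parsed <- if (grepl("<sbml", head, fixed = TRUE)) {
        importSBML(raw)
    } else if (grepl("^\\s*\\{", head)) {
        convertJSON(raw)
    } else {
        list(model = parseReactionFile(raw), scenario = scenario())
    }
    out <- file.path(dest, paste0(which, ".rxn"))
    writeReactionFile(parsed$model, out)
    invisible(list(path = out, checksum = unname(tools::md5sum(raw))))
}
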