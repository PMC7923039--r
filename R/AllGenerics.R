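#' @include AllClasses.R
NULL

#' Accessors for model components
#'
#' @param object A [MetabolicModel-class], [FluxDistribution-class] or
#'   other fluxnode object.
#' @param ... Passed on to methods.
#' @return \code{metabolites} and \code{reactions} return the metabolite /
#'   reaction [S4Vectors::DataFrame]; \code{nMetabolites} and
#'   \code{nReactions} their row counts; \code{stoichiometricMatrix} the
#'   sparse steady-state matrix (non-boundary rows only by default).
#'
#' @examples
#' toy <- makeFixture("TOY_LIN")
#' nReactions(toy$model)
#' stoichiometricMatrix(toy$model)
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("metabolites", function(object, ...) standardGeneric("metabolites"))

#' @rdname model-accessors
#' @export
setGeneric("reactions", function(object, ...) standardGeneric("reactions"))

#' @rdname model-accessors
#' @export
setGeneric("nMetabolites", function(object) standardGeneric("nMetabolites"))

#' @rdname model-accessors
#' @export
setGeneric("nReactions", function(object) standardGeneric("nReactions"))

#' @rdname model-accessors
#' @export
setGeneric("stoichiometricMatrix", function(object, ...) {
    standardGeneric("stoichiometricMatrix")
})

#' Accessors for optimization results
#'
#' @param object A [FluxDistribution-class], [VariabilityResult-class],
#'   [MetaboliteFluxReport-class] or [SplitRatioTable-class].
#' @return \code{fluxes}: named numeric flux vector; \code{objectiveValue}:
#'   scalar; \code{solverStatus}: character status; \code{resultTable}: the
#'   tabular payload of report-style objects as a [S4Vectors::DataFrame].
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname result-accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @rdname result-accessors
#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))

#' @rdname result-accessors
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))

#' Accessors for scenarios
#'
#' @param object A [Scenario-class].
#' @return \code{objective}: list with elements \code{reaction} and
#'   \code{direction} (empty list when unset).
#' @name scenario-accessors
NULL

#' @rdname scenario-accessors
#' @export
setGeneric("objective", function(object) standardGeneric("objective"))
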