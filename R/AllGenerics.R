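#' @rdname unfold
#' @export
setGeneric("unfold", function(x, mode) standardGeneric("unfold"))

#' Axis labels of a tensor or fit
#'
#' @param x an \linkS4class{InteractionTensor}, \linkS4class{TVFit} or
#'   \linkS4class{GroundTruth}
#' @param mode optional axis in \code{1:3}; when omitted the full list of
#'   three label vectors is returned
#' @return a character vector, or a list of three of them
#' @export
setGeneric("axisLabels", function(x, mode) standardGeneric("axisLabels"))

#' Accessors for fitted factors
#'
#' \code{geneFactor}, \code{conditionFactor} and \code{timeFactor} return the
#' U, V and W matrices of a fit or factor set.
#'
#' @param x a \linkS4class{TVFit} or \linkS4class{TVFactors}
#' @return a numeric matrix
#' @rdname factor-accessors
#' @export
setGeneric("geneFactor", function(x) standardGeneric("geneFactor"))

#' @rdname factor-accessors
#' @export
setGeneric("conditionFactor", function(x) standardGeneric("conditionFactor"))

#' @rdname factor-accessors
#' @export
setGeneric("timeFactor", function(x) standardGeneric("timeFactor"))

#' Objective value per outer iteration
#'
#' @param x a \linkS4class{TVFit}
#' @return numeric vector
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' Did the outer loop reach its tolerance?
#'
#' @param x a \linkS4class{TVFit}
#' @return logical scalar
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' Extract modules from converged factors
#'
#' @rdname extractModules
#' @export
setGeneric("extractModules", function(x, ...) standardGeneric("extractModules"))

#' Ground-truth modules as label sets
#'
#' Converts the planted index sets of a \linkS4class{GroundTruth} into
#' \linkS4class{TriModule} objects carrying axis labels, so that planted and
#' discovered modules can be compared directly.
#'
#' @param x a \linkS4class{GroundTruth}
#' @return list of \linkS4class{TriModule}
#' @export
setGeneric("truthModules", function(x) standardGeneric("truthModules"))
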