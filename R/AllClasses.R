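#' @import methods
NULL

#' InteractionTensor: a dense labeled gene x condition x time tensor
#'
#' Container for a dense third-order interaction tensor, e.g. expression of
#' \code{n1} genes under \code{n2} conditions over \code{n3} ordered
#' time-points. Entries may be negative; the array must be fully dense (no
#' \code{NA}/\code{NaN}/\code{Inf}) and carry complete, unique axis labels as
#' \code{dimnames}. The third axis is interpreted as chronologically ordered.
#'
#' @slot values numeric 3-d array with complete \code{dimnames}
#' @export
setClass("InteractionTensor", representation(values = "array"))

setValidity("InteractionTensor", function(object) {
    v <- object@values
    if (length(dim(v)) != 3L)
        return("'values' must be a three-dimensional array")
    if (!is.numeric(v))
        return("'values' must be numeric")
    if (anyNA(v) || any(!is.finite(v)))
        return("tensor must be dense: no NA/NaN/Inf entries")
    dn <- dimnames(v)
    if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
        return("all three axes must be labeled (complete dimnames)")
    for (i in 1:3) {
        if (length(dn[[i]]) != dim(v)[i])
            return(sprintf("axis %d: %d labels for extent %d",
                           i, length(dn[[i]]), dim(v)[i]))
        if (anyDuplicated(dn[[i]]))
            return(sprintf("axis %d labels are not unique", i))
    }
    TRUE
})

#' Construct an InteractionTensor
#'
#' @param values numeric 3-d array (genes x conditions x time-points)
#' @param geneLabels,conditionLabels,timeLabels character label vectors; taken
#'   from \code{dimnames(values)} when omitted, or autogenerated
#'   (\code{g1..}, \code{c1..}, \code{t1..}).
#' @return an \linkS4class{InteractionTensor}
#' @examples
#' a <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
#' InteractionTensor(a)
#' @export
InteractionTensor <- function(values, geneLabels = NULL,
                              conditionLabels = NULL, timeLabels = NULL) {
    stopifnot(is.array(values), length(dim(values)) == 3L)
    d <- dim(values)
    dn <- dimnames(values)
    if (is.null(dn)) dn <- vector("list", 3L)
    if (!is.null(geneLabels))      dn[[1L]] <- as.character(geneLabels)
    if (!is.null(conditionLabels)) dn[[2L]] <- as.character(conditionLabels)
    if (!is.null(timeLabels))      dn[[3L]] <- as.character(timeLabels)
    pref <- c("g", "c", "t")
    for (i in 1:3)
        if (is.null(dn[[i]])) dn[[i]] <- paste0(pref[i], seq_len(d[i]))
    dimnames(values) <- dn
    new("InteractionTensor", values = values)
}

#' TVFactors: the three decomposition matrices plus ADMM state
#'
#' Holds the factor matrices of the rank-K decomposition: \code{U}
#' (genes x K), \code{V} (conditions x K), \code{W} (time-points x K), and the
#' ADMM split variable \code{P} and scaled dual \code{Q} (both (n3-1) x K)
#' from the time-factor subproblem. After a completed time-factor update,
#' \code{W} is entrywise nonnegative with unit column sums; \code{U} and
#' \code{V} are unconstrained in sign.
#'
#' @slot U,V,W,P,Q numeric matrices
#' @export
setClass("TVFactors",
         representation(U = "matrix", V = "matrix", W = "matrix",
                        P = "matrix", Q = "matrix"))

setValidity("TVFactors", function(object) {
    K <- ncol(object@U)
    if (ncol(object@V) != K || ncol(object@W) != K)
        return("U, V, W must have the same number of columns")
    TRUE
})

#' TVParams: hyperparameters of the factorization
#'
#' @slot K integer, number of modules (rank)
#' @slot alpha numeric >= 0, weight of the total-variation penalty on W
#' @slot rho numeric > 0, ADMM penalty parameter
#' @slot tau numeric length-3 in [0,1]: extraction thresholds for the gene,
#'   condition and time modes
#' @slot outerTol numeric, outer-loop threshold on the summed squared factor
#'   change (default 0.001)
#' @slot outerMaxIter,innerMaxIter integer iteration caps
#' @slot innerTol numeric, ADMM stopping tolerance
#' @slot seed integer RNG seed
#' @slot wUpdate character, \code{"constrained"} (column-sum constraint
#'   enforced in the ADMM W-update) or \code{"projected"} (unconstrained
#'   update, clip-and-normalize after the inner loop)
#' @export
setClass("TVParams",
         representation(K = "integer", alpha = "numeric", rho = "numeric",
                        tau = "numeric", outerTol = "numeric",
                        outerMaxIter = "integer", innerTol = "numeric",
                        innerMaxIter = "integer", seed = "integer",
                        wUpdate = "character"))

setValidity("TVParams", function(object) {
    if (object@K < 1L) return("K must be >= 1")
    if (object@alpha < 0) return("alpha must be >= 0")
    if (object@rho <= 0) return("rho must be > 0")
    if (length(object@tau) != 3L || any(object@tau < 0) || any(object@tau > 1))
        return("tau must be three thresholds in [0, 1]")
    if (object@outerTol <= 0 || object@innerTol <= 0)
        return("tolerances must be positive")
    if (!object@wUpdate %in% c("constrained", "projected"))
        return("wUpdate must be 'constrained' or 'projected'")
    TRUE
})

#' Construct hyperparameters
#'
#' @param K number of modules (rank of the decomposition)
#' @param alpha total-variation weight (default 10)
#' @param rho ADMM penalty (default 1)
#' @param tau extraction thresholds \code{c(tau1, tau2, tau3)} for the gene,
#'   condition and time modes
#' @param outerTol outer convergence threshold on
#'   \eqn{||\Delta U||^2 + ||\Delta V||^2 + ||\Delta W||^2} (default 0.001)
#' @param outerMaxIter,innerMaxIter iteration caps
#' @param innerTol ADMM stopping tolerance
#' @param seed RNG seed
#' @param wUpdate see \linkS4class{TVParams}
#' @return a \linkS4class{TVParams}
#' @export
TVParams <- function(K, alpha = 10, rho = 1, tau = c(1, 1, 0.75),
                     outerTol = 0.001, outerMaxIter = 100L, innerTol = 1e-6,
                     innerMaxIter = 200L, seed = 1L,
                     wUpdate = c("constrained", "projected")) {
    new("TVParams", K = as.integer(K), alpha = as.numeric(alpha),
        rho = as.numeric(rho), tau = as.numeric(tau),
        outerTol = as.numeric(outerTol),
        outerMaxIter = as.integer(outerMaxIter),
        innerTol = as.numeric(innerTol),
        innerMaxIter = as.integer(innerMaxIter), seed = as.integer(seed),
        wUpdate = match.arg(wUpdate))
}

#' TVFit: result of the alternating factorization
#'
#' @slot factors a \linkS4class{TVFactors} at convergence
#' @slot objectiveTrace numeric, the penalized objective per outer iteration
#' @slot nOuterIterations integer
#' @slot converged logical, whether the outer tolerance was reached
#' @slot params the \linkS4class{TVParams} used
#' @slot axisLabels list of the three label vectors of the fitted tensor
#' @slot wConstraintViolation numeric, the largest violation of the W
#'   constraints (negativity or column-sum deviation) observed after any
#'   completed outer iteration
#' @slot restartObjectives numeric, final objectives of all restarts when the
#'   fit came from \code{\link{tvFactorizeRestarts}} (empty otherwise)
#' @export
setClass("TVFit",
         representation(factors = "TVFactors", objectiveTrace = "numeric",
                        nOuterIterations = "integer", converged = "logical",
                        params = "TVParams", axisLabels = "list",
                        wConstraintViolation = "numeric",
                        restartObjectives = "numeric"))

#' TriModule: one extracted gene/condition/time module
#'
#' A tricluster \eqn{\Omega_k}: the gene, condition and time-point label sets
#' selected from column k of the factor matrices. Any of the three sets may be
#' empty; such modules are kept (so module indices stay aligned with factor
#' columns) and the degenerate modes are named in \code{degenerate}.
#'
#' @slot k integer column index
#' @slot genes,conditions,timepoints character label sets
#' @slot degenerate character, subset of \code{c("gene","condition","time")}
#'   whose thresholding rule was undefined (no strictly positive entries)
#' @slot timeContiguous logical, whether the time set is one consecutive run
#' @export
setClass("TriModule",
         representation(k = "integer", genes = "character",
                        conditions = "character", timepoints = "character",
                        degenerate = "character", timeContiguous = "logical"))

#' PlantedModule: ground-truth specification of one planted module
#'
#' @slot genes,conditions integer index sets
#' @slot timeStart,timeEnd inclusive 1-based bounds of the consecutive time
#'   interval
#' @slot signalLow,signalHigh bounds of the uniform signal distribution
#' @export
setClass("PlantedModule",
         representation(genes = "integer", conditions = "integer",
                        timeStart = "integer", timeEnd = "integer",
                        signalLow = "numeric", signalHigh = "numeric"))

setValidity("PlantedModule", function(object) {
    if (object@timeStart > object@timeEnd)
        return("timeStart must be <= timeEnd (consecutive interval)")
    TRUE
})

#' GroundTruth: the planted modules of a synthetic benchmark tensor
#'
#' @slot modules list of \linkS4class{PlantedModule}
#' @slot noiseDensity fraction of tensor cells overwritten with noise
#' @slot seed integer seed used by the generator
#' @slot dims integer length-3 tensor dimensions
#' @slot axisLabels list of the three label vectors
#' @export
setClass("GroundTruth",
         representation(modules = "list", noiseDensity = "numeric",
                        seed = "integer", dims = "integer",
                        axisLabels = "list"))

setValidity("GroundTruth", function(object) {
    if (object@noiseDensity < 0 || object@noiseDensity > 1)
        return("noiseDensity must lie in [0, 1]")
    d <- object@dims
    for (m in object@modules) {
        if (!is(m, "PlantedModule")) return("modules must be PlantedModule")
        if (any(m@genes < 1L) || any(m@genes > d[1]) ||
            any(m@conditions < 1L) || any(m@conditions > d[2]) ||
            m@timeStart < 1L || m@timeEnd > d[3])
            return("planted module indices outside tensor bounds")
    }
    TRUE
})
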