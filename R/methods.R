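## Accessors and show methods.

#' @describeIn InteractionTensor dimensions of the tensor
#' @param x an InteractionTensor
#' @export
setMethod("dim", "InteractionTensor", function(x) dim(x@values))

#' Raw values of an InteractionTensor
#'
#' @param x an \linkS4class{InteractionTensor}
#' @return the underlying numeric 3-d array (with dimnames)
#' @export
tensorValues <- function(x) {
    stopifnot(is(x, "InteractionTensor"))
    x@values
}

setMethod("axisLabels", "InteractionTensor", function(x, mode) {
    dn <- dimnames(x@values)
    if (missing(mode)) dn else dn[[mode]]
})

setMethod("axisLabels", "TVFit", function(x, mode) {
    if (missing(mode)) x@axisLabels else x@axisLabels[[mode]]
})

setMethod("axisLabels", "GroundTruth", function(x, mode) {
    if (missing(mode)) x@axisLabels else x@axisLabels[[mode]]
})

setMethod("geneFactor", "TVFactors", function(x) x@U)
setMethod("geneFactor", "TVFit", function(x) x@factors@U)
setMethod("conditionFactor", "TVFactors", function(x) x@V)
setMethod("conditionFactor", "TVFit", function(x) x@factors@V)
setMethod("timeFactor", "TVFactors", function(x) x@W)
setMethod("timeFactor", "TVFit", function(x) x@factors@W)

setMethod("objectiveTrace", "TVFit", function(x) x@objectiveTrace)
setMethod("isConverged", "TVFit", function(x) x@converged)

setMethod("show", "InteractionTensor", function(object) {
    d <- dim(object@values)
    cat(sprintf("InteractionTensor: %d genes x %d conditions x %d time-points\n",
                d[1], d[2], d[3]))
    rng <- range(object@values)
    cat(sprintf("  values in [%.4g, %.4g], %.1f%% nonzero\n", rng[1], rng[2],
                100 * mean(object@values != 0)))
    dn <- dimnames(object@values)
    cat("  genes: ", .abbrevLabels(dn[[1]]), "\n", sep = "")
    cat("  conditions: ", .abbrevLabels(dn[[2]]), "\n", sep = "")
    cat("  time: ", .abbrevLabels(dn[[3]]), "\n", sep = "")
    invisible(NULL)
})

.abbrevLabels <- function(x) {
    if (length(x) <= 6L) return(paste(x, collapse = ", "))
    paste0(paste(utils::head(x, 3L), collapse = ", "), ", ..., ",
           paste(utils::tail(x, 2L), collapse = ", "))
}

setMethod("show", "TVFit", function(object) {
    p <- object@params
    cat(sprintf("TVFit: K = %d, alpha = %g, rho = %g (%s W-update)\n",
                p@K, p@alpha, p@rho, p@wUpdate))
    cat(sprintf("  %d outer iteration(s), %s (outer tol %g)\n",
                object@nOuterIterations,
                if (object@converged) "converged" else "not converged",
                p@outerTol))
    tr <- object@objectiveTrace
    cat(sprintf("  objective: %.6g -> %.6g\n", tr[1], tr[length(tr)]))
    if (length(object@restartObjectives) > 1L)
        cat(sprintf("  best of %d restarts (objectives %s)\n",
                    length(object@restartObjectives),
                    paste(signif(object@restartObjectives, 6),
                          collapse = ", ")))
    invisible(NULL)
})

setMethod("show", "TriModule", function(object) {
    cat(sprintf("TriModule %d: %d gene(s), %d condition(s), %d time-point(s)%s\n",
                object@k, length(object@genes), length(object@conditions),
                length(object@timepoints),
                if (length(object@degenerate))
                    paste0(" [degenerate: ",
                           paste(object@degenerate, collapse = ","), "]")
                else ""))
    if (length(object@timepoints))
        cat(sprintf("  time: %s (%scontiguous)\n",
                    paste(object@timepoints, collapse = ", "),
                    if (object@timeContiguous) "" else "NOT "))
    invisible(NULL)
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %d planted module(s) in a %s tensor, noise density %g\n",
                length(object@modules),
                paste(object@dims, collapse = " x "), object@noiseDensity))
    invisible(NULL)
})

setMethod("truthModules", "GroundTruth", function(x) {
    labs <- x@axisLabels
    lapply(seq_along(x@modules), function(k) {
        m <- x@modules[[k]]
        new("TriModule", k = as.integer(k),
            genes = labs[[1]][m@genes],
            conditions = labs[[2]][m@conditions],
            timepoints = labs[[3]][m@timeStart:m@timeEnd],
            degenerate = character(0), timeContiguous = TRUE)
    })
})
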