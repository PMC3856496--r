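## Module extraction: turn converged factor columns into label sets by
## per-column sign correction and thresholding, plus the binary membership
## matrix used for downstream clustering of one axis.

.signCorrect <- function(x) {
    if (sum(x[x > 0]) < -sum(x[x < 0])) -x else x
}

## Threshold rule for a sign-corrected gene/condition column: members are the
## entries >= 0.5 * tau * (max + min) of the positive part of the column
## (negative entries counted as zero). On an all-positive column this is the
## midpoint rule on the raw entries; as soon as any entry is <= 0 the lower
## anchor is 0 and the cut sits at 0.5 * tau * max.
.thresholdPositive <- function(x, tau) {
    pos <- pmax(x, 0)
    if (!any(pos > 0)) return(NULL)          # degenerate: rule undefined
    x >= 0.5 * tau * (max(pos) + min(pos))
}

.extractFromMatrices <- function(U, V, W, labels, tau1, tau2, tau3) {
    for (tau in c(tau1, tau2, tau3))
        if (length(tau) != 1L || is.na(tau) || tau < 0 || tau > 1)
            stop("thresholds tau1, tau2, tau3 must lie in [0, 1]")
    K <- ncol(U)
    out <- vector("list", K)
    for (k in seq_len(K)) {
        uk <- .signCorrect(U[, k])
        vk <- .signCorrect(V[, k])
        wk <- W[, k]
        degenerate <- character(0)

        gsel <- .thresholdPositive(uk, tau1)
        if (is.null(gsel)) {
            degenerate <- c(degenerate, "gene")
            warning(sprintf("module %d: gene column has no strictly positive entries after sign correction; gene set left empty", k))
            gsel <- rep(FALSE, length(uk))
        }
        csel <- .thresholdPositive(vk, tau2)
        if (is.null(csel)) {
            degenerate <- c(degenerate, "condition")
            warning(sprintf("module %d: condition column has no strictly positive entries after sign correction; condition set left empty", k))
            csel <- rep(FALSE, length(vk))
        }
        ## the time rule uses the full column (not positives only), and W is
        ## not sign-corrected: after a completed fit it is already nonnegative
        if (all(wk == 0)) {
            degenerate <- c(degenerate, "time")
            warning(sprintf("module %d: time column is identically zero; time set left empty", k))
            tsel <- rep(FALSE, length(wk))
        } else {
            tsel <- wk >= 0.5 * tau3 * (max(wk) + min(wk))
        }

        tidx <- which(tsel)
        contiguous <- length(tidx) > 0L &&
            all(diff(tidx) == 1L)
        out[[k]] <- new("TriModule", k = as.integer(k),
                        genes = labels[[1]][gsel],
                        conditions = labels[[2]][csel],
                        timepoints = labels[[3]][tsel],
                        degenerate = degenerate,
                        timeContiguous = contiguous)
    }
    out
}

#' @describeIn extractModules extract from a converged fit, using its axis
#'   labels and (by default) the thresholds stored in its parameters
#' @param x a \linkS4class{TVFit}, or a \linkS4class{TVFactors}
#' @param tau1,tau2,tau3 thresholds in [0, 1] for the gene, condition and
#'   time modes
#' @param labels list of three axis label vectors (required for
#'   \code{TVFactors} input)
#' @param ... unused
#' @export
setMethod("extractModules", "TVFit",
          function(x, tau1 = x@params@tau[1], tau2 = x@params@tau[2],
                   tau3 = x@params@tau[3], ...) {
    .extractFromMatrices(x@factors@U, x@factors@V, x@factors@W,
                         x@axisLabels, tau1, tau2, tau3)
})

#' Module extraction by sign correction and thresholding
#'
#' For each factor column k, the gene and condition columns are first
#' sign-corrected (negated when the negative mass exceeds the positive mass),
#' then an entity joins module k when its loading reaches
#' \code{0.5 * tau * (max + min)} of the positive part of the column
#' (negative entries counted as zero, so a column with any nonpositive
#' background is cut at \code{0.5 * tau * max}). The time rule uses the full
#' column range instead of the positive part. Ties at the threshold are
#' inclusive (\code{>=}). Columns whose rule
#' is undefined (no strictly positive entries) contribute an empty set and
#' the module is flagged degenerate rather than dropped, so module indices
#' always align with factor columns. Whether each module's time set forms one
#' consecutive run is reported (the TV penalty encourages, but does not
#' force, contiguity).
#'
#' @return a list of \linkS4class{TriModule}
#' @examples
#' U <- cbind(c(4, 5, 1, 0.5)); V <- cbind(c(1, 2)); W <- cbind(c(.5, .5, 0))
#' f <- new("TVFactors", U = U, V = V, W = W,
#'          P = matrix(0, 2, 1), Q = matrix(0, 2, 1))
#' mods <- extractModules(f, labels = list(paste0("g", 1:4), c("c1", "c2"),
#'                                         paste0("t", 1:3)))
#' mods[[1]]
#' @rdname extractModules
#' @export
setMethod("extractModules", "TVFactors",
          function(x, labels, tau1 = 1, tau2 = 1, tau3 = 0.75, ...) {
    stopifnot(is.list(labels), length(labels) == 3L)
    .extractFromMatrices(x@U, x@V, x@W, labels, tau1, tau2, tau3)
})

#' Binary membership matrix of one axis
#'
#' Builds the entities x modules indicator matrix for a chosen axis:
#' \code{m[i, k] = 1} iff \code{labels[i]} belongs to module k's set on that
#' axis. With the condition axis of a patient tensor this is the patient
#' membership matrix used to group patients by shared module participation.
#'
#' @param modules list of \linkS4class{TriModule}
#' @param axis 1/2/3 or \code{"gene"}/\code{"condition"}/\code{"time"}
#' @param labels character vector of entity labels for that axis
#' @return a binary matrix, \code{length(labels)} rows and one column per
#'   module
#' @export
buildMembershipMatrix <- function(modules, axis, labels) {
    if (is.character(axis))
        axis <- match(axis, c("gene", "condition", "time"))
    if (is.na(axis) || length(axis) != 1L || !axis %in% 1:3)
        stop("'axis' must be 1, 2, 3 or 'gene'/'condition'/'time'")
    M <- matrix(0L, length(labels), length(modules),
                dimnames = list(labels,
                                if (length(modules))
                                    paste0("M", vapply(modules, slot, 1L, "k"))
                                else NULL))
    for (j in seq_along(modules)) {
        set <- switch(axis, modules[[j]]@genes, modules[[j]]@conditions,
                      modules[[j]]@timepoints)
        M[labels %in% set, j] <- 1L
    }
    M
}
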