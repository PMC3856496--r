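## Scoring discovered modules against planted ground truth: per-pair F1,
## Hungarian-matched mean Fscore, and normalized mutual information over the
## element universe.

## a module as a set over three disjoint namespaces (recycle0: an empty set
## must contribute no elements, not a bare prefix)
.moduleElements <- function(m) {
    c(paste0("gene:", m@genes, recycle0 = TRUE),
      paste0("cond:", m@conditions, recycle0 = TRUE),
      paste0("time:", m@timepoints, recycle0 = TRUE))
}

.asModuleList <- function(x) {
    if (is(x, "GroundTruth")) return(truthModules(x))
    if (is(x, "TriModule")) return(list(x))
    stopifnot(is.list(x))
    x
}

#' F1 agreement of one found module with one truth module
#'
#' Each module is treated as the set of its elements over three disjoint
#' namespaces (genes, conditions, time-points); precision and recall are the
#' usual set ratios and F1 their harmonic mean (0 when both are 0, in
#' particular for an empty found module).
#'
#' @param found,truth \linkS4class{TriModule} objects (a
#'   \linkS4class{PlantedModule} must first be converted through
#'   \code{\link{truthModules}})
#' @return scalar in [0, 1]
#' @export
moduleF1 <- function(found, truth) {
    ef <- .moduleElements(found)
    et <- .moduleElements(truth)
    if (!length(ef) || !length(et)) return(0)
    i <- length(intersect(ef, et))
    if (i == 0L) return(0)
    p <- i / length(ef)
    r <- i / length(et)
    2 * p * r / (p + r)
}

## maximum-weight one-to-one matching on the F1 matrix (found x truth);
## zero-weight pairs are never matched
.matchModules <- function(f1) {
    nf <- nrow(f1); nt <- ncol(f1)
    pairs <- data.frame(found = integer(0), truth = integer(0),
                        f1 = numeric(0))
    pos <- which(f1 > 0, arr.ind = TRUE)
    if (nrow(pos)) {
        types <- c(rep(FALSE, nf), rep(TRUE, nt))
        edges <- as.vector(t(cbind(pos[, 1], nf + pos[, 2])))
        g <- igraph::make_bipartite_graph(types, edges)
        mm <- igraph::max_bipartite_match(g, weights = f1[pos])
        mt <- mm$matching[seq_len(nf)]
        ok <- !is.na(mt)
        pairs <- data.frame(found = which(ok), truth = mt[ok] - nf,
                            f1 = f1[cbind(which(ok), mt[ok] - nf)])
    }
    pairs
}

#' Matched-mean Fscore of discovered modules
#'
#' Computes the full found x truth F1 matrix, takes the maximum-weight
#' one-to-one matching (the Hungarian assignment), and returns the mean
#' matched F1 over truth modules; truth modules left unmatched contribute 0.
#' Invariant to the ordering of modules on either side.
#'
#' @param found list of \linkS4class{TriModule}
#' @param truth a \linkS4class{GroundTruth} or list of
#'   \linkS4class{TriModule}
#' @return scalar in [0, 1]
#' @export
moduleFscore <- function(found, truth) {
    truth <- .asModuleList(truth)
    found <- .asModuleList(found)
    if (!length(truth)) stop("need at least one truth module")
    if (!length(found)) return(0)
    f1 <- outer(seq_along(found), seq_along(truth),
                Vectorize(function(i, j) moduleF1(found[[i]], truth[[j]])))
    f1 <- matrix(f1, length(found), length(truth))
    pairs <- .matchModules(f1)
    sum(pairs$f1) / length(truth)
}

## module list -> integer labeling of the universe; 0 is the shared
## background label. Ties (an element claimed by several modules) go to the
## module with the largest supplied score, else to the lowest module index.
.moduleLabeling <- function(modules, universe, scores = NULL) {
    lab <- integer(length(universe))
    names(lab) <- universe
    best <- rep(-Inf, length(universe))
    for (k in seq_along(modules)) {
        el <- intersect(.moduleElements(modules[[k]]), universe)
        if (!length(el)) next
        idx <- match(el, universe)
        sc <- if (is.null(scores)) rep(-k, length(el)) else scores[[k]][el]
        sc[is.na(sc)] <- -Inf
        take <- lab[idx] == 0L | sc > best[idx]
        lab[idx[take]] <- k
        best[idx[take]] <- sc[take]
    }
    lab
}

.entropy <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
}

## NMI with sqrt normalization from two integer labelings
.nmiLabelings <- function(x, y) {
    n <- length(x)
    tab <- table(x, y)
    px <- rowSums(tab) / n
    py <- colSums(tab) / n
    hx <- .entropy(px)
    hy <- .entropy(py)
    if (hx == 0 && hy == 0) return(if (all(x == y)) 1 else 0)
    if (hx == 0 || hy == 0) return(0)
    pij <- tab / n
    nz <- pij > 0
    mi <- sum(pij[nz] * log(pij[nz] / (px[row(pij)[nz]] * py[col(pij)[nz]])))
    mi / sqrt(hx * hy)
}

#' Normalized mutual information of discovered vs planted modules
#'
#' Converts each module list into a labeling of the element universe: every
#' element receives the index of the module containing it, elements in no
#' module share a background label, and an element claimed by several modules
#' goes to the module where its factor loading is largest (when a fit is
#' supplied) or to the lowest module index otherwise. Returns
#' \eqn{I(X;Y) / \sqrt{H(X) H(Y)}}. If both labelings have zero entropy the
#' value is 1 when they are identical and 0 otherwise; if exactly one has
#' zero entropy the value is 0.
#'
#' @param found list of \linkS4class{TriModule}
#' @param truth a \linkS4class{GroundTruth} or list of
#'   \linkS4class{TriModule}
#' @param universe character vector of all element labels (namespaced
#'   internally); defaults to the full axis-label universe of a
#'   \linkS4class{GroundTruth} \code{truth}
#' @param fit optional \linkS4class{TVFit}; when given, overlaps between
#'   found modules are resolved toward the larger absolute factor loading
#' @return scalar in [0, 1]
#' @export
moduleNMI <- function(found, truth, universe = NULL, fit = NULL) {
    truthL <- .asModuleList(truth)
    found <- .asModuleList(found)
    if (is.null(universe)) {
        if (is(truth, "GroundTruth")) {
            labs <- truth@axisLabels
            universe <- c(paste0("gene:", labs[[1]]),
                          paste0("cond:", labs[[2]]),
                          paste0("time:", labs[[3]]))
        } else {
            universe <- unique(unlist(c(lapply(found, .moduleElements),
                                        lapply(truthL, .moduleElements))))
        }
    } else {
        universe <- unique(universe)
    }
    scores <- NULL
    if (!is.null(fit)) {
        labs <- fit@axisLabels
        scores <- lapply(seq_along(found), function(k) {
            v <- c(abs(geneFactor(fit)[, k]), abs(conditionFactor(fit)[, k]),
                   abs(timeFactor(fit)[, k]))
            names(v) <- c(paste0("gene:", labs[[1]]),
                          paste0("cond:", labs[[2]]),
                          paste0("time:", labs[[3]]))
            v
        })
    }
    x <- .moduleLabeling(found, universe, scores)
    y <- .moduleLabeling(truthL, universe)
    .nmiLabelings(x, y)
}

#' Evaluate a module set against ground truth
#'
#' Bundles \code{\link{moduleFscore}} and \code{\link{moduleNMI}} with the
#' per-pair matching table, the usual report for a benchmark run.
#'
#' @inheritParams moduleNMI
#' @return list with \code{fscore}, \code{nmi}, \code{matching} (data frame
#'   of matched found/truth pairs with their F1), and \code{perModuleF1}
#'   (best F1 per truth module)
#' @export
evaluateModules <- function(found, truth, universe = NULL, fit = NULL) {
    truthL <- .asModuleList(truth)
    foundL <- .asModuleList(found)
    f1 <- matrix(0, length(foundL), length(truthL))
    for (i in seq_along(foundL))
        for (j in seq_along(truthL))
            f1[i, j] <- moduleF1(foundL[[i]], truthL[[j]])
    pairs <- .matchModules(f1)
    list(fscore = sum(pairs$f1) / length(truthL),
         nmi = moduleNMI(foundL, truth, universe = universe, fit = fit),
         matching = pairs,
         perModuleF1 = if (nrow(f1)) apply(f1, 2, max) else
             rep(0, length(truthL)))
}
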