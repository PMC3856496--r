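## The optimizer: penalized objective, closed-form gene/condition factor
## updates, the ADMM solver for the time factor, and the outer alternating
## loop.

#' Penalized factorization objective
#'
#' Evaluates
#' \deqn{||A - \sum_k u_k \circ v_k \circ w_k||_F^2 + \alpha \sum_k ||B w_k||_1,}
#' the squared Frobenius reconstruction error of the rank-K model plus the
#' total variation of the time profiles. The residual is computed through the
#' mode-1 unfolding identity.
#'
#' @param tensor an \linkS4class{InteractionTensor} or 3-d array
#' @param factors a \linkS4class{TVFactors}, or a list with elements
#'   \code{U}, \code{V}, \code{W}
#' @param alpha nonnegative total-variation weight
#' @return scalar objective value
#' @export
tvObjective <- function(tensor, factors, alpha) {
    a <- if (is(tensor, "InteractionTensor")) tensor@values else tensor
    U <- if (is(factors, "TVFactors")) factors@U else factors$U
    V <- if (is(factors, "TVFactors")) factors@V else factors$V
    W <- if (is(factors, "TVFactors")) factors@W else factors$W
    d <- dim(a)
    if (nrow(U) != d[1] || nrow(V) != d[2] || nrow(W) != d[3] ||
        ncol(U) != ncol(V) || ncol(V) != ncol(W))
        stop("factor dimensions do not match the tensor")
    if (alpha < 0) stop("'alpha' must be >= 0")
    A1 <- .unfold3(a, 1L)
    resid <- A1 - U %*% t(khatriRao(W, V))
    tv <- if (d[3] >= 2L) sum(abs(differenceMatrix(d[3]) %*% W)) else 0
    sum(resid^2) + alpha * tv
}

## Least-squares factor update X = Amode Ft (Ft' Ft)^{-1}, shared by the gene
## and condition subproblems. Near-singular cross-products get a tiny ridge;
## an outright rank-deficient system falls back to the pseudoinverse.
.lsFactor <- function(Amode, Ft, what) {
    FFt <- crossprod(Ft)
    kap <- kappa(FFt, exact = FALSE)
    if (!is.finite(kap) || kap > 1e12) {
        warning(sprintf(
            "%s update: factor columns are nearly collinear (condition %.3g); adding 1e-10 ridge",
            what, kap))
        FFt <- FFt + 1e-10 * diag(ncol(FFt))
    }
    G <- Amode %*% Ft
    out <- tryCatch(t(solve(FFt, t(G))), error = function(e) {
        warning(sprintf(
            "%s update: normal equations are singular, falling back to pseudoinverse",
            what))
        G %*% MASS::ginv(FFt)
    })
    out
}

#' Closed-form gene-factor update
#'
#' Solves the unconstrained least-squares subproblem
#' \eqn{\min_U ||A^{(1)} - U F||_F^2} with \eqn{F = (W \odot V)^T}, giving
#' \eqn{U = A^{(1)} F^T (F F^T)^{-1}}. The linear system is solved directly;
#' no explicit inverse is formed. A rank-deficient cross-product triggers a
#' warning and a pseudoinverse fallback.
#'
#' @param A1 mode-1 unfolding (genes x conditions*time)
#' @param V,W current condition and time factors
#' @return the updated U matrix
#' @export
solveGeneFactor <- function(A1, V, W) {
    if (ncol(V) != ncol(W)) stop("V and W must have the same column count")
    if (ncol(A1) != nrow(V) * nrow(W))
        stop("A1 has ", ncol(A1), " columns; expected ", nrow(V) * nrow(W))
    .lsFactor(A1, khatriRao(W, V), "gene factor")
}

#' Closed-form condition-factor update
#'
#' Identical contract to \code{\link{solveGeneFactor}} with
#' \eqn{F = (W \odot U)^T}: \eqn{V = A^{(2)} F^T (F F^T)^{-1}}.
#'
#' @param A2 mode-2 unfolding (conditions x genes*time)
#' @param U,W current gene and time factors
#' @return the updated V matrix
#' @export
solveConditionFactor <- function(A2, U, W) {
    if (ncol(U) != ncol(W)) stop("U and W must have the same column count")
    if (ncol(A2) != nrow(U) * nrow(W))
        stop("A2 has ", ncol(A2), " columns; expected ", nrow(U) * nrow(W))
    .lsFactor(A2, khatriRao(W, U), "condition factor")
}

#' ADMM solver for the time-factor subproblem
#'
#' Minimizes \eqn{||A^{(3)} - W F||_F^2 + \alpha \sum_k ||B w_k||_1} subject
#' to \eqn{W \ge 0} and unit column sums, with \eqn{F = (V \odot U)^T}. The
#' L1 term is split off through an auxiliary variable P (with scaled dual Q)
#' and the three ADMM updates are iterated: a quadratic solve for
#' \code{vec(W)}, entrywise soft-thresholding for P, and the dual ascent for
#' Q. The quadratic system matrix is assembled once per call and its
#' factorization reused across inner iterations.
#'
#' Two treatments of the column-sum constraint are available.
#' \code{constrained = TRUE} (default) enforces \eqn{1^T w_k = 1} exactly
#' inside every W-update through a KKT system, so the inner loop converges to
#' the sum-constrained minimizer; \code{constrained = FALSE} iterates the
#' plain unconstrained updates and only normalizes at the end. Either way the
#' returned \code{W} is projected onto the feasible set on exit: negative
#' entries are clipped to zero and each column is divided by its sum (an
#' all-zero column is reset to the uniform profile with a warning). The
#' pre-projection iterate is returned as \code{Wraw}.
#'
#' @param A3 mode-3 unfolding (time x genes*conditions)
#' @param U,V current gene and condition factors
#' @param alpha nonnegative TV weight
#' @param rho positive ADMM penalty
#' @param P0,Q0 starting values for the split variable and scaled dual,
#'   \code{(n3-1) x K}; zero matrices when \code{NULL}
#' @param innerTol stop when both the iterate change \eqn{||W_s - W_{s-1}||_F}
#'   and the primal residual \eqn{||B W_s - P_s||_F} drop to this tolerance
#' @param innerMaxIter iteration cap
#' @param constrained see Details
#' @return list with elements \code{W} (feasible), \code{Wraw}
#'   (pre-projection), \code{P}, \code{Q}, \code{nInner},
#'   \code{primalResiduals} (one per inner iteration), and the cached
#'   cross-products \code{G} (\eqn{A^{(3)} F^T}) and \code{FFt}
#' @export
solveTimeFactorADMM <- function(A3, U, V, alpha, rho = 1, P0 = NULL,
                                Q0 = NULL, innerTol = 1e-6,
                                innerMaxIter = 200L, constrained = TRUE) {
    if (rho <= 0) stop("'rho' must be > 0")
    if (alpha < 0) stop("'alpha' must be >= 0")
    K <- ncol(U)
    n3 <- nrow(A3)
    if (ncol(A3) != nrow(U) * nrow(V))
        stop("A3 has ", ncol(A3), " columns; expected ", nrow(U) * nrow(V))
    Ft <- khatriRao(V, U)                       # (n1 n2) x K
    FFt <- crossprod(Ft)
    G <- A3 %*% Ft                              # n3 x K
    if (any(!is.finite(G)) || any(!is.finite(FFt)))
        stop("non-finite values in the time-factor system")
    B <- differenceMatrix(n3)
    BtB <- crossprod(B)
    S <- kronecker(FFt, 2 * diag(n3)) + rho * kronecker(diag(K), BtB)
    if (constrained) {
        Cm <- kronecker(diag(K), matrix(1, 1, n3))
        KKT <- rbind(cbind(S, t(Cm)), cbind(Cm, matrix(0, K, K)))
        qrS <- qr(KKT)
        if (qrS$rank < nrow(KKT))
            stop("time-factor system is singular: factor columns of U/V are ",
                 "degenerate (collinear)")
    } else {
        ch <- tryCatch(chol(S), error = function(e)
            stop("time-factor system is singular: factor columns of U/V are ",
                 "degenerate (collinear)"))
    }
    if (is.null(P0)) P0 <- matrix(0, n3 - 1L, K)
    if (is.null(Q0)) Q0 <- matrix(0, n3 - 1L, K)
    P <- P0; Q <- Q0
    W <- matrix(1 / n3, n3, K)
    primal <- numeric(0)
    nInner <- 0L
    for (s in seq_len(innerMaxIter)) {
        nInner <- s
        Wprev <- W
        rhs <- as.vector(rho * crossprod(B, P - Q / rho) + 2 * G)
        if (constrained) {
            sol <- qr.coef(qrS, c(rhs, rep(1, K)))
            W <- matrix(sol[seq_len(n3 * K)], n3, K)
        } else {
            W <- matrix(backsolve(ch, forwardsolve(t(ch), rhs)), n3, K)
        }
        BW <- B %*% W
        P <- softThreshold(BW + Q / rho, alpha / rho)
        Q <- Q + rho * (BW - P)
        pr <- sqrt(sum((BW - P)^2))
        primal <- c(primal, pr)
        if (any(!is.finite(W)))
            stop("non-finite values in the ADMM iterates")
        if (max(sqrt(sum((W - Wprev)^2)), pr) <= innerTol) break
    }
    Wraw <- W
    W[W < 0] <- 0
    cs <- colSums(W)
    zero <- cs == 0
    if (any(zero)) {
        warning("time factor column(s) ", paste(which(zero), collapse = ", "),
                " collapsed to zero; reset to the uniform profile")
        W[, zero] <- 1 / n3
        cs[zero] <- 1
    }
    W <- sweep(W, 2L, cs, "/")
    list(W = W, Wraw = Wraw, P = P, Q = Q, nInner = nInner,
         primalResiduals = primal, G = G, FFt = FFt)
}

#' Fit the total-variation regularized factorization
#'
#' Alternates the three subproblem solvers until the summed squared factor
#' change drops below \code{outerTol} (default 0.001) or \code{outerMaxIter}
#' is reached. Each outer iteration performs, in order: the gene-factor
#' update (from the previous W and V), the condition-factor update (from the
#' previous W and the fresh U -- the stale/fresh mix is deliberate
#' Gauss-Seidel ordering), and the ADMM time-factor update with freshly
#' randomized P, Q starting values drawn from the seeded RNG. The penalized
#' objective is recorded after every outer iteration.
#'
#' All randomness (initialization and the per-iteration ADMM starts) is
#' driven by \code{seed}, so repeated calls with identical arguments return
#' identical fits.
#'
#' @param tensor an \linkS4class{InteractionTensor} or 3-d array
#' @param K number of modules (rank)
#' @param alpha total-variation weight (default 10)
#' @param rho ADMM penalty (default 1)
#' @param tau extraction thresholds kept with the fit and used as defaults by
#'   \code{\link{extractModules}}
#' @param outerTol,outerMaxIter outer-loop stopping rule
#' @param innerTol,innerMaxIter ADMM stopping rule
#' @param seed RNG seed
#' @param wUpdate \code{"constrained"} or \code{"projected"}, see
#'   \code{\link{solveTimeFactorADMM}}
#' @param verbose print one line per outer iteration
#' @return a \linkS4class{TVFit}
#' @examples
#' sim <- generatePlantedTensor(n1 = 30, n2 = 30, n3 = 10, K = 2,
#'                              genesPerModule = 10, conditionsPerModule = 10,
#'                              intervalLength = 4, noiseDensity = 0, seed = 1)
#' fit <- tvFactorize(sim$tensor, K = 2, alpha = 1, seed = 1)
#' isConverged(fit)
#' @export
tvFactorize <- function(tensor, K, alpha = 10, rho = 1, tau = c(1, 1, 0.75),
                        outerTol = 0.001, outerMaxIter = 100L,
                        innerTol = 1e-6, innerMaxIter = 200L, seed = 1L,
                        wUpdate = c("constrained", "projected"),
                        verbose = FALSE) {
    params <- TVParams(K = K, alpha = alpha, rho = rho, tau = tau,
                       outerTol = outerTol, outerMaxIter = outerMaxIter,
                       innerTol = innerTol, innerMaxIter = innerMaxIter,
                       seed = seed, wUpdate = match.arg(wUpdate))
    a <- if (is(tensor, "InteractionTensor")) tensor@values else tensor
    d <- dim(a)
    if (length(d) != 3L) stop("'tensor' must be three-dimensional")
    if (d[3] < 2L) stop("need at least two time-points")
    labs <- dimnames(a)
    if (is.null(labs))
        labs <- list(paste0("g", seq_len(d[1])), paste0("c", seq_len(d[2])),
                     paste0("t", seq_len(d[3])))
    K <- params@K
    n1 <- d[1]; n2 <- d[2]; n3 <- d[3]

    A1 <- .unfold3(a, 1L)
    A2 <- .unfold3(a, 2L)
    A3 <- .unfold3(a, 3L)
    normA2 <- sum(A1^2)
    B <- differenceMatrix(n3)

    set.seed(params@seed)
    ## scale-matched random start: keeps the first residual on the order of
    ## ||A||_F instead of blowing up for large tensors
    sc <- sqrt(normA2) / (K * sqrt(n1 * n2))
    if (sc == 0) sc <- 1
    U <- matrix(stats::rnorm(n1 * K), n1, K) * sc
    V <- matrix(stats::rnorm(n2 * K), n2, K) * sc
    W <- matrix(stats::runif(n3 * K), n3, K)
    W <- sweep(W, 2L, colSums(W), "/")
    P <- matrix(0, n3 - 1L, K)
    Q <- matrix(0, n3 - 1L, K)

    trace <- numeric(0)
    converged <- FALSE
    maxViol <- 0
    it <- 0L
    for (it in seq_len(params@outerMaxIter)) {
        Uo <- U; Vo <- V; Wo <- W
        U <- solveGeneFactor(A1, V, W)
        V <- solveConditionFactor(A2, U, W)
        P0 <- matrix(stats::runif((n3 - 1L) * K), n3 - 1L, K) / n3
        Q0 <- matrix(stats::runif((n3 - 1L) * K), n3 - 1L, K) / n3
        ws <- solveTimeFactorADMM(A3, U, V, alpha = params@alpha,
                                  rho = params@rho, P0 = P0, Q0 = Q0,
                                  innerTol = params@innerTol,
                                  innerMaxIter = params@innerMaxIter,
                                  constrained = params@wUpdate == "constrained")
        W <- ws$W; P <- ws$P; Q <- ws$Q
        ## cheap objective through cached cross-products:
        ## ||A - WF||^2 = ||A||^2 - 2 <W, G> + <W'W, FF'>
        resid <- normA2 - 2 * sum(W * ws$G) + sum(crossprod(W) * ws$FFt)
        obj <- resid + params@alpha * sum(abs(B %*% W))
        trace <- c(trace, obj)
        maxViol <- max(maxViol, -min(0, min(W)), max(abs(colSums(W) - 1)))
        if (verbose)
            message(sprintf("outer %3d: objective %.6g (inner %d)", it, obj,
                            ws$nInner))
        delta <- sum((U - Uo)^2) + sum((V - Vo)^2) + sum((W - Wo)^2)
        if (delta <= params@outerTol) { converged <- TRUE; break }
    }
    if (any(!is.finite(trace)))
        stop("objective became non-finite during the fit")
    new("TVFit",
        factors = new("TVFactors", U = U, V = V, W = W, P = P, Q = Q),
        objectiveTrace = trace, nOuterIterations = it,
        converged = converged, params = params, axisLabels = labs,
        wConstraintViolation = maxViol, restartObjectives = numeric(0))
}

#' Best fit over random restarts
#'
#' Runs \code{\link{tvFactorize}} with seeds \code{seed + 0:(nRestarts-1)}
#' and keeps the run whose final penalized objective is lowest -- the usual
#' guard against local minima of alternating least squares.
#'
#' @param tensor an \linkS4class{InteractionTensor} or 3-d array
#' @param K number of modules
#' @param nRestarts number of random restarts (default 5)
#' @param seed base seed; restart r uses \code{seed + r - 1}
#' @param ... forwarded to \code{\link{tvFactorize}}
#' @return the best \linkS4class{TVFit}; its \code{restartObjectives} slot
#'   holds the final objectives of all restarts
#' @export
tvFactorizeRestarts <- function(tensor, K, nRestarts = 5L, seed = 1L, ...) {
    stopifnot(nRestarts >= 1L)
    fits <- lapply(seq_len(nRestarts), function(r)
        tvFactorize(tensor, K = K, seed = seed + r - 1L, ...))
    objs <- vapply(fits, function(f)
        f@objectiveTrace[length(f@objectiveTrace)], numeric(1))
    best <- fits[[which.min(objs)]]
    best@restartObjectives <- objs
    best
}
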