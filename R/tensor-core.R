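## Core linear-algebra primitives shared by every solver step: mode
## unfoldings, Khatri-Rao products, the first-difference matrix and the
## entrywise shrinkage operator.

#' Mode-p unfolding (matricization) of a third-order tensor
#'
#' Rearranges the tensor into a matrix along one mode. The column ordering is
#' the one under which the rank-K identities
#' \deqn{A^{(1)} = U (W \odot V)^T,\quad A^{(2)} = V (W \odot U)^T,\quad
#'       A^{(3)} = W (V \odot U)^T}
#' hold, with \eqn{\odot} the column-wise Kronecker (Khatri-Rao) product of
#' \code{\link{khatriRao}}: the lower-numbered retained mode varies fastest.
#' Concretely (1-based), \code{unfold(x, 1)[r, s + (t-1)*n2] == x[r, s, t]},
#' \code{unfold(x, 2)[s, r + (t-1)*n1] == x[r, s, t]} and
#' \code{unfold(x, 3)[t, r + (s-1)*n1] == x[r, s, t]}.
#'
#' @param x an \linkS4class{InteractionTensor} or a 3-d array
#' @param mode one of 1, 2, 3
#' @return a matrix of size \code{n_mode} x (product of the other two extents)
#' @examples
#' a <- array(seq_len(24), c(2, 3, 4))
#' dim(unfold(a, 2))  # 3 x 8
#' @rdname unfold
#' @export
setMethod("unfold", "array", function(x, mode) {
    stopifnot(length(dim(x)) == 3L)
    .unfold3(x, mode)
})

#' @rdname unfold
#' @export
setMethod("unfold", "InteractionTensor", function(x, mode) {
    .unfold3(x@values, mode)
})

.unfold3 <- function(a, mode) {
    if (length(mode) != 1L || !mode %in% 1:3)
        stop("'mode' must be one of 1, 2, 3")
    d <- dim(a)
    dimnames(a) <- NULL
    m <- switch(mode,
        { dim(a) <- c(d[1], d[2] * d[3]); a },
        { a <- aperm(a, c(2, 1, 3)); dim(a) <- c(d[2], d[1] * d[3]); a },
        { a <- aperm(a, c(3, 1, 2)); dim(a) <- c(d[3], d[1] * d[2]); a })
    m
}

#' Fold a mode-p unfolding back into a tensor
#'
#' Inverse of \code{\link{unfold}} under the same column-ordering convention.
#'
#' @param m matrix produced by (or shaped like) a mode-\code{mode} unfolding
#' @param mode one of 1, 2, 3
#' @param dims integer length-3 target dimensions
#' @return a 3-d array
#' @export
foldTensor <- function(m, mode, dims) {
    if (length(mode) != 1L || !mode %in% 1:3)
        stop("'mode' must be one of 1, 2, 3")
    stopifnot(length(dims) == 3L, nrow(m) == dims[mode],
              ncol(m) == prod(dims[-mode]))
    a <- switch(mode,
        { dim(m) <- dims; m },
        { dim(m) <- dims[c(2, 1, 3)]; aperm(m, c(2, 1, 3)) },
        { dim(m) <- dims[c(3, 1, 2)]; aperm(m, c(2, 3, 1)) })
    a
}

#' Khatri-Rao (column-wise Kronecker) product
#'
#' Column k of the result is \code{kronecker(X[, k], Y[, k])}, i.e. the second
#' argument varies fastest -- the ordering consistent with the column maps of
#' \code{\link{unfold}}.
#'
#' @param X,Y matrices with the same number of columns
#' @return an \code{(nrow(X) * nrow(Y)) x K} matrix
#' @examples
#' khatriRao(diag(2), diag(2))  # columns e1, e4
#' @export
khatriRao <- function(X, Y) {
    X <- as.matrix(X); Y <- as.matrix(Y)
    if (ncol(X) != ncol(Y))
        stop("column counts differ: ", ncol(X), " vs ", ncol(Y))
    na <- nrow(X); nb <- nrow(Y)
    X[rep(seq_len(na), each = nb), , drop = FALSE] *
        Y[rep.int(seq_len(nb), na), , drop = FALSE]
}

#' Entrywise soft-thresholding (shrinkage) operator
#'
#' Shrinks each entry toward zero by \code{tau}:
#' \eqn{m \mapsto sign(m) \max(|m| - \tau, 0)}, the proximal map of the L1
#' norm. Zero entries map to zero.
#'
#' @param M numeric matrix (or vector)
#' @param tau nonnegative scalar threshold
#' @return object of the same shape as \code{M}
#' @export
softThreshold <- function(M, tau) {
    if (length(tau) != 1L || is.na(tau) || tau < 0)
        stop("'tau' must be a single nonnegative number")
    sign(M) * pmax(abs(M) - tau, 0)
}

#' First-difference matrix for the total-variation penalty
#'
#' The \code{(n3-1) x n3} matrix B with \code{B[i, i] = 1},
#' \code{B[i, i+1] = -1} and zeros elsewhere, so that \code{B \%*\% w} holds
#' the first differences \eqn{w_i - w_{i+1}} of a time profile and
#' \code{sum(abs(B \%*\% w))} is its total variation.
#'
#' @param n3 time-axis length, at least 2
#' @return the difference matrix
#' @examples
#' differenceMatrix(4)
#' @export
differenceMatrix <- function(n3) {
    if (length(n3) != 1L || is.na(n3) || n3 < 2)
        stop("'n3' must be >= 2: total variation is undefined on a single ",
             "time point")
    n3 <- as.integer(n3)
    B <- matrix(0, n3 - 1L, n3)
    idx <- seq_len(n3 - 1L)
    B[cbind(idx, idx)] <- 1
    B[cbind(idx, idx + 1L)] <- -1
    B
}
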