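# Independent reference implementations used as oracles. Each is written
# directly from the mathematical definition (index enumeration, per-column
# Kronecker, brute-force summation, grid search) and shares no code with the
# package internals it checks.

# rank-K tensor from factor columns by enumerating every (r, s, t)
refRankTensor <- function(U, V, W) {
  n1 <- nrow(U); n2 <- nrow(V); n3 <- nrow(W)
  a <- array(0, c(n1, n2, n3))
  for (r in seq_len(n1)) for (s in seq_len(n2)) for (t in seq_len(n3))
    a[r, s, t] <- sum(U[r, ] * V[s, ] * W[t, ])
  a
}

# mode-p unfolding by looping over all entries with the documented index maps
refUnfold <- function(a, mode) {
  d <- dim(a)
  m <- switch(mode,
              matrix(0, d[1], d[2] * d[3]),
              matrix(0, d[2], d[1] * d[3]),
              matrix(0, d[3], d[1] * d[2]))
  for (r in seq_len(d[1])) for (s in seq_len(d[2])) for (t in seq_len(d[3])) {
    if (mode == 1) m[r, s + (t - 1) * d[2]] <- a[r, s, t]
    if (mode == 2) m[s, r + (t - 1) * d[1]] <- a[r, s, t]
    if (mode == 3) m[t, r + (s - 1) * d[1]] <- a[r, s, t]
  }
  m
}

# Khatri-Rao one column at a time via base kronecker()
refKhatriRao <- function(X, Y) {
  out <- matrix(0, nrow(X) * nrow(Y), ncol(X))
  for (k in seq_len(ncol(X))) out[, k] <- kronecker(X[, k], Y[, k])
  out
}

# full objective by triple-loop summation of both terms
refObjective <- function(a, U, V, W, alpha) {
  d <- dim(a)
  sq <- 0
  for (r in seq_len(d[1])) for (s in seq_len(d[2])) for (t in seq_len(d[3]))
    sq <- sq + (a[r, s, t] - sum(U[r, ] * V[s, ] * W[t, ]))^2
  tv <- 0
  for (k in seq_len(ncol(W))) for (t in seq_len(d[3] - 1))
    tv <- tv + abs(W[t, k] - W[t + 1, k])
  sq + alpha * tv
}

# time-factor objective for a single column (K = 1)
refTimeObjective <- function(w, A3, f, alpha) {
  sum((A3 - w %*% t(f))^2) + alpha * sum(abs(diff(w) * -1))
}

# dense grid search over the probability simplex in 4 dimensions at
# resolution 1/100 for the K = 1 time subproblem
refSimplexGridMin <- function(A3, f, alpha) {
  n <- 100L
  cmb <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
  cmb <- cmb[cmb$a + cmb$b + cmb$c <= n, ]
  Wg <- cbind(cmb$a, cmb$b, cmb$c, n - cmb$a - cmb$b - cmb$c) / n
  nA <- sum(A3^2); Af <- as.vector(A3 %*% f); ff <- sum(f^2)
  vals <- nA - 2 * (Wg %*% Af) + ff * rowSums(Wg^2)
  tv <- abs(Wg[, 1] - Wg[, 2]) + abs(Wg[, 2] - Wg[, 3]) +
    abs(Wg[, 3] - Wg[, 4])
  min(vals + alpha * tv)
}

# one-pass reference of the extraction step written straight from the
# pseudocode (sign correction, positive-part thresholds, full-column time
# rule); returns plain index sets
refExtract <- function(U, V, W, tau1, tau2, tau3) {
  out <- list()
  for (k in seq_len(ncol(U))) {
    uk <- U[, k]
    if (sum(uk[uk > 0]) < -sum(uk[uk < 0])) uk <- -uk
    vk <- V[, k]
    if (sum(vk[vk > 0]) < -sum(vk[vk < 0])) vk <- -vk
    up <- pmax(uk, 0); vp <- pmax(vk, 0)
    g <- if (any(up > 0))
      which(uk >= 0.5 * tau1 * (max(up) + min(up))) else integer(0)
    cc <- if (any(vp > 0))
      which(vk >= 0.5 * tau2 * (max(vp) + min(vp))) else integer(0)
    wk <- W[, k]
    tt <- if (any(wk != 0))
      which(wk >= 0.5 * tau3 * (max(wk) + min(wk))) else integer(0)
    out[[k]] <- list(genes = g, conditions = cc, times = tt)
  }
  out
}

# small helper: TriModule from plain label sets
mkModule <- function(k, genes, conditions, timepoints) {
  new("TriModule", k = as.integer(k), genes = as.character(genes),
      conditions = as.character(conditions),
      timepoints = as.character(timepoints), degenerate = character(0),
      timeContiguous = TRUE)
}

# sum-to-one nonnegative columns
simplexCols <- function(M) {
  M <- abs(M)
  sweep(M, 2, colSums(M), "/")
}
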