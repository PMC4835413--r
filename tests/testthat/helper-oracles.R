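# Independent brute-force oracles used to pin the semantics of the fast
# implementations.  These deliberately use the most literal formulation
# available (scalar loops, full enumeration) and share no code with R/.

# Mean |w| over unordered pairs by explicit double loop.
oracle_mean_strength <- function(w) {
  n <- nrow(w); s <- 0; cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- s + abs(w[i, j]); cnt <- cnt + 1
  }
  s / cnt
}

# Scalar triple-loop Floyd-Warshall over edge lengths 1/|w| (|w| >= tau).
oracle_path_length <- function(w, tau) {
  n <- nrow(w)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && abs(w[i, j]) >= tau) d[i, j] <- 1 / abs(w[i, j])
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  off <- d[upper.tri(d)]
  if (!any(is.finite(off))) return(Inf)
  mean(off[is.finite(off)])
}

# Onnela weighted clustering by exhaustive enumeration of node triples.
oracle_clustering <- function(w, tau) {
  n <- nrow(w)
  a <- abs(w) >= tau; diag(a) <- FALSE
  wn <- abs(w) * a
  mx <- max(wn)
  if (mx == 0) return(0)
  wn <- wn / mx
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ])
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (p in seq_len(k - 1)) for (q in (p + 1):k) {
      j <- nb[p]; h <- nb[q]
      s <- s + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
    }
    ci[i] <- 2 * s / (k * (k - 1))
  }
  mean(ci)
}

# Classic unweighted clustering coefficient (closed neighbour pairs).
oracle_unweighted_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k < 2) next
    closed <- 0
    for (p in seq_len(k - 1)) for (q in (p + 1):k)
      if (adj[nb[p], nb[q]]) closed <- closed + 1
    ci[i] <- closed / (k * (k - 1) / 2)
  }
  mean(ci)
}

# Two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins (probability-ordering rule; the 1e-7 factor
# absorbs floating-point ties, as is conventional).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n2, k)
  pobs <- dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Exhaustive two-sided Spearman permutation p (all n! permutations).
oracle_spearman_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  rx <- rank(x); ry <- rank(y)
  robs <- cor(rx, ry)
  rhos <- vapply(perms(seq_along(y)), function(p) cor(rx, ry[p]), 0)
  pge <- mean(rhos >= robs - 1e-12)
  ple <- mean(rhos <= robs + 1e-12)
  min(1, 2 * min(pge, ple))
}

# Random symmetric signed weight matrix with zero diagonal.
random_signed_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, -1, 1), n)
  w <- (m + t(m)) / 2
  diag(w) <- 0
  w
}

# Small fast cohort settings shared by simulation-based tests.
quick_config <- function(..., seed = 1) {
  cohort_config(n_migraine = 2, n_mwa = 1, n_control = 2, n_channels = 10,
                sampling_rate = 600, duration_s = 10, seed = seed, ...)
}
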