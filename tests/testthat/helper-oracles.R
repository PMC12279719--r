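# Independent oracles and small fixture builders. Everything here is
# deliberately naive (cubic relaxation, exhaustive enumeration, textbook
# formulas) and shares no code with the package implementation.

# All-pairs shortest paths by Floyd-Warshall relaxation on a length matrix
# (Inf = missing edge).
fw_distances <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Binary global efficiency from the textbook definition (hop distances).
binary_global_efficiency_oracle <- function(a) {
  n <- nrow(a)
  d <- fw_distances(ifelse(a > 0, 1, Inf))
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Binary local (regional) efficiency: hop distances within the subgraph
# induced by each node's neighbours.
binary_regional_efficiency_oracle <- function(a) {
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- a[nb, nb, drop = FALSE]
    d <- fw_distances(ifelse(sub > 0, 1, Inf))
    inv <- 1 / d
    diag(inv) <- 0
    out[i] <- sum(inv) / (k * (k - 1))
  }
  out
}

# Random symmetric binary adjacency with zero diagonal.
random_binary_graph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# Random symmetric weighted graph with zero diagonal.
random_weighted_graph <- function(n, p, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  present <- runif(sum(ut)) < p
  w[ut] <- ifelse(present, runif(sum(ut), 0.1, 5), 0)
  w + t(w)
}

# Newman weighted modularity of a given 2-colouring.
modularity_of_partition <- function(w, membership) {
  m2 <- sum(w)            # 2m
  k <- rowSums(w)
  q <- 0
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(nrow(w))) {
      if (membership[i] == membership[j]) {
        q <- q + w[i, j] - k[i] * k[j] / m2
      }
    }
  }
  q / m2
}

# Best modularity over all 2-partitions (exhaustive).
best_two_partition_modularity <- function(w) {
  n <- nrow(w)
  best <- -Inf
  for (code in 0:(2^(n - 1) - 1)) {
    memb <- c(0, as.integer(intToBits(code))[seq_len(n - 1)])
    best <- max(best, modularity_of_partition(w, memb))
  }
  best
}

# Brute-force Benjamini-Hochberg: try every k explicitly.
bh_oracle <- function(p, q) {
  m <- length(p)
  sorted <- sort(p)
  kstar <- 0
  for (k in seq_len(m)) {
    if (sorted[k] <= k * q / m) kstar <- k
  }
  crit <- if (kstar > 0) sorted[kstar] else 0
  list(rejected = p <= crit & kstar > 0, critical_p = crit)
}

# Textbook partial correlation via explicit normal equations.
partial_pearson_oracle <- function(x, y, covs) {
  X <- cbind(1, as.matrix(covs))
  bx <- solve(t(X) %*% X, t(X) %*% x)
  by <- solve(t(X) %*% X, t(X) %*% y)
  rx <- x - X %*% bx
  ry <- y - X %*% by
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exhaustive bootstrap distribution for an n=7 mediation triple: the 7^7
# ordered resamples collapse to the C(13,6) multisets of size 7, each with
# multinomial weight. Returns ab values with probabilities (degenerate
# resamples dropped and weights renormalized, matching the redraw rule).
enumerate_boot_ab <- function(iv, m, dv) {
  n <- 7L
  stopifnot(length(iv) == n)
  combos <- utils::combn(n + n - 1, n - 1)   # stars and bars
  vals <- numeric(0)
  wts <- numeric(0)
  lf7 <- lfactorial(n)
  for (col in seq_len(ncol(combos))) {
    bars <- combos[, col]
    counts <- diff(c(0, bars, n + n)) - 1
    stopifnot(sum(counts) == n)
    idx <- rep(seq_len(n), counts)
    ivb <- iv[idx]; mb <- m[idx]; dvb <- dv[idx]
    if (var(ivb) < 1e-12 || var(mb) < 1e-12 || var(dvb) < 1e-12) next
    fa <- lm(mb ~ ivb)
    fb <- lm(dvb ~ ivb + mb)
    # rank-deficient resamples correspond to redraws in the implementation
    if (anyNA(coef(fa)) || anyNA(coef(fb))) next
    vals <- c(vals, coef(fa)[["ivb"]] * coef(fb)[["mb"]])
    wts <- c(wts, exp(lf7 - sum(lfactorial(counts))))
  }
  list(ab = vals, prob = wts / sum(wts))
}

# Weighted CDF evaluated at q.
weighted_cdf <- function(x, w, q) sum(w[x <= q]) / sum(w)

# Weighted inverse-CDF quantile.
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

# Bias-corrected bounds from an exact (weighted) bootstrap distribution.
bc_bounds_oracle <- function(ab, prob, estimate, level = 0.95) {
  below <- sum(prob[ab < estimate])
  ties <- sum(prob[ab == estimate])
  prop <- below / max(1 - ties, 1e-12)
  z0 <- qnorm(min(max(prop, 1e-12), 1 - 1e-12))
  za <- qnorm((1 + level) / 2)
  weighted_quantile(ab, prob, c(pnorm(2 * z0 - za), pnorm(2 * z0 + za)))
}

# Shared small synthetic cohort (computed once per test run).
.fixture_env <- new.env()

fixture_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_cohort(
      simulation_params(n_subjects = 90, seed = 424242))
  }
  .fixture_env$sim
}

fixture_profiles <- function() {
  if (is.null(.fixture_env$prof)) {
    .fixture_env$prof <- cohort_profiles(fixture_sim()$cohort, seed = 7)
  }
  .fixture_env$prof
}
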