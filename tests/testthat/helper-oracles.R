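# Independent brute-force implementations used as oracles. These deliberately
# follow the defining formulas with literal loops and share no code with the
# package's fast paths.

# multilayer modularity as a literal quadruple sum over (i, j, s, r)
brute_modularity <- function(tensor, labels, gamma = 1, omega = 1) {
  N <- dim(tensor)[1]; T <- dim(tensor)[3]
  k <- matrix(0, N, T)
  twom <- numeric(T)
  for (s in seq_len(T)) {
    for (i in seq_len(N)) k[i, s] <- sum(tensor[i, , s])
    twom[s] <- sum(k[, s])
  }
  twomu <- sum(twom) + 2 * omega * N * (T - 1)
  q <- 0
  for (s in seq_len(T)) for (r in seq_len(T)) {
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (labels[i, s] != labels[j, r]) next
      if (s == r)
        q <- q + tensor[i, j, s] - gamma * k[i, s] * k[j, s] / twom[s]
      if (i == j && abs(s - r) == 1)
        q <- q + omega
    }
  }
  q / twomu
}

# Pearson correlation from the textbook definition, explicit loops
brute_correlation <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (t in seq_len(n)) {
    sxy <- sxy + (x[t] - mx) * (y[t] - my)
    sxx <- sxx + (x[t] - mx)^2
    syy <- syy + (y[t] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Benjamini-Hochberg step-up adjustment, O(m^2) from the definition:
# adjusted p_(i) = min over j >= i of min(1, m * p_(j) / j)
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (pos in seq_len(m)) {
    vals <- numeric(0)
    for (pos2 in pos:m)
      vals <- c(vals, min(1, m * p[ord[pos2]] / pos2))
    adj[ord[pos]] <- min(vals)
  }
  adj
}

# symmetric zero-diagonal tensor with uniform random weights
random_tensor <- function(N, T, seed, density = 1) {
  set.seed(seed)
  tensor <- array(0, dim = c(N, N, T))
  for (s in seq_len(T)) {
    W <- matrix(runif(N * N), N, N)
    if (density < 1) W[matrix(runif(N * N) > density, N, N)] <- 0
    W <- (W + t(W)) / 2
    diag(W) <- 0
    tensor[, , s] <- W
  }
  tensor
}
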