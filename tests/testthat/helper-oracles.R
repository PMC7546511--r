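# Independent oracles used across the suite. These deliberately avoid the
# package's computational path: the likelihood oracle works on the fully
# stacked N*L system with generic solve()/det(), the multiplicity oracles
# implement the step rules directly from their definitions.

# Brute-force GLS + multivariate-normal log-likelihood for a gene at fixed
# Sigma: stacks all samples into one system and sums per-sample densities.
oracleLoglik <- function(gene, form, Sigma) {
  Y <- gene@Y
  cond <- gene@condition
  L <- nrow(Y)
  J <- nlevels(cond)
  jIdx <- as.integer(cond)
  Xs <- do.call(rbind, lapply(jIdx, function(j) designBlock(form, J, L, j)))
  ys <- as.vector(Y)                      # column-major: sample-by-sample
  N <- ncol(Y)
  Wbig <- kronecker(diag(N), solve(Sigma))
  A <- t(Xs) %*% Wbig %*% Xs
  beta <- solve(A, t(Xs) %*% Wbig %*% ys)
  ll <- 0
  for (k in seq_len(N)) {
    r <- Y[, k] - designBlock(form, J, L, jIdx[k]) %*% beta
    ll <- ll - 0.5 * (L * log(2 * pi) + log(det(Sigma)) +
                        drop(t(r) %*% solve(Sigma) %*% r))
  }
  list(logLik = ll, beta = drop(beta), vcov = solve(A))
}

# Step-up BH rejection set from the definition: reject all p <= p_(k*),
# k* = max{k : p_(k) <= k alpha / M}.
oracleBH <- function(p, alpha) {
  M <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(M) * alpha / M)
  rejected <- rep(FALSE, M)
  if (length(ok)) rejected[p <= p[o][max(ok)]] <- TRUE
  rejected
}

oracleBonferroni <- function(p, level) p <= level / length(p)

# Holm step-down: walk the sorted p-values, stop at the first failure.
oracleHolm <- function(p, level) {
  n <- length(p)
  o <- order(p)
  rejected <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (p[o[i]] <= level / (n - i + 1)) rejected[o[i]] <- TRUE else break
  }
  rejected
}

# Hochberg step-up: find the largest i with p_(i) <= level/(n-i+1) and
# reject everything at or below it.
oracleHochberg <- function(p, level) {
  n <- length(p)
  o <- order(p)
  ok <- which(p[o] <= level / (n - seq_len(n) + 1))
  rejected <- rep(FALSE, n)
  if (length(ok)) rejected[o[seq_len(max(ok))]] <- TRUE
  rejected
}

# Textbook Welch statistic.
oracleWelch <- function(x, y) {
  m <- mean(y) - mean(x)
  se2 <- var(x) / length(x) + var(y) / length(y)
  t <- m / sqrt(se2)
  df <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                   (var(y) / length(y))^2 / (length(y) - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

# Random small GeneData with a known generating covariance.
randomGene <- function(L = 3, K = c(3, 3), id = "g") {
  J <- length(K)
  A <- matrix(rnorm(L * L), L)
  Sigma <- crossprod(A) + diag(L)
  mu <- matrix(rnorm(L * J, sd = 2), L, J)
  cond <- factor(rep(paste0("c", seq_len(J)), times = K))
  Y <- sapply(seq_along(cond), function(k)
    mu[, as.integer(cond[k])] + drop(rnorm(L) %*% chol(Sigma)))
  list(gene = GeneData(id, Y, cond), Sigma = Sigma, mu = mu)
}
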