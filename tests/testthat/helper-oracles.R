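# Independent oracles, deliberately implemented apart from the package's
# own code paths.

# Adaptive Gauss-Hermite quadrature for the marginal log-likelihood of an
# NB2 model with one scalar random intercept: per group, the integrand is
# recentered at its mode and rescaled by the local curvature before a
# fixed-node Gauss-Hermite rule is applied.
agq_nb_loglik <- function(y, group, beta, theta, sd, nodes = 50) {
  gh <- pracma::gaussHermite(nodes)
  total <- 0
  for (g in unique(group)) {
    yg <- y[group == g]
    logint <- function(u) {
      vapply(u, function(ui) {
        sum(dnbinom(yg, size = theta, mu = exp(beta + ui), log = TRUE)) +
          dnorm(ui, 0, sd, log = TRUE)
      }, numeric(1))
    }
    mu_hat <- optimize(function(u) -logint(u), c(-25, 25))$minimum
    h <- 1e-4
    curv <- -(logint(mu_hat + h) + logint(mu_hat - h) - 2 * logint(mu_hat)) / h^2
    s <- 1 / sqrt(curv)
    u <- mu_hat + sqrt(2) * s * gh$x
    lw <- log(gh$w) + logint(u) + gh$x^2 + log(sqrt(2) * s)
    m <- max(lw)
    total <- total + m + log(sum(exp(lw - m)))
  }
  total
}

# Closed-form ordinary least squares.
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))

# Exhaustive PERMANOVA p for one factor on small n: enumerate every
# permutation of the labels and compare pseudo-F directly from first
# principles (within/between decomposition of the Gower-centered matrix).
exhaustive_permanova_p <- function(D, g) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  fstat <- function(gg) {
    M <- stats::model.matrix(~ factor(gg))
    H <- M %*% solve(crossprod(M)) %*% t(M)
    df1 <- qr(M)$rank - 1
    ss_m <- sum((H - matrix(1 / n, n, n)) * G)
    ss_r <- sum((diag(n) - H) * G)
    (ss_m / df1) / (ss_r / (n - df1 - 1))
  }
  f_obs <- fstat(g)
  perms <- gtools_permutations(n)
  f_all <- apply(perms, 1, function(idx) fstat(g[idx]))
  mean(f_all >= f_obs - 1e-12)
}

# All permutations of 1..n (n small), base R only.
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
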