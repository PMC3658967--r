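# Independent oracles used across the suite; deliberately naive
# implementations, kept separate from the package's code paths.

# O(n^2) concordance by explicit pair enumeration, ties credited 0.5.
c_index_brute <- function(p, y) {
  ev <- p[y == 1]
  ne <- p[y == 0]
  conc <- 0
  for (a in ev) conc <- conc + sum(a > ne) + 0.5 * sum(a == ne)
  conc / (length(ev) * length(ne))
}

# Bernoulli log-likelihood of an intercept-only logistic model.
loglik_intercept_only <- function(alpha, y, offset = 0) {
  eta <- alpha + offset
  sum(y * eta - log1p(exp(eta)))
}

# Small clustered logistic dataset with known parameters.
make_clustered_fixture <- function(n_clusters, n_per, sigma2, alpha = -1,
                                   beta = c(1, 1), seed = 1) {
  set.seed(seed)
  u <- rnorm(n_clusters, 0, sqrt(sigma2))
  cl <- rep(seq_len(n_clusters), each = n_per)
  X <- cbind(x1 = rnorm(n_clusters * n_per),
             x2 = rbinom(n_clusters * n_per, 1, 0.4))
  lp <- alpha + as.vector(X %*% beta) + u[cl]
  list(X = X, y = as.integer(runif(length(lp)) <= plogis(lp)),
       cluster = cl, u = u, lp = lp)
}
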