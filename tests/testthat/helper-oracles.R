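# Independent brute-force oracles, deliberately naive and loop-based so they
# share no code path with the package implementation.

# pairwise Mann-Whitney kernel: 1 / 0.5 / 0 for > / = / <
oracle_auc <- function(d, nd) {
  total <- 0
  for (x in d) {
    for (y in nd) {
      total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
    }
  }
  total / (length(d) * length(nd))
}

# literal transcription of the tie-corrected Mann-Whitney variance:
# Q1 sums over nondiseased values, Q2 symmetrically over diseased values
oracle_auc_variance <- function(d, nd) {
  n1 <- length(d)
  n0 <- length(nd)
  auc <- oracle_auc(d, nd)
  q1 <- 0
  for (y in unique(nd)) {
    n0eq <- sum(nd == y)
    n1gt <- sum(d > y)
    n1eq <- sum(d == y)
    q1 <- q1 + n0eq * (n1gt^2 + n1gt * n1eq + n1eq^2 / 3)
  }
  q1 <- q1 / (n0 * n1^2)
  q2 <- 0
  for (y in unique(d)) {
    n1eq <- sum(d == y)
    n0lt <- sum(nd < y)
    n0eq <- sum(nd == y)
    q2 <- q2 + n1eq * (n0lt^2 + n0lt * n0eq + n0eq^2 / 3)
  }
  q2 <- q2 / (n0^2 * n1)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0)
  list(q1 = q1, q2 = q2, var = v)
}

# tie-free Hanley-McNeil component by triple loop:
# P(two random diseased both exceed one nondiseased)
oracle_q1_tripleloop <- function(d, nd) {
  n1 <- length(d)
  n0 <- length(nd)
  total <- 0
  for (i in seq_len(n1)) {
    for (k in seq_len(n1)) {
      for (j in seq_len(n0)) {
        total <- total + (d[i] > nd[j]) * (d[k] > nd[j])
      }
    }
  }
  total / (n1^2 * n0)
}

# Newton-Raphson probit maximum likelihood on weighted Bernoulli data,
# analytic score and expected-information updates
oracle_probit_ml <- function(X, y, w = rep(1, length(y)),
                             tol = 1e-12, maxit = 50) {
  beta <- c(0, 0)
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    p <- pnorm(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    phi <- dnorm(eta)
    score <- t(X) %*% (w * phi * (y - p) / (p * (1 - p)))
    info <- t(X) %*% (X * (w * phi^2 / (p * (1 - p))))
    step <- solve(info, score)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# simple trapezoid over sorted (x, y) points
oracle_trapezoid <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# random small sample with frequent ties (small integer support)
random_tied_sample <- function(n_max = 8, k = 5) {
  n1 <- sample(2:n_max, 1)
  n0 <- sample(2:n_max, 1)
  sample_data(sample.int(k, n1, replace = TRUE),
              sample.int(k, n0, replace = TRUE))
}
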