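# shared fixtures and independent oracles -----------------------------------

# one-stage alive-dead model: survival s, Poisson fertility lambda
one_stage <- function(s = 0.5, lambda = 1, ...) {
  mpm(matrix(s), matrix(lambda), model_id = "one_stage", ...)
}

# 2-stage semelparous fixture: mature with probability p at age 1, one burst
# of reproduction, then death
semelparous <- function(p = 0.8, f = 3) {
  generate_leslie(survival = c(p, 0), fertility = c(0, f),
                  model_id = "semelparous")
}

# random sub-stochastic transition matrix with column sums in (0, max_surv)
random_U <- function(tau, max_surv = 0.95) {
  m <- matrix(runif(tau * tau), tau)
  target <- runif(tau, 0.05, max_surv)
  sweep(m, 2, colSums(m) / target, "/")
}

random_model <- function(tau, max_surv = 0.95, max_fert = 3, id = "rand") {
  F_mat <- matrix(0, tau, tau)
  F_mat[1, ] <- runif(tau, 0, max_fert)
  mpm(random_U(tau, max_surv), F_mat, model_id = id)
}

# oracle: raw moments of the geometric distribution on {1, 2, ...} with
# success probability q, by direct pmf summation
geometric_raw_moments_oracle <- function(q, k_max = 4, t_max = 10000) {
  t <- seq_len(t_max)
  pmf <- (1 - q)^(t - 1) * q
  vapply(seq_len(k_max), function(k) sum(t^k * pmf), numeric(1))
}

# oracle: raw moments of Poisson(lambda) by direct pmf summation
poisson_raw_moments_oracle <- function(lambda, k, x_max = 400) {
  x <- 0:x_max
  sum(x^k * stats::dpois(x, lambda))
}

# oracle: fundamental matrix by truncated power series
power_series_N_oracle <- function(U, t_max = 200) {
  acc <- diag(ncol(U))
  term <- diag(ncol(U))
  for (t in seq_len(t_max)) {
    term <- term %*% U
    acc <- acc + term
  }
  acc
}
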