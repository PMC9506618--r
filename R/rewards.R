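#' Raw moments of the Poisson distribution
#'
#' Closed forms (Touchard polynomials) for the first four raw moments of
#' Poisson(lambda), used to build reproductive reward matrices.
#'
#' @param lambda Nonnegative mean.
#' @param k Moment order, 1 to 4.
#' @return The k-th raw moment, vectorized over `lambda`.
#' @export
poisson_raw_moments <- function(lambda, k) {
  if (any(lambda < 0)) {
    abort("lambda must be nonnegative", class = "stochlife_validation_error")
  }
  stopifnot(length(k) == 1, k %in% 1:4)
  switch(k,
    lambda,
    lambda + lambda^2,
    lambda + 3 * lambda^2 + lambda^3,
    lambda + 7 * lambda^2 + 6 * lambda^3 + lambda^4
  )
}

#' Poisson reproductive reward structure
#'
#' Reproduction is treated as a random reward collected on every transition
#' out of a living stage, up to and including the dying transition. The mean
#' reward for an individual in stage j is `lambda_j = sum(F[, j])` (offspring
#' types summed), and the per-transition reward is Poisson(lambda_j). `R1`
#' to `R4` hold the raw reward moments for each (destination, origin) pair of
#' the full chain; columns for absorbing origins are zero (the dead collect
#' nothing).
#'
#' @param model An [mpm] object (only `F` is used).
#' @param chain The [absorbing_chain][build_chain] built from the model's `U`.
#' @return An object of class `reward_structure` with fields `lambdas` and
#'   `R1`..`R4`.
#' @export
build_reward_structure <- function(model, chain) {
  stopifnot(inherits(model, "mpm"), inherits(chain, "absorbing_chain"))
  tau <- chain$tau
  if (ncol(model$F) != tau) {
    abort("model and chain dimensions disagree",
          class = "stochlife_validation_error")
  }
  lam <- colSums(model$F)
  s <- tau + chain$alpha
  Rk <- lapply(1:4, function(k) {
    lam_s <- c(poisson_raw_moments(lam, k), rep(0, chain$alpha))
    matrix(lam_s, nrow = s, ncol = s, byrow = TRUE)
  })
  structure(list(lambdas = lam, R1 = Rk[[1]], R2 = Rk[[2]],
                 R3 = Rk[[3]], R4 = Rk[[4]]),
            class = "reward_structure")
}

# Poisson raw moment of any order k <= 8 (Touchard polynomial via Stirling
# numbers); the public poisson_raw_moments() keeps the documented 1..4 forms
.poisson_raw_moment_k <- function(lambda, k) {
  stopifnot(k >= 1, k <= 8)
  pow <- outer(lambda, seq_len(k), "^")
  drop(pow %*% .stirling2[k, seq_len(k)])
}

# raw moments 1..k_max of lifetime reproductive output by the MCWR binomial
# recursion, over all transient starting stages (k_max x tau matrix)
.lro_raw_moments <- function(U, lam, k_max = 8) {
  tau <- ncol(U)
  ch <- build_chain(U)
  P <- ch$P
  s <- tau + ch$alpha
  Ntrans <- t(fundamental_matrix(U))
  # per-order reward moment vectors over all states (zero for absorbing)
  rl <- lapply(seq_len(k_max), function(l) c(.poisson_raw_moment_k(lam, l),
                                             rep(0, ch$alpha)))
  rho <- vector("list", k_max + 1)
  rho[[1]] <- rep(1, s)
  out <- matrix(0, k_max, tau)
  for (k in seq_len(k_max)) {
    term <- numeric(s)
    for (l in seq_len(k)) {
      # (P o R_l)' x = r_l * (P' x): rewards depend on the origin stage only
      term <- term + choose(k, l) * rl[[l]] * drop(crossprod(P, rho[[k - l + 1]]))
    }
    rho_k <- drop(Ntrans %*% term[seq_len(tau)])
    rho[[k + 1]] <- c(rho_k, rep(0, ch$alpha))
    out[k, ] <- rho_k
  }
  out
}

#' Moments of lifetime reproductive output
#'
#' Implements the Markov chain with rewards (MCWR) accumulation recursion for
#' the first four raw moments of the total reward collected before
#' absorption. Writing `rho_k` for the vector of k-th raw moments of
#' remaining lifetime reward by current state (zero on absorbing states), a
#' one-step binomial expansion of `(reward + future)^k` gives
#' \deqn{\rho_k = N' Z \sum_{l=1}^{k} \binom{k}{l} (P \circ R_l)' \tilde\rho_{k-l},}
#' where `Z` selects transient states, `P ∘ R_l` is the elementwise product
#' of the chain with the l-th reward-moment matrix, and `rho_0` is a vector
#' of ones.
#'
#' @param chain An [absorbing_chain][build_chain].
#' @param rewards A [reward_structure][build_reward_structure].
#' @param start_stage Starting stage for the reported statistics.
#' @return A list of class `lro_moments`: `rho1`..`rho4` (raw-moment vectors
#'   over transient starting stages) and `stats`, a
#'   [`dist_stats`][stats_from_raw_moments] with the standardized variance
#'   `ofs` included.
#' @export
lro_moments <- function(chain, rewards, start_stage = 1L) {
  stopifnot(inherits(chain, "absorbing_chain"),
            inherits(rewards, "reward_structure"))
  tau <- chain$tau
  s <- tau + chain$alpha
  stopifnot(start_stage >= 1, start_stage <= tau)
  P <- chain$P
  U <- P[seq_len(tau), seq_len(tau), drop = FALSE]
  Ntrans <- t(fundamental_matrix(U))       # N' once; repeated solves would also do
  Rl <- list(rewards$R1, rewards$R2, rewards$R3, rewards$R4)
  PRt <- lapply(Rl, function(R) t(P * R))
  rho_tilde <- vector("list", 5)
  rho_tilde[[1]] <- rep(1, s)              # rho_0
  for (k in 1:4) {
    term <- numeric(s)
    for (l in 1:k) {
      term <- term + choose(k, l) * drop(PRt[[l]] %*% rho_tilde[[k - l + 1]])
    }
    rho_k <- drop(Ntrans %*% term[seq_len(tau)])
    rho_tilde[[k + 1]] <- c(rho_k, rep(0, chain$alpha))
  }
  rho <- lapply(2:5, function(i) rho_tilde[[i]][seq_len(tau)])
  stats <- stats_from_raw_moments(vapply(rho, `[`, numeric(1), start_stage),
                                  ofs = TRUE)
  structure(list(rho1 = rho[[1]], rho2 = rho[[2]], rho3 = rho[[3]],
                 rho4 = rho[[4]], stats = stats),
            class = "lro_moments")
}

#' Statistics of lifetime reproductive output for a model
#'
#' Convenience wrapper: builds the absorbing chain and Poisson reward
#' structure and returns the distributional statistics of LRO, including the
#' standardized variance (opportunity for selection).
#'
#' @param model An [mpm] object.
#' @param start_stage Starting stage (default: first stage in the life cycle).
#' @return A [`dist_stats`][stats_from_raw_moments] object with `ofs`.
#' @export
#' @examples
#' m <- mpm(matrix(0.5), matrix(1))
#' lro_stats(m)  # mean 2, variance 4, OFS 1
lro_stats <- function(model, start_stage = 1L) {
  chain <- build_chain(model$U)
  rew <- build_reward_structure(model, chain)
  lro_moments(chain, rew, start_stage)$stats
}
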