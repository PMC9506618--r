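#' Embed a transition matrix in an absorbing Markov chain
#'
#' The life cycle's tau transient (living) stages are augmented with a single
#' absorbing "dead" state, giving the (tau+1) x (tau+1) column-stochastic
#' chain
#' \deqn{P = \begin{pmatrix} U & 0 \\ M & I \end{pmatrix}}
#' where the row vector `M` holds the per-stage death probabilities
#' `1 - colSums(U)`.
#'
#' @param U Transition matrix (column sums at most 1).
#' @return An object of class `absorbing_chain`: a list with `P`, `tau`,
#'   `alpha` (number of absorbing states, always 1 here) and `M`.
#' @export
#' @examples
#' build_chain(matrix(0.5))$P
build_chain <- function(U) {
  U <- as.matrix(U)
  tau <- ncol(U)
  cs <- colSums(U)
  if (any(cs > 1 + .col_sum_tol)) {
    abort(sprintf("column %d of U sums to %.6g > 1", which.max(cs), max(cs)),
          class = "stochlife_validation_error")
  }
  M <- matrix(pmax(1 - cs, 0), nrow = 1)
  P <- rbind(cbind(U, matrix(0, tau, 1)),
             cbind(M, matrix(1, 1, 1)))
  dimnames(P) <- NULL
  structure(list(P = P, tau = tau, alpha = 1L, M = M),
            class = "absorbing_chain")
}

#' @export
print.absorbing_chain <- function(x, ...) {
  cat(sprintf("<absorbing_chain> %d transient + %d absorbing states\n",
              x$tau, x$alpha))
  invisible(x)
}

#' Fundamental matrix of an absorbing chain
#'
#' `N = (I - U)^{-1}`; its (i, j) entry is the expected number of time steps
#' spent in stage i before death, for an individual now in stage j (the
#' current occupancy counts, so diagonal entries are at least 1).
#'
#' @param U Transition matrix with spectral radius below 1.
#' @param max_condition Hard failure threshold on the 2-norm condition number
#'   of `I - U`; near-singular systems give meaningless moments. This guard is
#'   distinct from (and far looser than) the screening filter
#'   [condition_filter()].
#' @return The tau x tau matrix `N`.
#' @export
fundamental_matrix <- function(U, max_condition = 1e12) {
  U <- as.matrix(U)
  A <- diag(ncol(U)) - U
  kap <- tryCatch(suppressWarnings(kappa(A, exact = TRUE)),
                  error = function(e) Inf)
  if (!is.finite(kap) || kap > max_condition) {
    abort(sprintf("I - U is singular or ill-conditioned (condition number %.3g)", kap),
          class = "stochlife_conditioning_error")
  }
  N <- tryCatch(solve(A), error = function(e) {
    abort(sprintf("I - U is singular (condition number %.3g): %s",
                  kap, conditionMessage(e)),
          class = "stochlife_conditioning_error")
  })
  dimnames(N) <- dimnames(U)
  N
}

#' Statistics of a distribution from its first four raw moments
#'
#' Converts raw moments m1..m4 of a nonnegative outcome to central moments and
#' the derived statistics used throughout: mean, variance, SD, coefficient of
#' variation, skewness (mu3 / sigma^3) and *excess* kurtosis
#' (mu4 / sigma^4 - 3, so the normal distribution scores 0). For lifetime
#' reproductive output the standardized variance variance/mean^2 -- the
#' opportunity for selection (OFS) -- is added when `ofs = TRUE`.
#'
#' Statistics that are undefined for a degenerate distribution (CV and OFS
#' when the mean is 0; skewness and kurtosis when the SD is 0) are returned as
#' `NA`. A variance between -1e-9 and 0 (floating-point cancellation) is
#' clipped to 0 with a warning; anything more negative is an error, since it
#' indicates inconsistent moments.
#'
#' @param m Numeric vector of length 4: raw moments `E[X], E[X^2], E[X^3], E[X^4]`.
#' @param ofs Also compute the standardized variance?
#' @return An object of class `dist_stats`.
#' @export
#' @examples
#' # geometric distribution on {1, 2, ...} with success probability 1/2
#' stats_from_raw_moments(c(2, 6, 26, 150))
stats_from_raw_moments <- function(m, ofs = FALSE) {
  stopifnot(is.numeric(m), length(m) == 4)
  m <- unname(m)
  if (!all(is.finite(m))) {
    abort("raw moments must be finite", class = "stochlife_validation_error")
  }
  m1 <- m[1]; m2 <- m[2]; m3 <- m[3]; m4 <- m[4]
  mu2 <- m2 - m1^2
  mu3 <- m3 - 3 * m1 * m2 + 2 * m1^3
  mu4 <- m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4
  if (mu2 < -1e-9 * max(1, m2)) {
    abort(sprintf("inconsistent moments: variance = %.6g < 0", mu2),
          class = "stochlife_validation_error")
  }
  if (mu2 < 0) {
    # pure cancellation noise is clipped silently; anything visibly negative
    # (but above the hard-error line) still deserves a warning
    if (mu2 < -1e-12 * max(1, m2)) {
      warn(sprintf("clipping tiny negative variance %.3g to 0", mu2))
    }
    mu2 <- 0
  }
  s <- sqrt(mu2)
  out <- list(
    raw_moments = c(m1 = m1, m2 = m2, m3 = m3, m4 = m4),
    mean = m1,
    variance = mu2,
    sd = s,
    cv = if (m1 != 0) s / m1 else NA_real_,
    skewness = if (s > 0) mu3 / s^3 else NA_real_,
    excess_kurtosis = if (s > 0) mu4 / mu2^2 - 3 else NA_real_
  )
  if (ofs) out$ofs <- if (m1 != 0) mu2 / m1^2 else NA_real_
  structure(out, class = "dist_stats")
}

#' @export
print.dist_stats <- function(x, digits = 4, ...) {
  cat("<dist_stats>\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dist_stats <- function(x, ...) {
  tibble(
    mean = x$mean, variance = x$variance, sd = x$sd, cv = x$cv,
    skewness = x$skewness, excess_kurtosis = x$excess_kurtosis,
    ofs = if (!is.null(x$ofs)) x$ofs else NA_real_
  )
}

# Stirling numbers of the second kind S(r, k), r, k = 1..8; row r converts
# binomial/factorial moments of order <= r into the r-th raw moment
.stirling2 <- local({
  s <- matrix(0, 8, 8)
  s[1, 1] <- 1
  for (r in 2:8) for (k in 1:r) {
    s[r, k] <- (if (k > 1) s[r - 1, k - 1] else 0) + k * s[r - 1, k]
  }
  s
})

# raw moments 1..k_max of time to absorption from start_stage, via the
# binomial-moment identity E[choose(T, k)] = 1' U^(k-1) N^k e
.longevity_raw_moments <- function(U, start_stage, k_max = 8) {
  U <- as.matrix(U)
  N <- fundamental_matrix(U)
  e <- numeric(ncol(U)); e[start_stage] <- 1
  y <- e                      # N^k e
  z <- rep(1, ncol(U))        # (U')^(k-1) 1
  binom <- numeric(k_max)
  for (k in seq_len(k_max)) {
    y <- N %*% y
    if (k > 1) z <- crossprod(U, z)
    binom[k] <- sum(z * y)
  }
  vapply(seq_len(k_max), function(r) {
    sum(.stirling2[r, 1:r] * factorial(1:r) * binom[1:r])
  }, numeric(1))
}

# eta-vectors of the first four raw moments of time to absorption, over all
# starting stages. Derived from the standard absorbing-chain recursions; the
# death step counts, so a one-stage chain with death probability q gives the
# geometric distribution on {1, 2, ...}.
.longevity_eta <- function(N) {
  tau <- ncol(N)
  I <- diag(tau)
  e1 <- colSums(N)                      # eta1' = 1'N
  e2 <- drop(e1 %*% (2 * N - I))
  N2 <- N %*% N
  e3 <- drop(e1 %*% (6 * N2 - 6 * N + I))
  e4 <- drop(e1 %*% (24 * N2 %*% N - 36 * N2 + 14 * N - I))
  rbind(e1, e2, e3, e4)
}

#' Moments and statistics of longevity
#'
#' Longevity is the number of time steps until absorption (death), counting
#' the step of the transition into the dead state: a one-stage model with
#' per-step death probability q yields the geometric distribution on
#' \{1, 2, ...\}. The first four raw moments follow from the fundamental
#' matrix via the standard absorbing-chain recursions
#' `eta1' = 1'N`, `eta2' = eta1'(2N - I)`, `eta3' = eta1'(6N^2 - 6N + I)`,
#' `eta4' = eta1'(24N^3 - 36N^2 + 14N - I)`.
#'
#' @param U Transition matrix.
#' @param start_stage Starting stage (1-based; the analyses here start every
#'   individual in the first stage of the life cycle).
#' @return A [`dist_stats`][stats_from_raw_moments] object; the attribute
#'   `"eta"` carries the 4 x tau matrix of raw-moment vectors over all
#'   starting stages.
#' @export
#' @examples
#' longevity_moments(matrix(0.5))  # geometric, mean 2, variance 2
longevity_moments <- function(U, start_stage = 1L) {
  U <- as.matrix(U)
  stopifnot(start_stage >= 1, start_stage <= ncol(U))
  N <- fundamental_matrix(U)
  eta <- .longevity_eta(N)
  out <- stats_from_raw_moments(eta[, start_stage])
  attr(out, "eta") <- eta
  out
}
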