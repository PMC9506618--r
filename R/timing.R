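#' Generation time and the parity measure
#'
#' The cohort generation time is the mean age at which an individual's
#' offspring are produced; spreading reproduction over many ages (iteroparity)
#' is measured by the coefficient of variation of those fertility-weighted
#' ages (the parity measure): strict semelparity at a fixed age has CV 0.
#'
#' A newborn has age 0 and the offspring it produces during the interval
#' entered at age t are recorded at age t, so the expected offspring schedule
#' is `phi(t) = 1'F U^t e_start`. Closed forms of the weighted sums give
#' total offspring `1'F N e`, first raw age moment `1'F U N^2 e / total` and
#' second raw age moment `1'F U (I + U) N^3 e / total`. The alternative
#' convention that ages offspring at the *end* of the interval
#' (`age_origin = "one"`) shifts the mean by exactly 1 and leaves the SD
#' unchanged.
#'
#' @param U,F_mat Transition and fertility matrices of the model.
#' @param start_stage Starting stage of the focal individual.
#' @param age_origin `"zero"` (default) or `"one"`; see Details.
#' @return A one-row tibble with `gt_mean`, `gt_sd`, `parity_cv` and the
#'   expected total offspring `total`.
#' @export
#' @examples
#' # one-stage model, survival 0.5: gt_mean = 1, gt_sd = sqrt(2)
#' offspring_age_moments(matrix(0.5), matrix(1))
offspring_age_moments <- function(U, F_mat, start_stage = 1L,
                                  age_origin = c("zero", "one")) {
  age_origin <- match.arg(age_origin)
  U <- as.matrix(U); F_mat <- as.matrix(F_mat)
  tau <- ncol(U)
  stopifnot(start_stage >= 1, start_stage <= tau)
  f <- colSums(F_mat)
  N <- fundamental_matrix(U)
  e <- numeric(tau); e[start_stage] <- 1
  total <- drop(f %*% N %*% e)
  if (total <= 0) {
    abort("no reproduction reachable from the starting stage",
          class = "stochlife_validation_error")
  }
  N2e <- N %*% (N %*% e)
  N3e <- N %*% N2e
  m1 <- drop(f %*% U %*% N2e) / total
  m2 <- drop(f %*% U %*% (N3e + U %*% N3e)) / total
  v <- m2 - m1^2
  if (v < 0) v <- max(v, 0)    # cancellation guard; exact-semelparity case
  gt_sd <- sqrt(v)
  if (age_origin == "one") m1 <- m1 + 1
  parity <- if (gt_sd == 0) 0 else gt_sd / m1
  tibble(gt_mean = m1, gt_sd = gt_sd, parity_cv = parity, total = total)
}

# Exact first and second moments of the per-individual triple
#   S1 = sum_t t k_t,  S2 = sum_t t^2 k_t,  L = sum_t k_t
# where k_t ~ Poisson(lambda_{J_t}) is the offspring count collected at age t
# while alive (the reward convention shared across the package). Used for
# delta-method standard errors of the simulated generation time and parity.
# Derivation: conditional on the path, the k_t are independent Poissons, so
# E[k_t k_s] = lambda_t lambda_s + 1{t=s} lambda_t; path expectations of
# lambda products reduce to f U^d Lambda U^t terms whose double sums factor
# into power-weighted resolvent series sum_t t^k U^t.
.offspring_age_cov <- function(U, F_mat, start_stage = 1L) {
  U <- as.matrix(U)
  tau <- ncol(U)
  lam <- colSums(as.matrix(F_mat))
  f <- matrix(lam, nrow = 1)
  L <- diag(lam, tau)
  e <- numeric(tau); e[start_stage] <- 1
  N <- fundamental_matrix(U)
  I <- diag(tau)
  N2 <- N %*% N; N3 <- N2 %*% N; N4 <- N3 %*% N; N5 <- N4 %*% N
  B0 <- N
  B1 <- U %*% N2                                   # sum t U^t
  B2 <- U %*% (I + U) %*% N3                       # sum t^2 U^t
  B3 <- U %*% (I + 4 * U + U %*% U) %*% N4         # sum t^3 U^t
  U2 <- U %*% U
  B4 <- U %*% (I + 11 * U + 11 * U2 + U %*% U2) %*% N5
  A0 <- N - I                                      # sum_{d>=1} U^d
  g2 <- lam + lam^2                                # E[k^2 | state]

  q <- function(M) drop(f %*% M %*% e)             # f M e
  qg <- function(M) drop(g2 %*% M %*% e)           # g2' M e
  # D(alpha, beta) = sum_{t, d>=1} t^alpha (t+d)^beta f U^d Lambda U^t e
  pair <- function(Ad, Bt) drop(f %*% Ad %*% L %*% Bt %*% e)
  A <- list(`0` = A0, `1` = B1, `2` = B2)
  B <- list(`0` = B0, `1` = B1, `2` = B2, `3` = B3, `4` = B4)
  D <- function(alpha, beta) {
    sum(vapply(0:beta, function(j) {
      choose(beta, j) * pair(A[[as.character(beta - j)]],
                             B[[as.character(alpha + j)]])
    }, numeric(1)))
  }

  mu <- c(S1 = q(B1), S2 = q(B2), L = q(B0))
  ES1S1 <- qg(B2) + 2 * D(1, 1)
  ES2S2 <- qg(B4) + 2 * D(2, 2)
  ELL <- qg(B0) + 2 * D(0, 0)
  ES1S2 <- qg(B3) + D(1, 2) + D(2, 1)
  ES1L <- qg(B1) + D(1, 0) + D(0, 1)
  ES2L <- qg(B2) + D(2, 0) + D(0, 2)
  second <- matrix(c(ES1S1, ES1S2, ES1L,
                     ES1S2, ES2S2, ES2L,
                     ES1L, ES2L, ELL), 3, 3,
                   dimnames = list(names(mu), names(mu)))
  list(mu = mu, Sigma = second - tcrossprod(mu))
}

#' Reproductive stages of a model
#'
#' A stage is reproductive when its fertility column has strictly positive
#' total output.
#'
#' @param F_mat Fertility matrix.
#' @return Integer vector of stage indices.
#' @export
reproductive_stage_set <- function(F_mat) {
  idx <- which(colSums(as.matrix(F_mat)) > 0)
  if (!length(idx)) {
    abort("model has no reproductive stage",
          class = "stochlife_validation_error")
  }
  idx
}

#' Age at maturity by conditional absorption
#'
#' Age at maturity is the time of first entry into a reproductive stage,
#' conditional on ever reaching one (individuals that die first are excluded,
#' not averaged in). The reproductive stages are made absorbing; from the
#' remaining (pre-reproductive) states, `b` is the probability of absorption
#' into the reproductive set rather than death. Conditioning on that event
#' gives the Doob-transformed chain `u_c[i, j] = u[i, j] b_i / b_j`, whose
#' time to absorption -- counting the entering step, consistent with the
#' longevity convention -- is the age at maturity.
#'
#' @param U,F_mat Transition and fertility matrices.
#' @param start_stage Starting stage.
#' @return A one-row tibble: `am_mean`, `am_sd`, `am_cv` and `p_reach` (the
#'   probability of ever maturing). A start in a reproductive stage returns
#'   zero mean and SD, `am_cv = NA` and `p_reach = 1`.
#' @export
#' @examples
#' # two stages, maturation with probability 0.8, reproduction from stage 2
#' U <- matrix(c(0, 0.8, 0, 0), 2)
#' F_mat <- matrix(c(0, 0, 3, 0), 2)
#' age_at_maturity(U, F_mat)   # am_mean 1, am_sd 0, p_reach 0.8
age_at_maturity <- function(U, F_mat, start_stage = 1L) {
  cond <- .conditional_maturity_chain(U, F_mat, start_stage)
  if (is.null(cond)) {
    return(tibble(am_mean = 0, am_sd = 0, am_cv = NA_real_, p_reach = 1))
  }
  stats <- longevity_moments(cond$Uc, cond$start_pos)
  tibble(am_mean = stats$mean, am_sd = stats$sd,
         am_cv = stats$cv, p_reach = cond$p_reach)
}

# the Doob-conditioned pre-reproductive chain underlying age_at_maturity;
# NULL when the start stage is itself reproductive
.conditional_maturity_chain <- function(U, F_mat, start_stage = 1L) {
  U <- as.matrix(U); F_mat <- as.matrix(F_mat)
  tau <- ncol(U)
  stopifnot(start_stage >= 1, start_stage <= tau)
  repro <- reproductive_stage_set(F_mat)
  if (start_stage %in% repro) return(NULL)
  pre <- setdiff(seq_len(tau), repro)
  Upre <- U[pre, pre, drop = FALSE]
  a <- colSums(U[repro, pre, drop = FALSE])   # one-step entry probabilities
  Npre <- fundamental_matrix(Upre)
  b <- unname(drop(crossprod(Npre, a)))       # b_j = P(reach maturity | in j)
  start_pos <- match(start_stage, pre)
  if (b[start_pos] <= 0) {
    abort("maturity unreachable from the starting stage",
          class = "stochlife_validation_error")
  }
  keep <- b > 0
  Uc <- Upre[keep, keep, drop = FALSE]
  bk <- b[keep]
  Uc <- Uc * (bk %o% (1 / bk))                # u_c[i,j] = u[i,j] b_i / b_j
  list(Uc = Uc, start_pos = match(start_pos, which(keep)),
       p_reach = b[start_pos])
}
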