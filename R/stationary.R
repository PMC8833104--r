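#' Exact stationary distribution of the TCR-pMHC complex number
#'
#' For the reversible binding reactions `L + R <-> B` with total copy
#' numbers `L_max`, `R_max` and dimensionless dissociation constant
#' `K_d`, the stationary probability of observing `B` complexes is
#'
#' \deqn{p(B) = \frac{a(B)}{Z}, \qquad
#'   a(B) = \binom{B_{max}}{B}\binom{U_{max}}{B} K_d^{-B}\, B!}
#'
#' for `B = 0, ..., B_max`, where `B_max = min(L_max, R_max)`,
#' `U_max = max(L_max, R_max)` and `Z` is the normalizing partition
#' function.  All weights are computed in log space (log-gamma for the
#' binomial coefficients and factorial, log-sum-exp for `Z`), so the
#' result is overflow-free even for `U_max` in the thousands at small
#' `K_d`.
#'
#' `k_on_over_nu = 0` (`K_d = Inf`) yields the degenerate distribution
#' with all mass at `B = 0`.
#'
#' @param params A [binding_params()] object.
#' @return An object of class `stationary_dist`: a list with fields
#'   `B_max`, `U_max`, `K_d`, `p` (probability vector indexed
#'   `0..B_max`), `log_a` (log unnormalized weights), `log_Z`
#'   (log partition function), plus the originating `L_max`, `R_max`.
#'
#' @examples
#' d <- stationary_distribution(binding_params(1, 1, k_off = 1, K_d = 1))
#' d$p  # c(0.5, 0.5)
#' @export
stationary_distribution <- function(params) {
  stopifnot(inherits(params, "binding_params"))
  b <- complex_bounds(params$L_max, params$R_max)
  B <- 0:b$B_max
  K_d <- params$K_d
  if (is.finite(K_d)) {
    log_a <- lchoose(b$B_max, B) + lchoose(b$U_max, B) -
      B * log(K_d) + lgamma(B + 1)
  } else {
    log_a <- c(0, rep(-Inf, b$B_max))
  }
  log_Z <- logsumexp(log_a)
  p <- exp(log_a - log_Z)
  p[p < 1e-300] <- 0
  structure(
    list(B_max = b$B_max, U_max = b$U_max, K_d = K_d,
         p = p, log_a = log_a, log_Z = log_Z,
         L_max = params$L_max, R_max = params$R_max),
    class = "stationary_dist"
  )
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @export
print.stationary_dist <- function(x, ...) {
  mv <- moments(x)
  cat(sprintf(
    "Stationary TCR-pMHC complex distribution (B_max = %d, U_max = %d, K_d = %g)\n",
    x$B_max, x$U_max, x$K_d))
  cat(sprintf("  mean %.4g, variance %.4g, P(adhesion) %.4g\n",
              mv[["mean_B"]], mv[["var_B"]], adhesion_probability(x)))
  invisible(x)
}

#' Mean and variance of the complex-number distribution
#'
#' @param dist A `stationary_dist` object (or any list with a
#'   probability vector `p` over `0..B_max`).
#' @return Named numeric vector `c(mean_B = , var_B = )`.
#' @export
moments <- function(dist) {
  p <- dist$p
  i <- seq_along(p) - 1
  m <- sum(i * p)
  v <- sum(i^2 * p) - m^2
  c(mean_B = m, var_B = max(v, 0))
}

#' Shannon entropy of the complex-number distribution (bits)
#'
#' `H(B) = -sum_i p(i) log2 p(i)` with the convention `0 log 0 = 0`.
#' This is the average information per binding/unbinding event imparted
#' to the T cell; it depends on `(L_max, R_max, K_d)` only and cannot
#' distinguish fast from slow kinetics.
#'
#' @inheritParams moments
#' @return Entropy in bits, in `[0, log2(B_max + 1)]`.
#' @export
shannon_entropy <- function(dist) {
  p <- dist$p
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy rate of the binding dynamics (bits per second)
#'
#' The mean reaction rate of the reversible binding system at
#' stationarity is `2 k_off <B>` events per second (binding and
#' unbinding balance), so the average information imparted to the T
#' cell per second is
#' \deqn{H'(B) = 2 k_{off} \langle B\rangle H(B).}
#' Unlike the Shannon entropy, the entropy rate depends on `k_off`
#' explicitly, not only on the ratio `K_d`: it scales exactly linearly
#' in `k_off` at fixed `(L_max, R_max, K_d)`.
#'
#' @inheritParams moments
#' @param k_off Unbinding rate, s^-1 (positive).
#' @return Entropy rate in bits s^-1.
#' @export
entropy_rate <- function(dist, k_off) {
  stopifnot(is.numeric(k_off), length(k_off) == 1L, k_off > 0)
  2 * k_off * moments(dist)[["mean_B"]] * shannon_entropy(dist)
}

#' Variance rate of the binding dynamics
#'
#' \deqn{Var'(B) = 2 k_{off} \langle B\rangle Var(B).}
#' The variance rate has no information-theoretic interpretation but
#' behaves like the entropy rate and is analytically tractable; half
#' the variance rate approximates the mean signalling rate of the
#' five-reaction activation model.
#'
#' @inheritParams entropy_rate
#' @return Variance rate in copy-number^2 s^-1.
#' @export
variance_rate <- function(dist, k_off) {
  stopifnot(is.numeric(k_off), length(k_off) == 1L, k_off > 0)
  mv <- moments(dist)
  2 * k_off * mv[["mean_B"]] * mv[["var_B"]]
}

#' Probability of adhesion
#'
#' The stationary probability that at least one TCR-pMHC complex is
#' present in the contact area, `P_a = 1 - 1/Z = 1 - p(0)` -- the
#' quantity fitted by adhesion frequency assays.
#'
#' @param x A [binding_params()] or `stationary_dist` object.
#' @return A probability in `[0, 1]`.
#' @examples
#' adhesion_probability(binding_params(1, 1, k_off = 1, K_d = 1))  # 0.5
#' @export
adhesion_probability <- function(x) {
  if (inherits(x, "binding_params")) x <- stationary_distribution(x)
  stopifnot(inherits(x, "stationary_dist"))
  # a(0) = 1, so p(0) = 1/Z and P_a = 1 - exp(-log Z)
  -expm1(-x$log_Z)
}

#' All summary measures for one parameter set
#'
#' Computes the stationary mean and variance of the complex number, the
#' Shannon entropy, the entropy and variance rates, and the adhesion
#' probability in one call.
#'
#' @param params A [binding_params()] object.
#' @return An object of class `summary_measures`: a list with fields
#'   `mean_B`, `var_B`, `shannon_entropy` (bits), `entropy_rate`
#'   (bits/s), `variance_rate` (s^-1), `adhesion_probability`, plus the
#'   input `params`.
#' @examples
#' summary_measures(binding_params(1000, 10, k_off = 1, K_d = 100))
#' @export
summary_measures <- function(params) {
  stopifnot(inherits(params, "binding_params"))
  d <- stationary_distribution(params)
  mv <- moments(d)
  H <- shannon_entropy(d)
  structure(
    list(mean_B = mv[["mean_B"]],
         var_B = mv[["var_B"]],
         shannon_entropy = H,
         entropy_rate = 2 * params$k_off * mv[["mean_B"]] * H,
         variance_rate = 2 * params$k_off * mv[["mean_B"]] * mv[["var_B"]],
         adhesion_probability = adhesion_probability(d),
         params = params),
    class = "summary_measures"
  )
}

#' @export
print.summary_measures <- function(x, ...) {
  cat("TCR-pMHC stationary summary measures\n")
  cat(sprintf("  mean complex number <B>   : %.6g\n", x$mean_B))
  cat(sprintf("  variance Var(B)           : %.6g\n", x$var_B))
  cat(sprintf("  Shannon entropy H(B)      : %.6g bits\n", x$shannon_entropy))
  cat(sprintf("  entropy rate H'(B)        : %.6g bits/s\n", x$entropy_rate))
  cat(sprintf("  variance rate Var'(B)     : %.6g /s\n", x$variance_rate))
  cat(sprintf("  adhesion probability P_a  : %.6g\n", x$adhesion_probability))
  invisible(x)
}

# single-row data.frame with the canonical export keys
#' @export
as.data.frame.summary_measures <- function(x, ...) {
  data.frame(mean_B = x$mean_B, var_B = x$var_B,
             shannon_entropy_bits = x$shannon_entropy,
             entropy_rate_bits_per_s = x$entropy_rate,
             variance_rate_per_s = x$variance_rate,
             adhesion_probability = x$adhesion_probability)
}
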