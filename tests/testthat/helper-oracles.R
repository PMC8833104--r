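# Independent oracles used across the suite.  These deliberately avoid
# the package's log-space code paths: plain choose()/factorial()
# products for the stationary law, and a dense linear solve of the
# chemical master equation for the five-reaction signalling model.

# direct term-by-term stationary distribution (safe for B_max <= ~20)
direct_stationary <- function(L_max, R_max, K_d) {
  B_max <- min(L_max, R_max)
  U_max <- max(L_max, R_max)
  B <- 0:B_max
  a <- choose(B_max, B) * choose(U_max, B) * K_d^(-B) * factorial(B)
  list(a = a, Z = sum(a), p = a / sum(a))
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Exact stationary moments of the five-reaction model from the CME:
# enumerate (B, R_A) states (r5 leaves them unchanged), solve pi Q = 0.
cme_signalling_moments <- function(L_max, R_max, kon_over_nu, k_off,
                                   k_revert = k_off) {
  B_max <- min(L_max, R_max)
  keys <- character(0)
  for (B in 0:B_max) for (RA in 0:(R_max - B)) {
    keys <- c(keys, paste0(B, "_", RA))
  }
  n <- length(keys)
  key_i <- stats::setNames(seq_len(n), keys)
  Q <- matrix(0, n, n)
  for (B in 0:B_max) for (RA in 0:(R_max - B)) {
    i <- key_i[[paste0(B, "_", RA)]]
    L <- L_max - B
    RI <- R_max - B - RA
    add <- function(B2, RA2, rate) {
      if (rate > 0) {
        j <- key_i[[paste0(B2, "_", RA2)]]
        Q[i, j] <<- Q[i, j] + rate
        Q[i, i] <<- Q[i, i] - rate
      }
    }
    add(B + 1, RA, kon_over_nu * L * RI)       # L + R_I -> B
    add(B - 1, RA + 1, k_off * B)              # B -> L + R_A
    add(B + 1, RA - 1, kon_over_nu * L * RA)   # L + R_A -> B
    add(B, RA - 1, k_revert * RA)              # R_A -> R_I
  }
  A <- t(Q)
  A[n, ] <- 1
  p <- solve(A, c(rep(0, n - 1), 1))
  Bv <- as.numeric(sub("_.*", "", keys))
  RAv <- as.numeric(sub(".*_", "", keys))
  list(mean_B = sum(p * Bv),
       var_B = sum(p * Bv^2) - sum(p * Bv)^2,
       mean_RA = sum(p * RAv),
       mean_RAB = sum(p * RAv * Bv),
       signalling_rate = k_off * sum(p * RAv * Bv))
}

default_params <- function(L_max = 1000, R_max = 10, K_d = 100, k_off = 1) {
  binding_params(L_max, R_max, k_off = k_off, K_d = K_d)
}
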