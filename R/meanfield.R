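#' Mean-field (mass-action ODE) integration of the signalling model
#'
#' Deterministic counterpart of [simulate_signalling()]: the mass-action
#' rate equations matching the five stochastic propensities,
#'
#' \deqn{\dot L = -\kappa L (R_I + R_A) + k_{off} B}
#' \deqn{\dot R_I = -\kappa L R_I + k_{rev} R_A}
#' \deqn{\dot R_A = k_{off} B - \kappa L R_A - k_{rev} R_A}
#' \deqn{\dot B = \kappa L (R_I + R_A) - k_{off} B}
#' \deqn{\dot S = k_{off} R_A B,}
#'
#' with \eqn{\kappa = k_{on}/\nu}, integrated from the standard initial
#' condition `L(0) = L_max`, `R_I(0) = R_max`, `R_A(0) = B(0) = S(0) = 0`.
#' At large copy numbers the equilibrium `B` approaches the stationary
#' mean of the stochastic system, and the late-time `dS/dt` settles to a
#' constant signalling rate; this serves as an independent cross-check
#' on the simulator.
#'
#' @param params A [binding_params()] object.
#' @param t_end Integration horizon in seconds.
#' @param n_out Number of output time points (default 400).
#' @param k_revert Active-TCR reversion rate; `NULL` uses `k_off`.
#' @return A data frame of class `mean_field_path` with columns
#'   `time_s, L, R_I, R_A, B, S, dS_dt`.
#' @examples
#' p <- binding_params(1000, 100, k_off = 1, K_d = 100)
#' mf <- integrate_mean_field(p, t_end = 50)
#' tail(mf, 1)
#' @export
integrate_mean_field <- function(params, t_end, n_out = 400L,
                                 k_revert = NULL) {
  stopifnot(inherits(params, "binding_params"),
            is.numeric(t_end), length(t_end) == 1L, t_end > 0,
            n_out >= 2)
  kappa <- params$k_on_over_nu
  koff <- params$k_off
  krev <- if (is.null(k_revert)) koff else k_revert
  deriv <- function(t, y, parms) {
    L <- y[1]; RI <- y[2]; RA <- y[3]; B <- y[4]
    bind <- kappa * L * (RI + RA)
    list(c(L = -bind + koff * B,
           R_I = -kappa * L * RI + krev * RA,
           R_A = koff * B - kappa * L * RA - krev * RA,
           B = bind - koff * B,
           S = koff * RA * B))
  }
  y0 <- c(L = params$L_max, R_I = params$R_max, R_A = 0, B = 0, S = 0)
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-8)
  if (attr(sol, "istate")[1L] < 0) {
    stop("mean-field ODE integration failed; deSolve istate = ",
         attr(sol, "istate")[1L], call. = FALSE)
  }
  out <- as.data.frame(sol)
  names(out)[1] <- "time_s"
  out$dS_dt <- koff * out$R_A * out$B
  class(out) <- c("mean_field_path", "data.frame")
  out
}
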