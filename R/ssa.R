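#' Run configuration for the signalling-model protocol
#'
#' Stopping rules and replication settings for [simulate_signalling()]
#' and [estimate_signalling_rate()].  Defaults follow the published
#' protocol: each realization runs until the cumulative signal exceeds
#' `S_stop = 1e4` or time exceeds `t_stop = 1e4` s, and the signalling
#' rate is averaged over `n_reps = 10` replicates.
#'
#' @param S_stop Signal-count stopping threshold (positive; `Inf`
#'   disables it).
#' @param t_stop Time horizon in seconds (positive).
#' @param n_reps Number of replicates for rate estimation (>= 1).
#' @param seed Base RNG seed; replicate `i` uses `seed + i - 1`.
#'   Required by any stochastic estimate.
#' @param k_revert Rate at which an active TCR reverts to the inactive
#'   state, s^-1.  `NULL` (default) uses `k_off`, the model's single
#'   deactivation constant.
#' @return An object of class `signalling_config`.
#' @export
signalling_config <- function(S_stop = 1e4, t_stop = 1e4, n_reps = 10L,
                              seed = NULL, k_revert = NULL) {
  stopifnot(is.numeric(S_stop), length(S_stop) == 1L, S_stop > 0,
            is.numeric(t_stop), length(t_stop) == 1L, is.finite(t_stop),
            t_stop > 0,
            is.numeric(n_reps), length(n_reps) == 1L, n_reps >= 1)
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  }
  if (!is.null(k_revert)) {
    stopifnot(is.numeric(k_revert), length(k_revert) == 1L,
              is.finite(k_revert), k_revert >= 0)
  }
  structure(list(S_stop = S_stop, t_stop = t_stop,
                 n_reps = as.integer(n_reps), seed = seed,
                 k_revert = k_revert),
            class = "signalling_config")
}

#' Simulate reversible TCR-pMHC binding (Gillespie direct method)
#'
#' Exact stochastic simulation of `L + R <-> B` with propensities
#' `a_bind = (k_on/nu) L R` and `a_unbind = k_off B`.  The trajectory
#' ends at the first event time beyond `t_end`, with the state held at
#' `t_end`.  A holding-time-weighted occupancy histogram of `B` over
#' `[burn_in, t_end]` is always accumulated, so long runs can be
#' compared against [stationary_distribution()] without storing every
#' event.
#'
#' @param params A [binding_params()] object (integer copy numbers).
#' @param t_end Simulation horizon in seconds (positive).
#' @param seed Optional RNG seed (`set.seed()` is called when given).
#' @param B0 Initial complex count (default 0; must lie in
#'   `[0, B_max]`).
#' @param burn_in Time excluded from the occupancy histogram (default
#'   0).
#' @param record Store the full event-by-event trajectory?  Disable for
#'   long runs where only the occupancy summary is needed.
#' @param max_events Hard cap on the number of reaction events.
#' @return An object of class `ssa_trajectory`; see
#'   [simulate_signalling()] for the fields.
#' @examples
#' p <- binding_params(1000, 10, k_off = 1, K_d = 100)
#' tr <- simulate_binding(p, t_end = 10, seed = 1)
#' head(tr$states)
#' @export
simulate_binding <- function(params, t_end, seed = NULL, B0 = 0L,
                             burn_in = 0, record = TRUE,
                             max_events = if (record) 1e6 else 1e9) {
  stopifnot(inherits(params, "binding_params"),
            is.numeric(t_end), length(t_end) == 1L, t_end > 0,
            burn_in >= 0)
  check_count(B0, "B0")
  if (!is.null(seed)) set.seed(as_seed(seed))
  res <- ssa_binding_cpp(params$L_max, params$R_max, as.integer(B0),
                         params$k_on_over_nu, params$k_off,
                         t_end, burn_in, record, max_events)
  states <- NULL
  if (record) {
    states <- data.frame(time_s = res$times,
                         L = params$L_max - res$B,
                         R_I = params$R_max - res$B,
                         R_A = 0L,
                         B = res$B,
                         S = 0L)
  }
  structure(
    list(model = "binding", states = states, params = params,
         seed = seed, t_final = res$t_final, S_final = 0,
         B_final = res$B_final, n_events = res$n_events,
         occupancy = as.numeric(res$occupancy),
         occupancy_time = res$occupancy_time,
         mean_R_A = 0, burn_in = burn_in),
    class = "ssa_trajectory"
  )
}

#' Simulate the five-reaction minimal signalling model
#'
#' Exact Gillespie simulation of the minimal T cell activation model:
#'
#' * `L + R_I -> B` at rate `(k_on/nu) L R_I` (serial engagement),
#' * `B -> L + R_A` at rate `k_off B` (unbinding leaves the TCR in the
#'   conformationally active state),
#' * `L + R_A -> B` at rate `(k_on/nu) L R_A` (active TCRs rebind at
#'   the same rate),
#' * `R_A -> R_I` at rate `k_off R_A` (reversion),
#' * `R_A + B -> R_A + B + S` at rate `k_off R_A B` (aggregation: an
#'   active TCR adjacent to a complex emits one unit of signal).
#'
#' Initial conditions are `R_I(0) = R_max`, `R_A(0) = B(0) = S(0) = 0`.
#' The run terminates at the first of `S > S_stop`, the next event
#' falling beyond `t_stop` (state held at `t_stop`), or total
#' propensity zero.
#'
#' The marginal dynamics of `B` (and of `R = R_I + R_A`) are identical
#' in law to the plain reversible-binding system, so the analytic
#' stationary machinery applies to this model's complex number too.
#'
#' @param params A [binding_params()] object.
#' @param config A [signalling_config()] object.
#' @param seed RNG seed; defaults to `config$seed`.
#' @param burn_in Time excluded from occupancy/`R_A` averaging.
#' @param record Store the full trajectory?  (Default `FALSE`: long
#'   protocol runs only need the summaries.)
#' @param max_events Hard cap on the number of reaction events.
#' @return An object of class `ssa_trajectory`: a list with `model`,
#'   `states` (a data frame `time_s, L, R_I, R_A, B, S` when
#'   `record = TRUE`), `params`, `seed`, `t_final` (termination time
#'   `t*`), `S_final`, `n_events`, `occupancy` (holding-time-weighted
#'   distribution of `B` over `[burn_in, t*]`), and `mean_R_A` (the
#'   time-averaged active-TCR count).
#' @examples
#' p <- binding_params(10, 10, k_off = 1, K_d = 10)
#' tr <- simulate_signalling(p, signalling_config(t_stop = 50), seed = 1,
#'                           record = TRUE)
#' tail(tr$states)
#' @export
simulate_signalling <- function(params, config = signalling_config(),
                                seed = config$seed, burn_in = 0,
                                record = FALSE,
                                max_events = if (record) 1e6 else 1e9) {
  stopifnot(inherits(params, "binding_params"),
            inherits(config, "signalling_config"), burn_in >= 0)
  if (!is.null(seed)) set.seed(as_seed(seed))
  k_rev <- if (is.null(config$k_revert)) params$k_off else config$k_revert
  res <- ssa_signalling_cpp(params$L_max, params$R_max,
                            params$k_on_over_nu, params$k_off, k_rev,
                            config$S_stop, config$t_stop,
                            burn_in, record, max_events)
  states <- NULL
  if (record) {
    states <- data.frame(time_s = res$times,
                         L = params$L_max - res$B,
                         R_I = res$RI, R_A = res$RA,
                         B = res$B, S = res$S)
  }
  structure(
    list(model = "signalling", states = states, params = params,
         config = config, seed = seed,
         t_final = res$t_final, S_final = res$S_final,
         B_final = res$B_final, n_events = res$n_events,
         occupancy = as.numeric(res$occupancy),
         occupancy_time = res$occupancy_time,
         mean_R_A = res$RA_time_avg, burn_in = burn_in),
    class = "ssa_trajectory"
  )
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf("Gillespie trajectory (%s model)\n", x$model))
  cat(sprintf("  L_max = %d, R_max = %d, k_on/nu = %g, k_off = %g\n",
              x$params$L_max, x$params$R_max,
              x$params$k_on_over_nu, x$params$k_off))
  cat(sprintf("  %0.f events over %.4g s; final B = %d, final S = %g\n",
              x$n_events, x$t_final, x$B_final, x$S_final))
  if (is.null(x$states)) cat("  (trajectory not recorded; summaries only)\n")
  invisible(x)
}

#' Estimate the mean signalling rate (replicated protocol)
#'
#' Runs `n_reps` independent realizations of the signalling model; each
#' replicate `i` is seeded with `seed + i - 1` and terminated by the
#' stopping rules in `config`.  The per-replicate signalling rate is
#' `S(t*)/t*` at the termination time `t*` (0 when no time elapses);
#' the estimate is the mean over replicates.  The holding-time-averaged
#' active-TCR count `<R_A>` is returned alongside, for comparison with
#' the analytic `Var(B)`.
#'
#' @inheritParams simulate_signalling
#' @param burn_in Time excluded from the `<R_A>` average (the rate
#'   itself always uses the full `[0, t*]` window, as in the protocol).
#' @return A list with `mean_rate` (s^-1), `per_rep_rates`,
#'   `mean_R_A`, `per_rep_R_A`, `per_rep_t`, and the `config` used.
#' @examples
#' p <- binding_params(100, 10, k_off = 1, K_d = 100)
#' est <- estimate_signalling_rate(
#'   p, signalling_config(S_stop = 100, t_stop = 100, seed = 1))
#' est$mean_rate
#' @export
estimate_signalling_rate <- function(params, config = signalling_config(),
                                     burn_in = 0) {
  stopifnot(inherits(params, "binding_params"),
            inherits(config, "signalling_config"))
  if (is.null(config$seed)) {
    stop("a base seed is required in 'config' for rate estimation",
         call. = FALSE)
  }
  rates <- numeric(config$n_reps)
  ras <- numeric(config$n_reps)
  ts <- numeric(config$n_reps)
  for (i in seq_len(config$n_reps)) {
    tr <- simulate_signalling(params, config, seed = config$seed + i - 1,
                              burn_in = burn_in, record = FALSE)
    rates[i] <- if (tr$t_final > 0) tr$S_final / tr$t_final else 0
    ras[i] <- tr$mean_R_A
    ts[i] <- tr$t_final
  }
  list(mean_rate = mean(rates), per_rep_rates = rates,
       mean_R_A = mean(ras), per_rep_R_A = ras,
       per_rep_t = ts, config = config)
}

# keep derived seeds inside 32-bit integer range
as_seed <- function(seed) {
  as.integer(round(seed) %% .Machine$integer.max)
}
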