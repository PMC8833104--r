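#' Sweep binding and unbinding rates on a grid
#'
#' Evaluates the analytic stationary summaries over a grid of binding
#' propensities `k_on/nu` and unbinding rates `k_off` at fixed copy
#' numbers, the characterization used to contrast slow and fast
#' dynamics at equal affinity.  Default grids span the physiological
#' ranges `k_on/nu` in `[1e-4, 1e0]` s^-1 and `k_off` in `[1, 10]`
#' s^-1.
#'
#' @param L_max,R_max Copy numbers (defaults 1000 and 10).
#' @param kon_grid Vector of binding propensities, s^-1 (positive).
#' @param koff_grid Vector of unbinding rates, s^-1 (positive).
#' @return A data frame with one row per `(k_on/nu, k_off)` pair:
#'   columns `kon_over_nu, k_off, K_d, mean_B, shannon_entropy,
#'   entropy_rate`.
#' @examples
#' g <- sweep_rate_grid(kon_grid = 10^seq(-4, 0), koff_grid = c(1, 10))
#' head(g)
#' @export
sweep_rate_grid <- function(L_max = 1000L, R_max = 10L,
                            kon_grid = 10^seq(-4, 0, length.out = 9),
                            koff_grid = c(1, 10)) {
  stopifnot(all(kon_grid > 0), all(koff_grid > 0),
            length(kon_grid) > 0, length(koff_grid) > 0)
  grid <- expand.grid(kon_over_nu = kon_grid, k_off = koff_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- binding_params(L_max, R_max, k_off = grid$k_off[i],
                        k_on_over_nu = grid$kon_over_nu[i])
    s <- summary_measures(p)
    data.frame(kon_over_nu = p$k_on_over_nu, k_off = p$k_off, K_d = p$K_d,
               mean_B = s$mean_B, shannon_entropy = s$shannon_entropy,
               entropy_rate = s$entropy_rate)
  })
  do.call(rbind, res)
}

dose_responses <- c("entropy_rate", "variance_rate", "mean_signalling_rate",
                    "shannon_entropy", "mean_B", "adhesion_probability")

analytic_response <- function(response, L_max, R_max, k_off, K_d) {
  s <- summary_measures(binding_params(L_max, R_max, k_off = k_off,
                                       K_d = K_d))
  switch(response,
         entropy_rate = s$entropy_rate,
         variance_rate = s$variance_rate,
         shannon_entropy = s$shannon_entropy,
         mean_B = s$mean_B,
         adhesion_probability = s$adhesion_probability,
         stop("unknown analytic response: ", response))
}

#' Dose-response sweep over ligand number and affinity
#'
#' Computes a response surface over a grid of pMHC doses (`L_max`
#' values) and 2D dissociation constants (`K_d` values) at fixed
#' `R_max` and `k_off`.  Analytic responses (`entropy_rate`,
#' `variance_rate`, `shannon_entropy`, `mean_B`,
#' `adhesion_probability`) are evaluated exactly;
#' `mean_signalling_rate` runs the replicated stochastic protocol of
#' [estimate_signalling_rate()] for each cell (doses are rounded to
#' integers >= 1 at this boundary) and therefore requires a seed in
#' `config`.
#'
#' Default axes follow the physiological parametrization: doses
#' log-spaced over `[1, 1000]`, `K_d` in `{10, 100, 1000, 10000}`,
#' `R_max = 10`, `k_off = 1` s^-1.
#'
#' @param dose_axis Vector of `L_max` doses (positive, increasing).
#' @param kd_axis Vector of `K_d` values (positive).
#' @param R_max TCR copy number.
#' @param k_off Unbinding rate, s^-1.
#' @param response One of `"entropy_rate"`, `"variance_rate"`,
#'   `"mean_signalling_rate"`, `"shannon_entropy"`, `"mean_B"`,
#'   `"adhesion_probability"`.
#' @param config A [signalling_config()]; only used (and then required,
#'   with a seed) for `mean_signalling_rate`.
#' @return An object of class `dose_response_grid`: list with
#'   `dose_axis`, `kd_axis`, `response`, `values` (matrix
#'   `|kd_axis| x |dose_axis|`), `R_max`, `k_off`, `seed`.
#' @examples
#' g <- sweep_dose(kd_axis = c(10, 1e4), response = "entropy_rate")
#' g$values
#' @export
sweep_dose <- function(dose_axis = unique(round(10^seq(0, 3, length.out = 13))),
                       kd_axis = c(10, 1e2, 1e3, 1e4),
                       R_max = 10L, k_off = 1,
                       response = dose_responses,
                       config = NULL) {
  response <- match.arg(response)
  stopifnot(length(dose_axis) > 0, all(dose_axis > 0),
            length(kd_axis) > 0, all(kd_axis > 0))
  simulated <- response == "mean_signalling_rate"
  seed <- NULL
  if (simulated) {
    if (is.null(config) || is.null(config$seed)) {
      stop("'mean_signalling_rate' sweeps require a 'config' with a seed",
           call. = FALSE)
    }
    seed <- config$seed
    dose_axis <- pmax(1, round(dose_axis))
  }
  values <- matrix(NA_real_, nrow = length(kd_axis), ncol = length(dose_axis),
                   dimnames = list(K_d = signif(kd_axis, 6),
                                   L_max = signif(dose_axis, 6)))
  for (k in seq_along(kd_axis)) {
    for (d in seq_along(dose_axis)) {
      if (simulated) {
        p <- binding_params(dose_axis[d], R_max, k_off = k_off,
                            K_d = kd_axis[k])
        # each grid cell gets its own seed block so cells are independent
        cfg <- config
        cfg$seed <- seed + ((k - 1L) * length(dose_axis) + d - 1L) *
          config$n_reps
        values[k, d] <- estimate_signalling_rate(p, cfg)$mean_rate
      } else {
        values[k, d] <- analytic_response(response, dose_axis[d], R_max,
                                          k_off, kd_axis[k])
      }
    }
  }
  structure(list(dose_axis = dose_axis, kd_axis = kd_axis,
                 response = response, values = values,
                 R_max = as.integer(R_max), k_off = k_off, seed = seed,
                 config = if (simulated) config else NULL),
            class = "dose_response_grid")
}

#' @export
print.dose_response_grid <- function(x, ...) {
  cat(sprintf("Dose-response grid: %s (R_max = %d, k_off = %g)\n",
              x$response, x$R_max, x$k_off))
  cat(sprintf("  %d doses x %d affinities%s\n", length(x$dose_axis),
              length(x$kd_axis),
              if (!is.null(x$seed)) sprintf(", seed %g", x$seed) else ""))
  print(signif(x$values, 4))
  invisible(x)
}

#' Long-format view of a dose-response grid
#'
#' @param x A `dose_response_grid`.
#' @param ... Unused.
#' @return Data frame with columns `kd, L_max, response_name, value,
#'   seed`.
#' @export
as.data.frame.dose_response_grid <- function(x, ...) {
  data.frame(kd = rep(x$kd_axis, times = length(x$dose_axis)),
             L_max = rep(x$dose_axis, each = length(x$kd_axis)),
             response_name = x$response,
             value = as.vector(x$values),
             seed = if (is.null(x$seed)) NA_real_ else x$seed)
}

#' @export
plot.dose_response_grid <- function(x, ...) {
  graphics::matplot(x$dose_axis, t(x$values), type = "b", log = "x",
                    pch = 19, lty = 1, xlab = "dose (L_max)",
                    ylab = x$response, ...)
  graphics::legend("topleft", legend = paste0("K_d = ", signif(x$kd_axis, 3)),
                   col = seq_along(x$kd_axis), lty = 1, pch = 19, bty = "n")
  invisible(x)
}

# Bell-shaped means: maximum strictly interior to the dose axis and
# exceeding both endpoint responses by > 5% (guards float noise).
classify_dose_curve <- function(values, doses) {
  stopifnot(length(values) == length(doses), length(values) >= 1)
  i <- which.max(values)  # first maximum: ties break toward smaller dose
  interior <- i > 1L && i < length(values) &&
    values[i] > 1.05 * values[1L] && values[i] > 1.05 * values[length(values)]
  list(index = i, interior = interior,
       shape = if (interior) "bell" else "boundary")
}

#' Optimal dose for a given affinity
#'
#' Finds the dose maximizing the response row of a
#' [sweep_dose()] grid at the requested `K_d`.  Ties break toward the
#' smaller dose.  The result records whether the maximum is interior to
#' the dose axis (a bell-shaped curve) or attained at a boundary.
#'
#' @param grid A `dose_response_grid`.
#' @param kd One of `grid$kd_axis`.
#' @return List with `L_max_opt`, `response_opt`, `interior` (logical),
#'   `shape` (`"bell"` or `"boundary"`).
#' @export
find_optimal_dose <- function(grid, kd) {
  stopifnot(inherits(grid, "dose_response_grid"))
  if (length(grid$dose_axis) == 0L) stop("empty dose grid", call. = FALSE)
  k <- match(TRUE, abs(grid$kd_axis - kd) <= 1e-9 * abs(kd))
  if (is.na(k)) stop("'kd' is not on the grid's kd_axis", call. = FALSE)
  row <- grid$values[k, ]
  cls <- classify_dose_curve(row, grid$dose_axis)
  list(L_max_opt = grid$dose_axis[cls$index],
       response_opt = unname(row[cls$index]),
       interior = cls$interior, shape = cls$shape)
}

#' Optimal affinity for a given dose
#'
#' Evaluates an analytic response over a grid of dissociation constants
#' at fixed `L_max`, `R_max`, `k_off` and returns the maximizing `K_d`.
#' Ties break toward the larger `K_d` (weaker binding).
#'
#' @param L_max,R_max Copy numbers.
#' @param k_off Unbinding rate, s^-1.
#' @param kd_grid Vector of candidate `K_d` values (positive;
#'   log-spaced grids recommended).
#' @param response An analytic response name (see [sweep_dose()];
#'   `mean_signalling_rate` is not available here).
#' @return List with `K_d_opt`, `response_opt`, `interior` (logical:
#'   maximum strictly inside the grid).
#' @examples
#' find_optimal_kd(1000, 10, 1, 10^seq(1, 4, length.out = 25),
#'                 "entropy_rate")
#' @export
find_optimal_kd <- function(L_max, R_max, k_off, kd_grid,
                            response = setdiff(dose_responses,
                                               "mean_signalling_rate")) {
  response <- match.arg(response)
  if (length(kd_grid) == 0L) stop("empty K_d grid", call. = FALSE)
  stopifnot(all(kd_grid > 0))
  kd_grid <- sort(kd_grid)
  vals <- vapply(kd_grid, function(kd) {
    analytic_response(response, L_max, R_max, k_off, kd)
  }, numeric(1))
  # ties toward larger K_d: scan from the weak-binding end
  i <- length(vals) + 1L - which.max(rev(vals))
  list(K_d_opt = kd_grid[i], response_opt = vals[i],
       interior = i > 1L && i < length(vals))
}
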