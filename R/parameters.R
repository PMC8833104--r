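#' Binding parameters for the TCR-pMHC contact area
#'
#' Bundles the copy numbers and kinetic rates that every computation in
#' the package consumes: the total pMHC ligand count `L_max`, the total
#' TCR count `R_max`, the per-pair binding propensity `k_on_over_nu`
#' (s^-1), the unbinding rate `k_off` (s^-1) and the 2D contact area
#' `nu` (um^2).  Exactly one of `k_on_over_nu` and `K_d` must be given;
#' the other is derived through the dimensionless 2D dissociation
#' constant `K_d = k_off / k_on_over_nu`.
#'
#' `K_d` is stored in dimensionless copy-number form, the form in which
#' it enters the stationary distribution.  The physical quantity
#' `nu * k_off / k_on` is recovered only when converting to or from
#' measured surface units (see [kd_from_effective_affinity()]).
#' `k_on_over_nu = 0` is permitted as a limiting no-binding case and
#' corresponds to `K_d = Inf`.
#'
#' @param L_max Total pMHC ligand copy number (non-negative integer).
#' @param R_max Total TCR copy number (non-negative integer).
#' @param k_off Unbinding rate, s^-1 (strictly positive).
#' @param k_on_over_nu Binding propensity per reactant pair, s^-1
#'   (non-negative).  Mutually exclusive with `K_d`.
#' @param K_d Dimensionless 2D dissociation constant (positive, may be
#'   `Inf`).  Mutually exclusive with `k_on_over_nu`.
#' @param nu 2D contact area in um^2; defaults to `1e-1`, the measured
#'   order-of-magnitude estimate for T cell-APC contacts.
#'
#' @return An object of class `binding_params`: a list with fields
#'   `L_max`, `R_max`, `k_on_over_nu`, `k_off`, `K_d`, `nu`.
#'
#' @examples
#' p <- binding_params(L_max = 1000, R_max = 10, k_off = 1, K_d = 100)
#' p$k_on_over_nu  # 0.01
#' @export
binding_params <- function(L_max, R_max, k_off, k_on_over_nu = NULL,
                           K_d = NULL, nu = 1e-1) {
  check_count(L_max, "L_max")
  check_count(R_max, "R_max")
  if (!is.numeric(k_off) || length(k_off) != 1L || !is.finite(k_off) ||
      k_off <= 0) {
    stop("'k_off' must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0) {
    stop("'nu' must be a single positive finite number", call. = FALSE)
  }
  if (is.null(k_on_over_nu) == is.null(K_d)) {
    stop("exactly one of 'k_on_over_nu' and 'K_d' must be supplied",
         call. = FALSE)
  }
  if (is.null(k_on_over_nu)) {
    if (!is.numeric(K_d) || length(K_d) != 1L || is.na(K_d) || K_d <= 0) {
      stop("'K_d' must be a single positive number (Inf allowed)",
           call. = FALSE)
    }
    k_on_over_nu <- if (is.finite(K_d)) k_off / K_d else 0
  } else {
    if (!is.numeric(k_on_over_nu) || length(k_on_over_nu) != 1L ||
        !is.finite(k_on_over_nu) || k_on_over_nu < 0) {
      stop("'k_on_over_nu' must be a single non-negative finite number",
           call. = FALSE)
    }
    K_d <- if (k_on_over_nu > 0) k_off / k_on_over_nu else Inf
  }
  structure(
    list(L_max = as.integer(L_max), R_max = as.integer(R_max),
         k_on_over_nu = k_on_over_nu, k_off = k_off, K_d = K_d, nu = nu),
    class = "binding_params"
  )
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      abs(x - round(x)) > 1e-8) {
    stop(sprintf("'%s' must be a single non-negative integer", name),
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.binding_params <- function(x, ...) {
  cat("TCR-pMHC binding parameters\n")
  cat(sprintf("  L_max (pMHC ligands) : %d\n", x$L_max))
  cat(sprintf("  R_max (TCRs)         : %d\n", x$R_max))
  cat(sprintf("  k_on/nu              : %g /s\n", x$k_on_over_nu))
  cat(sprintf("  k_off                : %g /s\n", x$k_off))
  cat(sprintf("  K_d (dimensionless)  : %g\n", x$K_d))
  cat(sprintf("  contact area nu      : %g um^2\n", x$nu))
  invisible(x)
}

#' Complex-count bounds for reversible binding
#'
#' The maximum number of TCR-pMHC complexes, `B_max`, is the smaller of
#' the ligand and receptor totals; `U_max` is the larger.
#'
#' @param L_max,R_max Non-negative integer copy numbers.
#' @return A list with integer components `B_max` and `U_max`.
#' @examples
#' complex_bounds(1000, 10)  # B_max = 10, U_max = 1000
#' @export
complex_bounds <- function(L_max, R_max) {
  check_count(L_max, "L_max")
  check_count(R_max, "R_max")
  list(B_max = as.integer(min(L_max, R_max)),
       U_max = as.integer(max(L_max, R_max)))
}

#' Dimensionless 2D dissociation constant from kinetic rates
#'
#' `K_d = k_off / (k_on/nu)`, the copy-number form of the 2D
#' dissociation constant `nu * k_off / k_on`.
#'
#' @param k_on_over_nu Binding propensity per pair, s^-1 (positive).
#' @param k_off Unbinding rate, s^-1 (positive).
#' @return The dimensionless dissociation constant.
#' @examples
#' kd_from_rates(1e-4, 1)  # 1e4, the weak end of the physiological range
#' @export
kd_from_rates <- function(k_on_over_nu, k_off) {
  if (!is.numeric(k_on_over_nu) || length(k_on_over_nu) != 1L ||
      !is.finite(k_on_over_nu) || k_on_over_nu <= 0) {
    stop("'k_on_over_nu' must be a single positive finite number",
         call. = FALSE)
  }
  if (!is.numeric(k_off) || length(k_off) != 1L || !is.finite(k_off) ||
      k_off <= 0) {
    stop("'k_off' must be a single positive finite number", call. = FALSE)
  }
  k_off / k_on_over_nu
}

#' Copy number from a measured surface density
#'
#' Converts a surface density (molecules per um^2, as reported by
#' adhesion frequency assays) to an expected copy number within the
#' contact area: `count = density * nu`.  The result is real-valued;
#' callers round at the simulation boundary.
#'
#' @param density Surface density, um^-2 (non-negative).
#' @param nu Contact area, um^2 (positive).
#' @return Expected copy number (real-valued).
#' @examples
#' counts_from_density(1e2, 1e-1)  # 10 TCRs in the contact area
#' @export
counts_from_density <- function(density, nu) {
  if (!is.numeric(density) || any(density < 0) || any(!is.finite(density))) {
    stop("'density' must be non-negative and finite", call. = FALSE)
  }
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0) {
    stop("'nu' must be a single positive finite number", call. = FALSE)
  }
  density * nu
}

#' Dimensionless K_d from a fitted effective 2D affinity
#'
#' Adhesion frequency assays report the effective 2D affinity
#' `nu^2 / K_d` (um^4).  Inverting it at a known contact area gives the
#' dimensionless dissociation constant `K_d = nu^2 / eff_affinity`.
#'
#' @param eff_affinity Effective 2D affinity, um^4 (positive).
#' @param nu Contact area, um^2 (positive).
#' @return The dimensionless dissociation constant.
#' @examples
#' kd_from_effective_affinity(1e-3, 1e-1)  # 10 (strongest binder)
#' kd_from_effective_affinity(1e-6, 1e-1)  # 1e4 (weakest binder)
#' @export
kd_from_effective_affinity <- function(eff_affinity, nu) {
  if (!is.numeric(eff_affinity) || any(!is.finite(eff_affinity)) ||
      any(eff_affinity <= 0)) {
    stop("'eff_affinity' must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0) {
    stop("'nu' must be a single positive finite number", call. = FALSE)
  }
  nu^2 / eff_affinity
}
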