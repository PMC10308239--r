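# Steady-state balance of CO2 diffusion into the plastid against
# Michaelis-Menten carbon fixation:
#
#   d[CO2]_p/dt = D*([CO2]_m - [CO2]_p) - Vmax*[CO2]_p/([CO2]_p + K)
#
# At steady state [CO2]_p solves the quadratic
#
#   x^2 + (Vmax/D + K - [CO2]_m)*x - K*[CO2]_m = 0,
#
# whose unique non-negative root is taken (the other root is negative
# whenever [CO2]_m > 0). Only the ratio Vmax/D matters for the steady state;
# time units are arbitrary and cancel out of the fold changes downstream.

# Resolve (vmax, d) vs vmax_over_d into a consistent pair. When only the
# ratio is supplied, D is normalized to 1 (steady states are identical).
resolve_kinetics <- function(vmax = NULL, d = NULL, vmax_over_d = NULL) {
  if (!is.null(vmax_over_d)) {
    if (!is.null(vmax) || !is.null(d)) {
      abort_invalid(
        "Supply either `vmax_over_d` or the pair (`vmax`, `d`), not both."
      )
    }
    check_number(vmax_over_d, "vmax_over_d", lower = 0)
    return(list(vmax = vmax_over_d, d = rep_len(1, length(vmax_over_d))))
  }
  if (is.null(vmax) || is.null(d)) {
    abort_invalid("Supply both `vmax` and `d`, or `vmax_over_d`.")
  }
  check_number(vmax, "vmax", lower = 0)
  check_number(d, "d", lower = 0)
  out <- recycle_args(vmax = vmax, d = d)
  list(vmax = out$vmax, d = out$d)
}

#' Michaelis-Menten carbon-fixation rate
#'
#' Fixation rate at a given plastid CO2 concentration,
#' \eqn{V = V_{max} \, [CO_2]_p / ([CO_2]_p + K)}.
#'
#' @param co2_p Plastid CO2 concentration, umol/L.
#' @param vmax Maximum fixation rate, umol/L per unit time.
#' @param k Half-saturation constant, umol/L (default 44, a RuBisCO-scale
#'   affinity).
#' @return Fixation rate in the units of `vmax`, in [0, vmax).
#' @examples
#' fixation_rate(44, vmax = 1, k = 44) # half saturation
#' @export
fixation_rate <- function(co2_p, vmax = 1, k = 44) {
  check_number(co2_p, "co2_p", lower = 0)
  check_number(vmax, "vmax", lower = 0)
  check_number(k, "k", lower = 0, allow_lower = FALSE)
  args <- recycle_args(co2_p = co2_p, vmax = vmax, k = k)
  args$vmax * args$co2_p / (args$co2_p + args$k)
}

#' Steady-state plastid CO2 concentration
#'
#' The non-negative root of the steady-state quadratic. Computed in the
#' cancellation-safe form `2*k*co2_m / (b + sqrt(b^2 + 4*k*co2_m))` when
#' `b = vmax/d + k - co2_m > 0`, so it stays accurate for very large
#' `vmax/d` where the naive formula loses all digits.
#'
#' @param co2_m Middle-space CO2 concentration, umol/L.
#' @param vmax,d Maximum fixation rate and membrane diffusion coefficient;
#'   give both, or give `vmax_over_d` alone.
#' @param vmax_over_d The ratio Vmax/D in umol/L; when used, D is normalized
#'   to 1 (the steady state depends on the ratio only).
#' @param k Half-saturation constant, umol/L.
#' @return Plastid CO2 in umol/L, in [0, co2_m]. `d = 0` is handled as an
#'   explicit limit: the plastid equilibrates to 0 if `vmax > 0`, else to
#'   `co2_m`.
#' @examples
#' steady_state_co2p(64.59, vmax_over_d = 44, k = 44)
#' @export
steady_state_co2p <- function(co2_m, vmax = NULL, d = NULL,
                              vmax_over_d = NULL, k = 44) {
  check_number(co2_m, "co2_m", lower = 0)
  check_number(k, "k", lower = 0, allow_lower = FALSE)
  kin <- resolve_kinetics(vmax, d, vmax_over_d)
  args <- recycle_args(co2_m = co2_m, vmax = kin$vmax, d = kin$d, k = k)
  quadratic_root(args$co2_m, args$vmax, args$d, args$k)
}

quadratic_root <- function(co2_m, vmax, d, k) {
  out <- numeric(length(co2_m))
  zero_d <- d == 0
  out[zero_d] <- ifelse(vmax[zero_d] > 0, 0, co2_m[zero_d])
  i <- !zero_d
  if (any(i)) {
    b <- vmax[i] / d[i] + k[i] - co2_m[i]
    disc <- sqrt(b^2 + 4 * k[i] * co2_m[i])
    out[i] <- ifelse(b > 0,
      2 * k[i] * co2_m[i] / (b + disc),
      (disc - b) / 2
    )
  }
  out
}

#' Solve the full steady state of the plastid CO2 balance
#'
#' Solves for the steady-state plastid CO2 and reports the fixation rate,
#' the diffusive influx and the quadratic residual, so that the flux balance
#' (fixation = diffusion) and the root quality are inspectable. Accepts a
#' data frame of conditions in `data` (columns `co2_m`, `vmax`, `d`,
#' `vmax_over_d`, `k` override the arguments), so parameter grids pipe in.
#'
#' @param data Optional data frame supplying any arguments as columns.
#' @inheritParams steady_state_co2p
#' @return A tibble with one row per condition: `co2_m`, `vmax`, `d`, `k`,
#'   `co2_p`, `vcfix`, `diffusive_flux` (= d*(co2_m - co2_p)) and
#'   `residual` (quadratic evaluated at the root). At steady state
#'   `vcfix == diffusive_flux` up to roundoff (exactly zero when `d = 0` and
#'   `vmax > 0`, where both fluxes vanish).
#' @examples
#' solve_steady_state(co2_m = 64.59, vmax = 44, d = 1, k = 44)
#' @export
solve_steady_state <- function(data = NULL, co2_m = NULL, vmax = NULL,
                               d = NULL, vmax_over_d = NULL, k = 44) {
  if (!is.null(data) && !is.data.frame(data)) {
    abort_invalid("`data` must be a data frame or NULL.")
  }
  co2_m <- col_or_default(data, "co2_m", co2_m)
  vmax <- col_or_default(data, "vmax", vmax)
  d <- col_or_default(data, "d", d)
  vmax_over_d <- col_or_default(data, "vmax_over_d", vmax_over_d)
  k <- col_or_default(data, "k", k)
  if (is.null(co2_m)) abort_invalid("`co2_m` is required.")

  check_number(co2_m, "co2_m", lower = 0)
  check_number(k, "k", lower = 0, allow_lower = FALSE)
  kin <- resolve_kinetics(vmax, d, vmax_over_d)
  args <- recycle_args(co2_m = co2_m, vmax = kin$vmax, d = kin$d, k = k)

  co2_p <- quadratic_root(args$co2_m, args$vmax, args$d, args$k)
  vcfix <- ifelse(co2_p + args$k > 0,
                  args$vmax * co2_p / (co2_p + args$k), 0)
  b <- ifelse(args$d > 0, args$vmax / args$d, 0) + args$k - args$co2_m
  tibble::tibble(
    co2_m = args$co2_m,
    vmax = args$vmax,
    d = args$d,
    k = args$k,
    co2_p = co2_p,
    vcfix = vcfix,
    diffusive_flux = args$d * (args$co2_m - co2_p),
    residual = ifelse(args$d > 0,
                      co2_p^2 + b * co2_p - args$k * args$co2_m, 0)
  )
}

#' Fixation rate in the uptake-limited regime (Vmax << D)
#'
#' When fixation is slow relative to diffusion the plastid equilibrates with
#' the middle space, so the rate is the Michaelis-Menten term evaluated at
#' the middle-space CO2 itself: `vmax * co2_m / (co2_m + k)`.
#'
#' @inheritParams steady_state_co2p
#' @return Fixation rate in the units of `vmax`.
#' @export
vcfix_uptake_limit <- function(co2_m, vmax = 1, k = 44) {
  fixation_rate(co2_m, vmax = vmax, k = k)
}

#' Fixation rate in the diffusion-limited regime (Vmax >> D)
#'
#' When fixation is fast the plastid CO2 is drawn down to ~0 and every
#' molecule that diffuses in is fixed: the rate is `d * co2_m`.
#'
#' @inheritParams steady_state_co2p
#' @return Fixation rate in the units of `d * co2_m`.
#' @export
vcfix_diffusion_limit <- function(co2_m, d = 1) {
  check_number(co2_m, "co2_m", lower = 0)
  check_number(d, "d", lower = 0)
  d * co2_m
}
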