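# Time integration of the plastid CO2 balance. The closed-form quadratic
# root is the production path; the ODE here is the independent check that the
# root really is the attractor of the dynamics.

#' Integrate the plastid CO2 balance over time
#'
#' Numerically integrates
#' \deqn{d[CO_2]_p/dt = D([CO_2]_m - [CO_2]_p) - V_{max}[CO_2]_p/([CO_2]_p+K)}
#' from an initial plastid concentration, using an adaptive-step solver
#' (deSolve's lsoda). The derivative at 0 is non-negative whenever
#' `co2_m >= 0`, so trajectories stay non-negative and relax monotonically
#' to the steady state from either side. This serves as a brute-force oracle
#' for [steady_state_co2p()].
#'
#' @param co2_p0 Initial plastid CO2, umol/L.
#' @inheritParams steady_state_co2p
#' @param t_end End of the integration window; defaults to `60 / d`, many
#'   relaxation times (the linear relaxation rate is at least `d`).
#' @param reltol Convergence threshold: the trajectory is flagged converged
#'   when the final derivative magnitude is below
#'   `reltol * d * max(1, co2_m)`.
#' @param n_steps Number of output time points.
#' @return A `ccm_trajectory`: a tibble with columns `time` and `co2_p`, and
#'   attributes `converged` (logical), `final_derivative`, and `params`.
#'   Non-convergence within `t_end` is flagged with a warning, never
#'   silently.
#' @examples
#' traj <- integrate_dynamics(0, co2_m = 64.6, vmax = 44, d = 1, k = 44)
#' attr(traj, "converged")
#' @export
integrate_dynamics <- function(co2_p0, co2_m, vmax = NULL, d = NULL,
                               vmax_over_d = NULL, k = 44,
                               t_end = NULL, reltol = 1e-8,
                               n_steps = 200L) {
  check_number(co2_p0, "co2_p0", lower = 0, scalar = TRUE)
  check_number(co2_m, "co2_m", lower = 0, scalar = TRUE)
  check_number(k, "k", lower = 0, allow_lower = FALSE, scalar = TRUE)
  check_number(reltol, "reltol", lower = 0, allow_lower = FALSE)
  kin <- resolve_kinetics(vmax, d, vmax_over_d)
  vmax <- kin$vmax[1L]
  d <- kin$d[1L]
  if (d <= 0) {
    abort_invalid("`d` must be positive to integrate the dynamics.")
  }
  if (is.null(t_end)) t_end <- 60 / d
  check_number(t_end, "t_end", lower = 0, allow_lower = FALSE, scalar = TRUE)

  deriv <- function(t, y, parms) {
    co2_p <- max(y[1L], 0)
    list(d * (co2_m - co2_p) - vmax * co2_p / (co2_p + k))
  }
  times <- seq(0, t_end, length.out = n_steps)
  sol <- deSolve::ode(
    y = c(co2_p = co2_p0), times = times, func = deriv, parms = NULL,
    method = "lsoda", rtol = 1e-10, atol = 1e-14 * max(1, co2_m)
  )
  co2_p_t <- pmax(as.numeric(sol[, "co2_p"]), 0)
  final <- co2_p_t[length(co2_p_t)]
  final_deriv <- d * (co2_m - final) - vmax * final / (final + k)
  converged <- abs(final_deriv) < reltol * d * max(1, co2_m)
  if (!converged) {
    warning(
      sprintf(
        "trajectory not converged by t_end = %g (|dCO2_p/dt| = %g)",
        t_end, abs(final_deriv)
      ),
      call. = FALSE
    )
  }
  out <- tibble::tibble(time = as.numeric(sol[, "time"]), co2_p = co2_p_t)
  structure(
    out,
    class = c("ccm_trajectory", class(out)),
    converged = converged,
    final_derivative = final_deriv,
    params = list(co2_p0 = co2_p0, co2_m = co2_m, vmax = vmax, d = d, k = k)
  )
}

#' @export
print.ccm_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "Plastid CO2 trajectory: co2_m = %g, vmax = %g, d = %g, k = %g\n",
    p$co2_m, p$vmax, p$d, p$k
  ))
  cat(sprintf(
    "converged: %s (final dCO2_p/dt = %.3g); final co2_p = %.6g\n",
    attr(x, "converged"), attr(x, "final_derivative"),
    x$co2_p[nrow(x)]
  ))
  NextMethod()
}

#' Plot a plastid CO2 trajectory
#'
#' @param object A `ccm_trajectory` from [integrate_dynamics()].
#' @param ... Unused.
#' @return A ggplot of plastid CO2 against time, with the closed-form steady
#'   state as a dashed reference line.
#' @export
autoplot.ccm_trajectory <- function(object, ...) {
  p <- attr(object, "params")
  ss <- steady_state_co2p(p$co2_m, vmax = p$vmax, d = p$d, k = p$k)
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$co2_p)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = ss, linetype = "dashed") +
    ggplot2::labs(
      x = "time (1/D units)",
      y = expression("[CO"[2] * "]"[p] ~ "(µmol" ~ L^-1 * ")")
    )
}
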