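# The pH x Vmax/D scan: middle-space CO2, plastid CO2 and the fixation-rate
# fold change relative to a reference middle-space pH, plus the analytic
# uptake-limited / diffusion-limited fold-change bounds.

#' Configuration for a middle-space pH scan
#'
#' Bundles and validates every parameter of the scan. Defaults are the study
#' conditions: DIC 993 umol/L and reference pH 7.59 (the one mean
#' intracellular pH measured for a diatom), half-saturation K = 44 umol/L,
#' standard seawater at 298.15 K and salinity 35, a pH grid of 5-8 in steps
#' of 0.05 (which contains the reference and the commonly quoted points 7, 6,
#' 5 exactly), and seven log-spaced Vmax/D values spanning 0.1-10^4 umol/L,
#' wide enough to bracket both kinetic regimes.
#'
#' @param dic Middle-space dissolved inorganic carbon, umol/L.
#' @param reference_ph Reference middle-space pH; fold changes are relative
#'   to the fixation rate here. Added to the pH grid if absent.
#' @param ph Numeric vector of pH grid points, strictly increasing.
#' @param vmax_over_d Numeric vector of Vmax/D ratios, umol/L, strictly
#'   increasing.
#' @param k Half-saturation constant of fixation, umol/L.
#' @param temperature Absolute temperature, Kelvin.
#' @param salinity Practical salinity.
#' @return A `ccm_config` list with the validated fields.
#' @examples
#' scan_config()
#' scan_config(ph = c(5, 6, 7, 7.59), vmax_over_d = c(0.1, 44, 1e4))
#' @export
scan_config <- function(dic = 993,
                        reference_ph = 7.59,
                        ph = seq(5, 8, by = 0.05),
                        vmax_over_d = 10^seq(-1, 4, length.out = 7),
                        k = 44,
                        temperature = 298.15,
                        salinity = 35) {
  check_number(dic, "dic", lower = 0, scalar = TRUE)
  check_number(reference_ph, "reference_ph", scalar = TRUE)
  check_number(ph, "ph")
  check_number(vmax_over_d, "vmax_over_d", lower = 0)
  check_number(k, "k", lower = 0, allow_lower = FALSE, scalar = TRUE)
  check_conditions(temperature, salinity)
  check_number(temperature, "temperature", scalar = TRUE, lower = 0,
               allow_lower = FALSE)
  check_number(salinity, "salinity", scalar = TRUE, lower = 0, upper = 50)
  if (is.unsorted(ph, strictly = TRUE)) {
    abort_invalid("`ph` grid must be strictly increasing.")
  }
  if (is.unsorted(vmax_over_d, strictly = TRUE)) {
    abort_invalid("`vmax_over_d` grid must be strictly increasing.")
  }
  if (!reference_ph %in% ph) {
    ph <- sort(c(ph, reference_ph))
  }
  structure(
    list(
      dic = dic, reference_ph = reference_ph, ph = ph,
      vmax_over_d = vmax_over_d, k = k,
      temperature = temperature, salinity = salinity
    ),
    class = "ccm_config"
  )
}

#' @export
print.ccm_config <- function(x, ...) {
  cat("Middle-space pH scan configuration\n")
  cat(sprintf("  dic:          %g umol/L\n", x$dic))
  cat(sprintf("  reference_ph: %g\n", x$reference_ph))
  cat(sprintf("  ph grid:      %d points in [%g, %g]\n",
              length(x$ph), min(x$ph), max(x$ph)))
  cat(sprintf("  vmax_over_d:  %s umol/L\n",
              paste(signif(x$vmax_over_d, 4), collapse = ", ")))
  cat(sprintf("  k:            %g umol/L\n", x$k))
  cat(sprintf("  temperature:  %g K, salinity: %g\n",
              x$temperature, x$salinity))
  invisible(x)
}

#' Run the middle-space pH scan
#'
#' For every (pH, Vmax/D) pair: computes the middle-space CO2 from carbonate
#' chemistry, solves the steady-state plastid CO2 and fixation rate, and
#' normalizes the rate by its value at the reference pH at the same Vmax/D.
#' The middle-space CO2 depends on pH only, so it is constant across Vmax/D
#' within a pH value.
#'
#' @param config A [scan_config()].
#' @return A `ccm_scan` tibble with columns `ph`, `vmax_over_d`, `co2_m`,
#'   `co2_p`, `vcfix`, `fold_change`, carrying the config as an attribute.
#'   `fold_change` is exactly 1 at the reference pH; if the reference rate
#'   is zero (e.g. `vmax_over_d = 0`) the fold change is reported as `NA`.
#' @examples
#' scan <- run_scan(scan_config(ph = c(5, 6, 7, 7.59)))
#' dplyr::filter(scan, ph == 6)
#' @export
run_scan <- function(config = scan_config()) {
  if (!inherits(config, "ccm_config")) {
    abort_invalid("`config` must be a `ccm_config` from scan_config().")
  }
  co2_m_grid <- co2_from_dic(config$dic, config$ph,
                             config$temperature, config$salinity)
  co2_m_ref <- co2_from_dic(config$dic, config$reference_ph,
                            config$temperature, config$salinity)

  grid <- tidyr::expand_grid(
    ph = config$ph,
    vmax_over_d = config$vmax_over_d
  ) |>
    dplyr::mutate(co2_m = co2_m_grid[match(.data$ph, config$ph)])

  ss <- solve_steady_state(
    co2_m = grid$co2_m, vmax_over_d = grid$vmax_over_d, k = config$k
  )
  vcfix_ref <- solve_steady_state(
    co2_m = co2_m_ref, vmax_over_d = config$vmax_over_d, k = config$k
  )$vcfix

  out <- grid |>
    dplyr::mutate(
      co2_p = ss$co2_p,
      vcfix = ss$vcfix,
      vcfix_ref = vcfix_ref[match(.data$vmax_over_d, config$vmax_over_d)],
      fold_change = dplyr::if_else(
        .data$vcfix_ref > 0, .data$vcfix / .data$vcfix_ref, NA_real_
      )
    ) |>
    dplyr::select(-"vcfix_ref")

  structure(
    out,
    class = c("ccm_scan", class(out)),
    config = config
  )
}

#' Analytic fold-change bounds for a pH shift
#'
#' The fixation-rate fold change between a pH and the reference pH depends on
#' Vmax/D, but is bracketed by two closed forms: the uptake-limited limit
#' (Vmax << D), where the plastid equilibrates with the middle space and the
#' fold change is the ratio of Michaelis-Menten terms
#' `[c/(c+K)] / [c_ref/(c_ref+K)]`, and the diffusion-limited limit
#' (Vmax >> D), where every incoming molecule is fixed and the fold change
#' is the plain concentration ratio `c/c_ref`. For acidification below the
#' reference pH the uptake-limited value is the lower bound.
#'
#' @param ph pH value(s) to compare against the reference.
#' @param config A [scan_config()]; supplies the reference pH, DIC, K and
#'   seawater conditions.
#' @return A tibble with columns `ph`, `co2_m`, `low` (uptake-limited fold
#'   change) and `high` (diffusion-limited fold change).
#' @examples
#' fold_change_bounds(c(7, 6, 5))
#' @export
fold_change_bounds <- function(ph, config = scan_config()) {
  if (!inherits(config, "ccm_config")) {
    abort_invalid("`config` must be a `ccm_config` from scan_config().")
  }
  check_number(ph, "ph")
  co2_m <- co2_from_dic(config$dic, ph, config$temperature, config$salinity)
  co2_ref <- co2_from_dic(config$dic, config$reference_ph,
                          config$temperature, config$salinity)
  mm <- function(c) c / (c + config$k)
  tibble::tibble(
    ph = ph,
    co2_m = co2_m,
    low = mm(co2_m) / mm(co2_ref),
    high = co2_m / co2_ref
  )
}

#' Split a scan into the three canonical tables
#'
#' One table per panel of the standard figure: middle-space CO2 against pH
#' (independent of Vmax/D), plastid CO2 against pH per Vmax/D, and the
#' relative fixation rate (fold change) against pH per Vmax/D.
#'
#' @param scan A `ccm_scan` from [run_scan()], or a [scan_config()] (in
#'   which case the scan is run first).
#' @return A named list of three tibbles: `middle_co2` (`ph`, `co2_m`),
#'   `plastid_co2` (`ph`, `vmax_over_d`, `co2_p`), `fold_change` (`ph`,
#'   `vmax_over_d`, `fold_change`).
#' @examples
#' tabs <- figure_tables(scan_config(ph = c(5, 6, 7, 7.59)))
#' tabs$middle_co2
#' @export
figure_tables <- function(scan = scan_config()) {
  if (inherits(scan, "ccm_config")) scan <- run_scan(scan)
  if (!inherits(scan, "ccm_scan")) {
    abort_invalid("`scan` must be a `ccm_scan` or a `ccm_config`.")
  }
  list(
    middle_co2 = dplyr::distinct(
      tibble::as_tibble(scan), .data$ph, .data$co2_m
    ),
    plastid_co2 = dplyr::select(
      tibble::as_tibble(scan), "ph", "vmax_over_d", "co2_p"
    ),
    fold_change = dplyr::select(
      tibble::as_tibble(scan), "ph", "vmax_over_d", "fold_change"
    )
  )
}

#' @export
print.ccm_scan <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Middle-space pH scan: %d pH x %d Vmax/D points (reference pH %g)\n",
    length(cfg$ph), length(cfg$vmax_over_d), cfg$reference_ph
  ))
  NextMethod()
}

#' Tidy a pH scan result
#'
#' @param x A `ccm_scan`.
#' @param ... Unused.
#' @return The scan as a plain tibble, one row per (pH, Vmax/D) grid point.
#' @export
tidy.ccm_scan <- function(x, ...) {
  class(x) <- setdiff(class(x), "ccm_scan")
  attr(x, "config") <- NULL
  tibble::as_tibble(x)
}

#' One-row summary of a pH scan
#'
#' @param x A `ccm_scan`.
#' @param ... Unused.
#' @return A one-row tibble: grid sizes, the configuration scalars, the
#'   reference middle-space CO2, and the fold-change range over the grid.
#' @export
glance.ccm_scan <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_ph = length(cfg$ph),
    n_vmax_over_d = length(cfg$vmax_over_d),
    dic = cfg$dic,
    reference_ph = cfg$reference_ph,
    k = cfg$k,
    temperature = cfg$temperature,
    salinity = cfg$salinity,
    co2_m_reference = co2_from_dic(cfg$dic, cfg$reference_ph,
                                   cfg$temperature, cfg$salinity),
    min_fold_change = min(x$fold_change, na.rm = TRUE),
    max_fold_change = max(x$fold_change, na.rm = TRUE)
  )
}

#' Plot a pH scan
#'
#' @param object A `ccm_scan` from [run_scan()].
#' @param panel Which quantity to plot against middle-space pH: `"co2_m"`
#'   (middle-space CO2, independent of Vmax/D), `"co2_p"` (plastid CO2, one
#'   line per Vmax/D) or `"fold_change"` (relative fixation rate, one line
#'   per Vmax/D, with the analytic bounds as dashed envelopes).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ccm_scan <- function(object,
                              panel = c("fold_change", "co2_m", "co2_p"),
                              ...) {
  panel <- match.arg(panel)
  cfg <- attr(object, "config")
  df <- tibble::as_tibble(object)
  if (panel == "co2_m") {
    return(
      ggplot2::ggplot(
        dplyr::distinct(df, .data$ph, .data$co2_m),
        ggplot2::aes(.data$ph, .data$co2_m)
      ) +
        ggplot2::geom_line() +
        ggplot2::labs(
          x = expression(pH[m]),
          y = expression("[CO"[2] * "]"[m] ~ "(µmol" ~ L^-1 * ")")
        )
    )
  }
  yvar <- if (panel == "co2_p") "co2_p" else "fold_change"
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(.data$ph, .data[[yvar]],
                 colour = factor(signif(.data$vmax_over_d, 3)))
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(pH[m]),
      y = if (panel == "co2_p") {
        expression("[CO"[2] * "]"[p] ~ "(µmol" ~ L^-1 * ")")
      } else {
        sprintf("C fixation rate relative to pH %g", cfg$reference_ph)
      },
      colour = expression(V[max] / D ~ "(µmol" ~ L^-1 * ")")
    )
  if (panel == "fold_change") {
    bounds <- fold_change_bounds(cfg$ph, cfg)
    p <- p +
      ggplot2::geom_line(
        data = bounds, ggplot2::aes(.data$ph, .data$low),
        inherit.aes = FALSE, linetype = "dashed"
      ) +
      ggplot2::geom_line(
        data = bounds, ggplot2::aes(.data$ph, .data$high),
        inherit.aes = FALSE, linetype = "dashed"
      ) +
      ggplot2::scale_y_log10()
  }
  p
}
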