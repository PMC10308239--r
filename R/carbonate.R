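# Carbonate chemistry of the middle space: apparent dissociation constants of
# carbonic acid as functions of temperature and salinity, and the speciation
# of dissolved inorganic carbon (DIC) at a given pH.
#
# Unit conventions, fixed package-wide:
#   * temperature in Kelvin (the ln(T) terms require it),
#   * [H+], K1, K2 in mol L^-1,
#   * DIC and all carbon species in umol L^-1. The speciation formula uses
#     only the dimensionless ratios K1/[H+] and K1*K2/[H+]^2, so DIC units
#     propagate unchanged -- do not convert DIC to mol L^-1.

# Coefficients of the pK1/pK2 regressions in T (Kelvin) and practical
# salinity. Kept verbatim in this one table; everything else derives from it.
.pk_coefficients <- list(
  pk1 = c(inv_T = 3633.86, const = -61.2172, ln_T = 9.6777,
          S = -0.011555, S2 = 0.0001152),
  pk2 = c(inv_T = 471.78, const = 25.9290, ln_T = -3.16967,
          S = -0.01781, S2 = 0.0001122)
)

eval_pk <- function(coef, temperature, salinity) {
  coef[["inv_T"]] / temperature + coef[["const"]] +
    coef[["ln_T"]] * log(temperature) +
    coef[["S"]] * salinity + coef[["S2"]] * salinity^2
}

check_conditions <- function(temperature, salinity) {
  check_number(temperature, "temperature", lower = 0, allow_lower = FALSE)
  check_number(salinity, "salinity", lower = 0, upper = 50)
  if (any(salinity > 40)) {
    warning("salinity above the typical oceanic range (0-40)", call. = FALSE)
  }
  invisible(NULL)
}

#' First apparent dissociation constant of carbonic acid (as pK)
#'
#' Empirical regression of pK1 = -log10(K1) on absolute temperature and
#' practical salinity, valid for oceanic conditions.
#'
#' @param temperature Absolute temperature in Kelvin.
#' @param salinity Practical salinity (dimensionless). Values outside the
#'   typical oceanic range 0-40 trigger a warning; values outside 0-50 are
#'   rejected.
#' @return pK1 (dimensionless), vectorized over the inputs.
#' @examples
#' carb_pk1(298.15, 35)
#' @export
carb_pk1 <- function(temperature, salinity = 35) {
  check_conditions(temperature, salinity)
  eval_pk(.pk_coefficients$pk1, temperature, salinity)
}

#' Second apparent dissociation constant of carbonic acid (as pK)
#'
#' @inheritParams carb_pk1
#' @return pK2 (dimensionless), vectorized over the inputs.
#' @examples
#' carb_pk2(298.15, 35)
#' @export
carb_pk2 <- function(temperature, salinity = 35) {
  check_conditions(temperature, salinity)
  eval_pk(.pk_coefficients$pk2, temperature, salinity)
}

#' Carbonic-acid dissociation constants for given seawater conditions
#'
#' @inheritParams carb_pk1
#' @return A tibble with columns `temperature`, `salinity`, `pk1`, `pk2`,
#'   `k1`, `k2`; the K's are on the mol per litre scale, `k1 = 10^-pk1`,
#'   `k2 = 10^-pk2`.
#' @examples
#' dissociation_constants(298.15, 35)
#' @export
dissociation_constants <- function(temperature = 298.15, salinity = 35) {
  args <- recycle_args(temperature = temperature, salinity = salinity)
  pk1 <- carb_pk1(args$temperature, args$salinity)
  pk2 <- carb_pk2(args$temperature, args$salinity)
  tibble::tibble(
    temperature = args$temperature,
    salinity = args$salinity,
    pk1 = pk1,
    pk2 = pk2,
    k1 = 10^(-pk1),
    k2 = 10^(-pk2)
  )
}

#' CO2 concentration from DIC and pH
#'
#' The dissolved CO2 fraction of DIC at a given pH:
#' \deqn{[CO_2] = \frac{[DIC]}{1 + K_1/[H^+] + K_1 K_2 / [H^+]^2}}
#' with \eqn{[H^+] = 10^{-pH}} mol/L. This is the quantity that drives
#' diffusion into the plastid: acidifying the middle space shifts DIC from
#' bicarbonate towards CO2.
#'
#' @param dic Dissolved inorganic carbon in umol/L.
#' @param ph pH of the compartment.
#' @inheritParams carb_pk1
#' @return CO2 concentration in umol/L (same units as `dic`), in (0, dic].
#' @examples
#' co2_from_dic(993, 7.59) # reference middle-space conditions, ~17 umol/L
#' co2_from_dic(993, c(7.59, 7, 6, 5))
#' @export
co2_from_dic <- function(dic, ph, temperature = 298.15, salinity = 35) {
  check_number(dic, "dic", lower = 0)
  check_number(ph, "ph")
  kk <- dissociation_constants(temperature, salinity)
  args <- recycle_args(dic = dic, ph = ph, k1 = kk$k1, k2 = kk$k2)
  h <- 10^(-args$ph)
  args$dic / (1 + args$k1 / h + args$k1 * args$k2 / h^2)
}

#' Full carbonate speciation of a compartment
#'
#' Splits DIC into CO2, HCO3- and CO3^2- at the given pH, temperature and
#' salinity. Accepts either scalar/vector arguments or a data frame whose
#' columns (`dic`, `ph`, `temperature`, `salinity`; all optional) override
#' the defaults, so parameter grids pipe straight in.
#'
#' @param data Optional data frame supplying any of the other arguments as
#'   columns; unnamed columns fall back to the argument defaults.
#' @inheritParams co2_from_dic
#' @return A tibble with one row per condition: `dic`, `ph`, `temperature`,
#'   `salinity`, `h` (mol/L), `co2`, `hco3`, `co3` (umol/L). The three
#'   species sum to `dic` by construction.
#' @examples
#' speciate(dic = 993, ph = 7.59)
#' tibble::tibble(ph = c(7.59, 7, 6, 5)) |> speciate()
#' @export
speciate <- function(data = NULL, dic = 993, ph = 7.59,
                     temperature = 298.15, salinity = 35) {
  if (!is.null(data) && !is.data.frame(data)) {
    abort_invalid("`data` must be a data frame or NULL.")
  }
  dic <- col_or_default(data, "dic", dic)
  ph <- col_or_default(data, "ph", ph)
  temperature <- col_or_default(data, "temperature", temperature)
  salinity <- col_or_default(data, "salinity", salinity)

  check_number(dic, "dic", lower = 0)
  check_number(ph, "ph")
  kk <- dissociation_constants(temperature, salinity)
  args <- recycle_args(
    dic = dic, ph = ph,
    temperature = kk$temperature, salinity = kk$salinity,
    k1 = kk$k1, k2 = kk$k2
  )
  h <- 10^(-args$ph)
  co2 <- args$dic / (1 + args$k1 / h + args$k1 * args$k2 / h^2)
  tibble::tibble(
    dic = args$dic,
    ph = args$ph,
    temperature = args$temperature,
    salinity = args$salinity,
    h = h,
    co2 = co2,
    hco3 = co2 * args$k1 / h,
    co3 = co2 * args$k1 * args$k2 / h^2
  )
}
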