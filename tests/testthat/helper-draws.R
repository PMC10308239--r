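# Random parameter draws shared by the property-style tests.
# log-uniform over the physically interesting ranges.
draw_params <- function(n, seed = 1,
                        ratio_range = c(1e-3, 1e5)) {
  set.seed(seed)
  tibble::tibble(
    co2_m = 10^stats::runif(n, -1, 3),
    vmax_over_d = 10^stats::runif(n, log10(ratio_range[1]),
                                  log10(ratio_range[2])),
    k = 10^stats::runif(n, 0, 2.5)
  )
}

draw_speciation_inputs <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    dic = stats::runif(n, 0, 3000),
    ph = stats::runif(n, 3, 10),
    temperature = stats::runif(n, 273.15, 308.15),
    salinity = stats::runif(n, 0, 40)
  )
}
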