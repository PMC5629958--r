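# shared fixtures for the trial-statistics and synthetic-data tests

significance_class_ref <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))
}

default_noise_sd_of <- function(v) {
  c(ber_incidence = 0.4, marketable_yield = 3.0, sar = 0.25,
    salinity = 0.08, avail_n = 6.0, avail_p = 0.9, avail_k = 6.0)[[v]]
}

default_surfaces_copy <- function() {
  list(ber_incidence = response_surface(8.5, -1.2, -0.5),
       marketable_yield = response_surface(105, 7, 8),
       sar = response_surface(9.0, -1.0, 0.6, -0.1),
       salinity = response_surface(2.05, -0.25, -0.1),
       avail_n = response_surface(155, 3, 11),
       avail_p = response_surface(18.2, 0.5, 1.2),
       avail_k = response_surface(130, 3, 6))
}
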