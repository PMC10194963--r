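# Shared builders for the test suite.  Everything is generated in code at
# fixed seeds; no stored fixtures.

# a clean oculomotor ramp (no artifacts) with the given slope (units/s)
make_ramp_trace <- function(n = 2000, rate = 500, slope = 1) {
  oculomotor_trace(slope * (seq_len(n) - 1) / rate, rate = rate)
}

# per-subject forward/reverse delay-time maps for a synthetic study;
# 64 epochs/condition keep the extreme-value noise floor of the reverse
# map well below a quarter of the forward effect
study_maps <- function(n_sub, n_ep, delays, times, window, seed,
                       cfg_fun = sim_config, bias_correct = FALSE) {
  out <- list(fwd_int = list(), fwd_dif = list(),
              rev_int = list(), rev_dif = list())
  for (s in seq_len(n_sub)) {
    ei <- synth_epochs(n_ep, "to_INT", cfg_fun(seed = seed * 1000 + s),
                       window = window)
    ed <- synth_epochs(n_ep, "to_DIF", cfg_fun(seed = seed * 1000 + 500 + s),
                       window = window)
    out$fwd_int[[s]] <- directed_information(ei$front, ei$back, delays, times,
                                             bias_correct = bias_correct)$values
    out$fwd_dif[[s]] <- directed_information(ed$front, ed$back, delays, times,
                                             bias_correct = bias_correct)$values
    out$rev_int[[s]] <- directed_information(ei$back, ei$front, delays, times,
                                             bias_correct = bias_correct)$values
    out$rev_dif[[s]] <- directed_information(ed$back, ed$front, delays, times,
                                             bias_correct = bias_correct)$values
  }
  out
}

grand_mean <- function(lst) Reduce(`+`, lst) / length(lst)

# standardized decoder dataset from the generator
make_decoder_data <- function(n_per_class, noise_sd = 0.5, seed = 11,
                              fast_phase_rate = 0) {
  cfg <- sim_config(noise_sd = noise_sd, fast_phase_rate = fast_phase_rate,
                    seed = seed)
  dat <- synth_okn_epochs(n_per_class, cfg)
  sc <- stats::sd(dat$x)
  if (sc > 0) dat$x <- dat$x / sc
  dat
}
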