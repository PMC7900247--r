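# canonical presynaptic bundles used across tests
mf_presyn <- function() presyn_params(p = 0.6, tau_rec = 8, tau_facil = 5, tau_i = 1)
gg_presyn <- function() presyn_params(p = 0.35, tau_rec = 36, tau_facil = 58.5, tau_i = 0.1)

# independent brute-force oracle for the release recursion: integrates the
# three-pool ODEs between spikes with a fine Euler step instead of the
# closed-form relaxation used by the implementation
release_oracle <- function(spike_times, pr, dt = 5e-4) {
  R <- 1; E <- 0; I <- 0; u <- 0
  out <- numeric(length(spike_times))
  t_last <- spike_times[1]
  for (k in seq_along(spike_times)) {
    if (k > 1) {
      nstep <- ceiling((spike_times[k] - t_last) / dt)
      h <- (spike_times[k] - t_last) / nstep
      for (s in seq_len(nstep)) {
        dE <- -E / pr$tau_i
        dI <- E / pr$tau_i - I / pr$tau_rec
        dR <- I / pr$tau_rec
        du <- -u / pr$tau_facil
        E <- E + h * dE; I <- I + h * dI; R <- R + h * dR; u <- u + h * du
      }
    }
    u <- u + pr$p * (1 - u)
    out[k] <- u * R
    R <- R - out[k]
    E <- E + out[k]
    t_last <- spike_times[k]
  }
  out
}

# small deterministic current trace with two identical biexponential events
two_event_trace <- function(amp = -20, t1 = 60, t2 = 200) {
  spec <- synthetic_spec(tau_rise = 1, tau_decay = 18, amplitude = amp,
                         event_times = c(t1, t2), duration = 360, dt = 0.05)
  gen_psc_train(spec)
}
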