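# deterministic bimodal train: n_bursts bursts of `spikes_per_burst`
# spikes at fixed intra-burst ISI, separated by `gap_s`
make_bimodal_train <- function(n_bursts = 20, spikes_per_burst = 6,
                               intra_isi = 0.005, gap_s = 1) {
  period <- (spikes_per_burst - 1) * intra_isi + gap_s
  as.vector(outer(seq(0, by = intra_isi,
                      length.out = spikes_per_burst),
                  period * (seq_len(n_bursts) - 1), "+"))
}

# small two-electrode ground truth + raw recording for detection tests
small_truth_recording <- function(seed = 5, duration_s = 60,
                                  n_electrodes = 2,
                                  wf = waveform_model(amplitude_uv = 40,
                                                      noise_sd_uv = 5)) {
  par <- preset("hPSC_peak")
  par$n_electrodes <- as.integer(n_electrodes)
  par$duration_s <- duration_s
  truth <- simulate_trains(par, seed = seed)
  rec <- synthesize_raw(truth, wf, seed = seed)
  list(truth = truth, rec = rec)
}
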