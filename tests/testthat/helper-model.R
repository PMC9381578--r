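# Calibrated model shared across test files. Calibration is fast (<0.1 s)
# and deterministic, so it is simply recomputed at suite load.
calibrated <- calibrate_endpoints(photophilic_model())

# Measurement model with well-separated populations for the trivial gating
# cases (the default geometric SD 1.8 deliberately leaves ~2% overlap).
separated_cytometry <- function(n_events = 5000) {
  measurement_model(n_events = n_events,
                    pos_sdlog = log(1.2), neg_sdlog = log(1.2))
}
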