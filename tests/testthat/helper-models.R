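# calibration model matching a simulation preset's known truth: the slope,
# efficiency and flow constants the trace was generated with (intercept 0,
# because detected net intensities are already background-subtracted)
truth_model <- function(preset) {
  cfg <- preset$config
  calibration_model(response_slope = cfg$response_slope,
                    transport_efficiency = cfg$transport_efficiency,
                    flow = cfg$sample_flow, dwell_time = cfg$dwell_time)
}

acq_duration <- function(config) config$n_dwells * config$dwell_time

# quantify a preset simulation end to end (detect -> merge -> concentrations)
run_pipeline <- function(preset, seed, n_sigma = 5L) {
  tr <- simulate_trace(preset$config, preset$population, seed = seed)
  ev <- merge_split_events(detect_particles(tr, n_sigma = n_sigma))
  model <- truth_model(preset)
  res <- concentrations(ev, model, flow = preset$config$sample_flow,
                        duration = acq_duration(preset$config),
                        dilution_factor = preset$config$dilution_factor,
                        density = preset$population$density)
  list(trace = tr, events = ev, model = model, result = res)
}
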