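# Demo pipeline configuration: generate a noiseless control/drug pair
# from the default calibrated binding model, fit both curves, and run
# the coupled-equilibrium inference end to end.
seed: 1
output_dir: statenav-demo-out
stages: [synth, fit, infer]
model:
  v_half: -75.2      # mV, control availability midpoint
  slope: 7.9         # mV, Boltzmann slope factor
  kd_rest: 360       # nM, resting-state dissociation constant
  kd_inact: 50       # nM, inactivated-state dissociation constant
  drug_conc: 300     # nM
noise:
  sd: 0.0            # additive Gaussian noise on normalized current
voltages: {from: -130, to: -20, by: 5}
control_drift: 0     # mV, time-matched drug-free midpoint drift
dose_response:
  ic50: 1820         # nM
  hill_n: 1
  concs: [300, 1000, 3000, 10000, 30000]
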