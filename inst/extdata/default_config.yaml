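# Default run configuration: 380 ml flat-panel vessel, case-1 calibration,
# the seven-step light staircase, two-flux light mode.
run_id: demo
output_dir: "."
seed: 1
geometry:
  fill_height: 0.1439
optics:
  kappa_medium: 2.5
  sigma_bubbles: 1.0
kinetics:
  mu_max: 0.364
  K_I_S: 114.5
  K_I_i: 72.46
simulation:
  setpoints_uE: [50, 100, 200, 300, 500, 950, 1200]
  calibration_case: 1
  hold_hours: 24
  dt_h: 0.05
  light_mode: two_flux
trace:
  n_particles: 50
  duration: 60
  dt: 0.1
  setpoint_uE: 300
campaign:
  setpoints_uE: [50, 100, 200, 300, 500, 950, 1200]
  cases: [1, 2, 3]
  replicates: [3, 2, 2]
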