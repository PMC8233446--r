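# taSSAW bead-separation validation device: 19.32 MHz (lambda = 200 um),
# theta = 15 deg, w = 1000 um, h = 75 um, PS beads 9.9 / 7.3 um,
# calibration 7.5 V -> 1 MPa. All units SI.
device:
  preset: validation
  tilt_deg: 15.0
  drive_voltage: 7.5
numerics:
  mode: overdamped
  tol: 1.0e-6
  streaming: yes
  streaming_grid: [64, 24, 8]
output:
  directory: sawstream-out
seed: 1
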