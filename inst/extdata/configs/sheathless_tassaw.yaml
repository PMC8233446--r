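# Sheathless three-stage separator: lambda = 400 um (9.99 MHz free-surface
# operation), theta = 10 deg, inlet 6 mm/s, side flow 18 mm/s, focusing
# width lambda/2 = 200 um; PS beads 4 / 10 um ("beads") or WBC / MCF-7
# ("cells"). All units SI.
device:
  preset: sheathless
  particles: beads
  tilt_deg: 10.0
  drive_voltage: 40.0
numerics:
  mode: overdamped
  tol: 1.0e-6
  streaming: yes
  streaming_grid: [64, 24, 8]
output:
  directory: sawstream-out
seed: 1
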