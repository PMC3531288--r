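# Calibrated model defaults: threshold-switched CICR reaction with
# gap-junction diffusion on a cell lattice (dimensionless units).
parameters:
  uc1: 0.3        # lower concentration threshold (CICR trigger)
  uc2: 3.0        # upper threshold (entry to permanent refractory state)
  k1: 0.03        # intake rate below uc1
  k2: -0.025      # release rate between uc1 and uc2
  k3: 0.0045      # refractory intake rate above uc2
  c0: 2.0         # stimulus concentration
settings:
  dt: 0.01        # dimensionless integration step
  n_steps: 15000
  record_every: 1
  convention: calibrated
d_edge: 0.6       # edge (side-contact) diffusion coefficient
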