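# Default fisheries run: printed parameterization, full action grid.
model: fisheries
params:
  r: 1.0
  K_max: 10000
  sigma_K: 0.55
  sigma_H: 0.50
  c: 500
m_min: 0.0
m_max: 1.0
m_step: 0.01
seed: 1
out_dir: segsolve-out
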