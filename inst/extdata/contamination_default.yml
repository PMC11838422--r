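# Default configuration for the soma-targeting contamination experiment.
# Every entry overrides the package default of the same name; omitted
# entries keep their defaults (see ?contamination_config).
seed: 1
n_neurons: 30
fov_um: [128, 128]
pixel_size: 1
frame_rate: 10
n_frames: 600
spike_rate_hz: 0.25
modality: widefield
photons_per_unit: 50
neuropil_r: 0.7
bin_edges_um: [0, 200, 400, 800]
indicator:
  name: FRCaMPi
  kd: 81
  hill_n: 3.1
  f_apo: 1
  f_sat: 16.3
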