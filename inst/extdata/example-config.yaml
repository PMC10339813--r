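# Example configuration for the psinetfs CLI (desk-scale).
seed: 7
fs: 256
epoch_len_s: 4
n_channels: 8
n_epochs_per_group: 6
noise_sd: 0.3
band_coupling:
  alpha: [0.30, 0.70]
  beta: [0.45, 0.55]
tau: 0.3
bands: [alpha, beta]
reference: none
method: psi
scheme: kfold10
algorithms: [mopso_gdm]
ensemble:
  n_random: 20
  rewires_per_edge: 10
optimizer:
  n_particles: 12
  n_iterations: 8
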