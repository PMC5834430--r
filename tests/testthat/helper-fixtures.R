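# shared fixtures: all data are generated in code at test time

# white-matter-like truth: substantial strictly diffusion-limited fraction
wm_truth <- function() modtriexp_params(0.15, 0.58, 816e-6, 4525e-6)

# gray-matter-like truth: near-zero floor, very-slow pool at 445e-6
gm_truth <- function() modtriexp_params(0.02, 0.16, 445e-6, 1800e-6)

# one noisy voxel curve at a given per-average SNR, deterministic by seed
sim_voxel_curve <- function(params, seed, snr = 25, s0 = 560,
                            scheme = default_bvalue_scheme()) {
  set.seed(seed)
  raw <- acquire_voxel(tissue_class("t", params, s0, 0), scheme,
                       sigma = s0 / snr)
  normalize_signal(raw, scheme)
}

# random plausible modified tri-exponential truth (brain-like ranges)
random_modtriexp <- function() {
  modtriexp_params(runif(1, 0, 0.2), runif(1, 0.3, 0.7),
                   runif(1, 300e-6, 1000e-6), runif(1, 1500e-6, 4500e-6))
}

# largest relative deviation of fitted params from a named truth vector
rel_err <- function(params, truth) {
  max(abs(unlist(params[names(truth)]) / truth - 1))
}
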