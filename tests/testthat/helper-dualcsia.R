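# shared fixtures: all synthetic, generated in code

# noiseless exact-Rayleigh series on the standard nine-vial grid
noiseless_series <- function(epsilon_c, epsilon_cl = NA_real_,
                             delta0_c = 0, delta0_cl = 0,
                             f_grid = seq(0.9, 0.1, by = -0.1),
                             n_replicates = 1L) {
  cfg <- simulation_config(
    epsilon_c = epsilon_c, epsilon_cl = epsilon_cl,
    delta0_c = delta0_c, delta0_cl = delta0_cl,
    f_grid = f_grid, noise_sd = 0, n_replicates = n_replicates
  )
  simulate_rayleigh_series(cfg)
}

# OLS slope of delta13C on delta37Cl for exact-Rayleigh points with
# delta0 = 0, f = 0.9 ... 0.1, eps_C = -27.5, eps_Cl = -5.3 permil;
# frozen from an independent brute-force lm() on the closed-form points
LAMBDA_NOISELESS_DCA <- 5.3252219058
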