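# shared fixtures, all generated in code

lj_names <- c("sigma_C", "sigma_H", "eps_C", "eps_H")

# Table-style acquisition specs used across tests
grid1296_spec <- function() grid_spec(
  min  = c(0.0750, 0.0683, 0.2465, 0.0300),
  step = c(0.0500, 0.0455, 0.1643, 0.0200),
  max  = c(0.3250, 0.2958, 1.0680, 0.1300))

grid2401_spec <- function() grid_spec(
  min  = c(0.0500, 0.0455, 0.1643, 0.0200),
  step = c(0.0500, 0.0455, 0.1643, 0.0200),
  max  = c(0.3500, 0.3185, 1.1501, 0.1400))

sobol1_space <- function() parameter_space(
  lj_names, c(0.0500, 0.0450, 0.1500, 0.0200),
  c(0.3500, 0.3200, 1.1500, 0.1400))

# noiseless deterministic oracle configuration
quiet_oracle <- function(...) oracle_config(noise_sd = 0, failure_prob = 0,
                                            rugged_amplitude = 0, ...)

# small synthetic density dataset from an arbitrary response function
toy_dataset <- function(points, fn, name = "toy") {
  density_dataset(data.frame(points, density = fn(as.matrix(points)),
                             valid = TRUE), name = name)
}

prevopt_params <- function() lj_params(0.3286, 0.2606, 0.6730, 0.1194)
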