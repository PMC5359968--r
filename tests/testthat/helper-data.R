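# Shared fixtures, built in code at test time.

# Benchmark-design data set (101 subjects, X equally spaced on [1, 10]).
bench_data <- function(seed = 1) simulate_mediation(seed = seed)

# Small linear mediation data (p = q = p' = q' = 1), positive by shifting
# intercepts well above zero.
linear_data <- function(n = 60, seed = 1, sigma_M = 0.5, sigma_Y = 0.5,
                        rho = 0) {
  simulate_mediation(n = n, seed = seed, x = NULL, x_range = c(1, 8),
                     p = 1, q = 1, p_prime = 1, q_prime = 1,
                     i_M = 4, a = 0.8, i_Y = 6, c_prime = 0.7, b = 0.5,
                     sigma_M = sigma_M, sigma_Y = sigma_Y, rho = rho)
}

# Data with no X -> M pathway (a = 0).
null_pathway_data <- function(n = 100, seed = 1) {
  simulate_mediation(n = n, seed = seed, x_range = c(1, 10),
                     p = 1, q = 1, p_prime = 1, q_prime = 1,
                     i_M = 5, a = 0, i_Y = 6, c_prime = 0.5, b = 0.5,
                     sigma_M = 0.7, sigma_Y = 0.7)
}
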