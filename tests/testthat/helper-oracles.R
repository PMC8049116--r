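# Independent oracles and fixture builders shared across tests.

# O(N^2) all-pairs elastic force reference, independent of the package's
# cell-list implementation.
brute_elastic <- function(positions, k_EL, r_0, cutoff) {
  n <- nrow(positions)
  out <- matrix(0, n, 3)
  pos <- cbind(positions$x, positions$y, positions$z)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- pos[i, ] - pos[j, ]
      r <- sqrt(sum(d^2))
      if (r == 0 || r > cutoff) next
      out[i, ] <- out[i, ] - k_EL * (r - r_0) * d / r
    }
  }
  out
}

# Closed-form Haldane curve for generating synthetic irradiance-growth data.
haldane_mu <- function(I, mu_max, K_S, K_i) mu_max * I / (K_S + I + I^2 / K_i)

# The seven experimental staircase setpoints (uE).
staircase_uE <- c(50, 100, 200, 300, 500, 950, 1200)

# Noisy replicated staircase dataset from a given kinetic parameter set.
make_recovery_data <- function(kin, sigma = 0.02, replicates = 3, seed = 1) {
  I <- microE_to_wm2(staircase_uE)
  mu <- growth_rate(I, kin)
  set.seed(seed)
  do.call(rbind, lapply(seq_len(replicates), function(r) {
    data.frame(I_Wm2 = I, mu_h = mu * exp(rnorm(length(I), 0, sigma)))
  }))
}

minimal_config <- function(path, setpoints = c(100, 300), hold = 2,
                           extra = "") {
  writeLines(c(
    "run_id: testrun",
    "seed: 7",
    "kinetics:",
    "  mu_max: 0.364",
    "  K_I_S: 114.5",
    "  K_I_i: 72.46",
    "simulation:",
    paste0("  setpoints_uE: [", paste(setpoints, collapse = ", "), "]"),
    paste0("  hold_hours: ", hold),
    "  dt_h: 0.05",
    "  light_mode: two_flux",
    extra
  ), path)
  path
}
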