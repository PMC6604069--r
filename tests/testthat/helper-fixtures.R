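# Shared fixtures and independent oracles for the test suite.

# pure-water GHz process at 25 C (Debye)
water_model <- function(tau = tau_water_25C[["diagram"]]) {
  spectrum_model(5.2, relaxation_process(73.2, tau))
}

# brute-force box-count oracle: loop over every box, test any() occupancy.
# Deliberately independent of the packed-index implementation in box_count().
naive_box_count <- function(x, sizes) {
  dm <- dim(x)
  vapply(sizes, function(s) {
    if (s == 1L) return(as.numeric(sum(x)))  # boxes are single cells
    starts <- lapply(dm, function(d) seq(1L, d, by = s))
    n <- 0L
    if (length(dm) == 2L) {
      for (i in starts[[1]]) for (j in starts[[2]]) {
        if (any(x[i:min(i + s - 1L, dm[1]), j:min(j + s - 1L, dm[2])]))
          n <- n + 1L
      }
    } else {
      for (i in starts[[1]]) for (j in starts[[2]]) for (k in starts[[3]]) {
        if (any(x[i:min(i + s - 1L, dm[1]),
                  j:min(j + s - 1L, dm[2]),
                  k:min(k + s - 1L, dm[3])]))
          n <- n + 1L
      }
    }
    as.numeric(n)
  }, numeric(1))
}

# descending-branch trajectory fixtures mirroring the two trajectory
# families seen in aqueous systems: a solution-type arc that approaches its
# beta asymptote, and a near-vertical dispersion-type arc far from it
solution_trajectory <- function(D = 1.44, noise = 0.02, seed = NULL) {
  synth_trajectory(D, branch = "descending", omega_s = 1 / 2.1e-12,
                   tau0_s = 3e-12, beta_noise = noise, seed = seed)
}

dispersion_trajectory <- function(D = 0.16, noise = 0.02, seed = NULL) {
  synth_trajectory(D, branch = "descending", omega_s = 6.5e11, tau0_s = 1e-11,
                   tau_range = c(1.2e-11, 1.56e-11),
                   beta_noise = noise, seed = seed)
}
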