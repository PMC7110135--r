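# shared fixtures built in code

wt_truth_vector <- function() {
  c(kd_um = 1.14e-3, ss_kp = 2.6e-2, ss_ku = 0.1, ss_kq = 1e-2,
    ss_ks = 1e-4, ds_kp = 4e-3, ds_ku = 0.1, ds_ks = 5e-4)
}

f86e_truth_vector <- function() {
  c(kd_um = 10.2,
    `kp_dT-50` = 2e-3, `kp_dN-50` = 1.2e-3, `kp_dA-50` = 5e-4,
    `kp_dN-50p` = 4e-4,
    `kpr_dT-50` = 1e-2, `kpr_dN-50` = 4e-3, `kpr_dA-50` = 1e-3,
    `kpr_dN-50p` = 1e-4)
}

# a capacity-1 monomer-only model: exact two-state relaxation
# occupancy(t) = a/(a+r) * (1 - exp(-(a+r) t)) during association
two_state_occupancy <- function(a, r, t) a / (a + r) * (1 - exp(-(a + r) * t))

# solution distribution object with prescribed concentrations (for building
# rate matrices directly in tests)
manual_distribution <- function(conc, kd_um = 1) {
  d <- polymer_distribution(kd_um, 0, n_max = length(conc))
  d$concentrations_um <- conc
  d$total_monomer_um <- sum(seq_along(conc) * conc)
  d
}

# cheap two-parameter toy model for exercising the ABC machinery without
# the kinetic simulator: y(t) = A * exp(-k t) on a fixed grid
toy_simulator <- function(times = seq(0, 10, by = 0.5)) {
  function(theta) {
    list(toy = theta[["amp"]] * exp(-theta[["rate"]] * times))
  }
}

toy_priors <- function() {
  prior_spec(data.frame(name = c("amp", "rate"),
                        lower = c(1e-2, 1e-3),
                        upper = c(1e2, 1e1)))
}
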