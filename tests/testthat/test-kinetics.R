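test_that("a 50-mer substrate yields a 17-state model and a 16-species ladder", {
  dist <- polymer_distribution(1.14e-3, 0.15, n_max = 16)
  expect_length(dist$concentrations_um, 16L)
  Q <- build_rate_matrix(get_substrate("dN-50"), wt_parameter_preset()$ss,
                         dist)
  expect_identical(dim(Q), c(17L, 17L))
  expect_equal(colSums(Q), rep(0, 17), tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("rate matrices conserve probability for every variant and topology", {
  dist <- polymer_distribution(0.01, 3)
  sub <- get_substrate("dN-17")
  pars <- list(
    kinetic_params("ssWT", kd_um = 0.01, kp = 0.1, ku = 1, kq = 0.1,
                   ks = 0.01),
    kinetic_params("ssWT", kd_um = 0.01, kp = 0.1, ku = 1, kq = 0.1,
                   ks = 0.01, reverse_topology = "whole_nucleus"),
    kinetic_params("dsWT", kd_um = 0.01, kp = 0.1, ku = 1, ks = 0.01),
    kinetic_params("singleReverse", kd_um = 0.01, kp = 0.1, kpr = 0.05)
  )
  for (p in pars) {
    Q <- build_rate_matrix(sub, p, dist)
    expect_equal(colSums(Q), rep(0, 6), tolerance = 1e-14,
                 ignore_attr = TRUE)
    expect_true(all(Q[lower.tri(Q) | upper.tri(Q)] >= 0))
  }
})

test_that("capacity-1 chain reproduces the closed-form two-state relaxation", {
  sub <- dna_substrate("cap1", "single", 3, 1)
  # build Q directly from a manual monomer-only distribution: a = r = 0.1
  dist <- manual_distribution(c(0.1), kd_um = 1e9)
  p <- kinetic_params("singleReverse", kd_um = 1e9, kp = 1, kpr = 0.1)
  Qa <- build_rate_matrix(sub, p, dist)
  expect_equal(Qa, matrix(c(-0.1, 0.1, 0.1, -0.1), 2), tolerance = 1e-12)
  proto <- injection_protocol(0.1, t_association_s = 5, t_dissociation_s = 5,
                              dt_association_s = 1)
  Qd <- build_rate_matrix(sub, p, zero_distribution(dist))
  occ <- simulate_occupancy(Qa, Qd, proto)
  nb <- mean_occupancy(occ)
  i5 <- which(nb$time_s == 5)
  expect_equal(nb$n_bound[i5], two_state_occupancy(0.1, 0.1, 5),
               tolerance = 1e-10)
  expect_equal(nb$n_bound[i5], 0.3161, tolerance = 2e-4)
})

test_that("zero forward rate leaves all DNA unbound", {
  sub <- get_substrate("dN-14")
  p <- kinetic_params("ssWT", kd_um = 1, kp = 0, ku = 1, kq = 1, ks = 1)
  dist <- polymer_distribution(1, 3)
  occ <- simulate_occupancy(build_rate_matrix(sub, p, dist),
                            build_rate_matrix(sub, p, zero_distribution(dist)),
                            injection_protocol(3, 20, 20))
  expect_equal(occ$D[1, ], rep(1, ncol(occ$D)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("occupancies stay a probability distribution through both phases", {
  truth <- wt_parameter_preset()
  for (nm in c("dN-17", "dN-50", "dN-11p")) {
    sub <- get_substrate(nm)
    p <- if (sub$strandedness == "single") truth$ss else truth$ds
    conc <- if (sub$length_nt == 50) 0.15 else 3
    dist <- polymer_distribution(truth$kd_um, conc)
    occ <- simulate_occupancy(
      build_rate_matrix(sub, p, dist),
      build_rate_matrix(sub, p, zero_distribution(dist)),
      injection_protocol(conc, 60, 300))
    expect_equal(colSums(occ$D), rep(1, ncol(occ$D)), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(occ$D >= 0))
    nb <- mean_occupancy(occ)$n_bound
    expect_true(all(nb <= sub$capacity + 1e-9))
    # dissociation phase: N non-increasing
    nd <- nb[occ$phase == "dissociation"]
    expect_true(all(diff(nd) <= 1e-12))
  }
})

test_that("irreversible binding saturates at capacity", {
  sub <- get_substrate("dN-14")
  p <- kinetic_params("ssWT", kd_um = 1, kp = 10, ku = 0, kq = 0, ks = 0)
  dist <- polymer_distribution(1, 3)
  occ <- simulate_occupancy(
    build_rate_matrix(sub, p, dist),
    build_rate_matrix(sub, p, zero_distribution(dist)),
    injection_protocol(3, t_association_s = 500, t_dissociation_s = 10))
  nb <- mean_occupancy(occ)
  na <- nb$n_bound[occ$phase == "association"]
  expect_true(all(diff(na) >= -1e-12))
  expect_equal(max(na), sub$capacity, tolerance = 1e-6)
})

test_that("stable dsDNA filaments plateau during dissociation", {
  # with ks -> 0, polymers of length >= 2 have no exit channel once the
  # lone-monomer states drain: N(t) flattens instead of decaying
  sub <- get_substrate("dN-50p")
  p <- kinetic_params("dsWT", kd_um = 1.14e-3, kp = 4e-3, ku = 0.1, ks = 0)
  dist <- polymer_distribution(1.14e-3, 0.15)
  occ <- simulate_occupancy(
    build_rate_matrix(sub, p, dist),
    build_rate_matrix(sub, p, zero_distribution(dist)),
    injection_protocol(0.15, 60, 1200))
  nb <- mean_occupancy(occ)
  nd <- nb$n_bound[occ$phase == "dissociation"]
  expect_gt(nd[length(nd)], 0.95 * nd[1])
})

test_that("fast-dissociating short ssDNA shows no accumulation", {
  # unstable nuclei (<= 3 protomers) with large ku: dN-11-sized substrates
  # barely accumulate RAD51
  sub <- get_substrate("dN-11")
  p <- kinetic_params("ssWT", kd_um = 1.14e-3, kp = 2.6e-2, ku = 10,
                      kq = 1e-2, ks = 1e-4)
  curve <- simulate_curve(sub, p, injection_protocol(3, 60, 60))
  expect_lt(max(curve$n_bound), 1e-2 * sub$capacity)
})

test_that("single-reverse model equals ssWT when all reverse rates agree", {
  sub <- get_substrate("dN-17")
  dist <- polymer_distribution(0.05, 3)
  r <- 0.02
  p_ss <- kinetic_params("ssWT", kd_um = 0.05, kp = 0.1, ku = r, kq = r,
                         ks = r)
  p_sr <- kinetic_params("singleReverse", kd_um = 0.05, kp = 0.1, kpr = r)
  expect_equal(build_rate_matrix(sub, p_ss, dist),
               build_rate_matrix(sub, p_sr, dist), tolerance = 1e-14)
})

test_that("matrix-exponential and stiff-integrator propagation agree", {
  truth <- wt_parameter_preset()
  sub <- get_substrate("dN-50")
  dist <- polymer_distribution(truth$kd_um, 0.15)
  Qa <- build_rate_matrix(sub, truth$ss, dist)
  Qd <- build_rate_matrix(sub, truth$ss, zero_distribution(dist))
  proto <- injection_protocol(0.15, 60, 600)
  o_expm <- simulate_occupancy(Qa, Qd, proto, method = "expm")
  o_ode <- simulate_occupancy(Qa, Qd, proto, method = "ode")
  expect_lt(max(abs(o_expm$D - o_ode$D)), 1e-8)
})

test_that("bound-RAD51 composition percentages are well formed", {
  # all mass placed in pentamers
  occ <- structure(
    list(time_s = c(0, 1), phase = c("association", "association"),
         D = matrix(c(0.6, 0, 0, 0, 0, 0.4,
                      0.6, 0, 0, 0, 0, 0.4), ncol = 2),
         capacity = 5L),
    class = "occupancy_series")
  comp <- occupancy_composition(occ, 1)
  expect_equal(comp$percent[comp$length == 5], 100)
  expect_equal(sum(comp$percent), 100)

  # nothing bound: flagged empty result
  occ$D <- matrix(rep(c(1, 0, 0, 0, 0, 0), 2), ncol = 2)
  comp0 <- occupancy_composition(occ, 0)
  expect_identical(nrow(comp0), 0L)
  expect_true(attr(comp0, "empty"))
})

test_that("composition of a simulated WT filament sums to 100", {
  sub <- get_substrate("dN-50")
  truth <- wt_parameter_preset()
  dist <- polymer_distribution(truth$kd_um, 0.15)
  occ <- simulate_occupancy(
    build_rate_matrix(sub, truth$ss, dist),
    build_rate_matrix(sub, truth$ss, zero_distribution(dist)),
    injection_protocol(0.15, 60, 60))
  comp <- occupancy_composition(occ, 60)
  expect_equal(sum(comp$percent), 100, tolerance = 1e-9)
  expect_identical(comp$length, 1:16)
})

test_that("variant/parameter mismatches are rejected", {
  expect_error(kinetic_params("ssWT", kd_um = 1, kp = 1, ku = 1, ks = 1),
               "kq")
  expect_error(kinetic_params("singleReverse", kd_um = 1, kp = 1),
               "kpr")
  expect_error(kinetic_params("ssWT", kd_um = 0, kp = 1, ku = 1, kq = 1,
                              ks = 1), "kd_um")
})
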