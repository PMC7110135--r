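make_sg <- function(time_s, resp, ...) sensorgram(time_s, resp, ...)

test_that("double-referencing removes control and drift signals", {
  tt <- seq(-10, 50, by = 1)
  sig <- ifelse(tt >= 0, 5 * (1 - exp(-0.1 * tt)), 0)

  # experimental == control -> zero trace
  sg <- double_reference(make_sg(tt, sig), make_sg(tt, sig))
  expect_equal(sg$response_ru, rep(0, length(tt)), tolerance = 1e-12)

  # constant control offset removed exactly
  exp_sg <- make_sg(tt, sig + 5)
  ctl_sg <- make_sg(tt, rep(5, length(tt)))
  out <- double_reference(exp_sg, ctl_sg)
  expect_equal(out$response_ru, sig, tolerance = 1e-12)

  # linear drift d(t) = 0.01 t subtracted via the drift trace
  drift <- 0.01 * tt
  out2 <- double_reference(make_sg(tt, sig + drift),
                           make_sg(tt, rep(0, length(tt))),
                           drift = make_sg(tt, drift))
  expect_equal(out2$response_ru, sig, tolerance = 1e-10)

  # idempotent on an already-referenced trace with a zero control
  zero <- make_sg(tt, rep(0, length(tt)))
  again <- double_reference(out, zero)
  expect_equal(again$response_ru, out$response_ru, tolerance = 1e-12)
})

test_that("control traces are resampled onto the experimental time base", {
  tt <- seq(0, 10, by = 1)
  ctl_t <- seq(-1, 11, by = 0.5)
  out <- double_reference(make_sg(tt, tt), make_sg(ctl_t, 0.5 * ctl_t))
  expect_equal(out$response_ru, 0.5 * tt, tolerance = 1e-12)
  expect_error(double_reference(make_sg(tt, tt), make_sg(tt + 100, tt)),
               "overlap")
})

test_that("mass-ratio normalization counts molecules", {
  sg <- sensorgram(0:3, c(0, 10, 20, 40), ligand_level_ru = 10)
  nc <- normalize_sensorgram(sg, m_dna_kda = 18.5) # mass ratio 37/18.5 = 2
  expect_equal(nc$n_bound, c(0, 0.5, 1, 2))

  # saturation arithmetic on the catalogue 50-mer: S at N = 16
  s_sat <- 10 * (37 / 15.682) * 16
  sg2 <- sensorgram(0, s_sat, substrate_name = "dN-50",
                    ligand_level_ru = 10)
  expect_equal(normalize_sensorgram(sg2)$n_bound, 16, tolerance = 1e-12)

  # zero signal stays zero
  sg3 <- sensorgram(0:5, rep(0, 6), ligand_level_ru = 8)
  expect_equal(normalize_sensorgram(sg3, m_dna_kda = 15)$n_bound, rep(0, 6))

  expect_error(normalize_sensorgram(sg, ligand_level_ru = 0,
                                    m_dna_kda = 15), "ligand")
  expect_error(normalize_sensorgram(sg, m_dna_kda = -2), "positive")
})

test_that("normalization round-trips through its inverse", {
  tt <- seq(0, 20, by = 0.5)
  s <- 3 * (1 - exp(-0.2 * tt))
  sg <- sensorgram(tt, s, substrate_name = "dN-17", ligand_level_ru = 12)
  nc <- normalize_sensorgram(sg, m_dna_kda = 5.795)
  back <- denormalize_curve(nc, ligand_level_ru = 12, m_dna_kda = 5.795)
  expect_equal(back$response_ru, s, tolerance = 1e-12)
  # linear in S, inverse-linear in L
  nc2 <- normalize_sensorgram(sensorgram(tt, 2 * s, ligand_level_ru = 12),
                              m_dna_kda = 5.795)
  expect_equal(nc2$n_bound, 2 * nc$n_bound, tolerance = 1e-12)
  nc3 <- normalize_sensorgram(sensorgram(tt, s, ligand_level_ru = 24),
                              m_dna_kda = 5.795)
  expect_equal(nc3$n_bound, nc$n_bound / 2, tolerance = 1e-12)
})

test_that("sensorgram CSV dialect round-trips data and metadata", {
  tt <- seq(0, 30, by = 2)
  sg <- sensorgram(tt, sin(tt), substrate_name = "dN-8",
                   concentration_um = 3, ligand_level_ru = 11.5,
                   t_association_s = 60, t_dissociation_s = 1200,
                   flow_cell = "Fc2")
  path <- tempfile(fileext = ".csv")
  write_sensorgram(sg, path)
  rt <- read_sensorgram(path)
  expect_equal(rt$time_s, sg$time_s)
  expect_equal(rt$response_ru, sg$response_ru, tolerance = 1e-12)
  expect_identical(attr(rt, "substrate_name"), "dN-8")
  expect_equal(attr(rt, "concentration_um"), 3)
  expect_equal(attr(rt, "ligand_level_ru"), 11.5)
  expect_identical(attr(rt, "flow_cell"), "Fc2")
})

test_that("sensorgram constructor enforces a monotone time base", {
  expect_error(sensorgram(c(0, 1, 1), c(0, 0, 0)), "increasing")
  expect_error(sensorgram(c(0, 1), c(0, 0, 0)))
})
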