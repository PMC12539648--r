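# Constituent energies, mixture stress and linearized stiffness.

test_that("neo-Hookean energy: anchors, zero state and linearity in ce", {
  expect_equal(neo_hookean_energy(3, 42.03), 0)
  # I1 from the baseline elastin deposition stretches 1.74, 2.24, 1/(1.74*2.24)
  I1 <- 1.74^2 + 2.24^2 + (1 / (1.74 * 2.24))^2
  expect_equal(neo_hookean_energy(I1, 42.03), 107.4, tolerance = 1e-3)
  expect_equal(neo_hookean_energy(5, 2 * 42.03),
               2 * neo_hookean_energy(5, 42.03))
  # convention flag: without the half factor the energy doubles
  expect_equal(neo_hookean_energy(I1, 42.03, half = FALSE),
               2 * neo_hookean_energy(I1, 42.03))
  expect_error(neo_hookean_energy(NaN, 42.03))
  expect_error(neo_hookean_energy(2.5, 42.03), "I1 < 3")
})

test_that("Fung fibre energy: anchors, guards and monotonicity", {
  expect_equal(fung_fiber_energy(1, 665.6, 2.14), 0)
  expect_equal(fung_fiber_energy(1.25^2, 665.6, 2.14), 75.28, tolerance = 2e-4)
  expect_equal(fung_fiber_energy(1.19^2, 1.26, 30.0), 1.882, tolerance = 5e-4)
  expect_error(fung_fiber_energy(0, 1, 1))
  expect_error(fung_fiber_energy(40, 665.6, 2.14), "non-physical")
  # strictly increasing in |I4 - 1| (symmetric form) and in c2 for I4 != 1
  d <- seq(0.05, 0.45, by = 0.1)
  up <- fung_fiber_energy(1 + d, 665.6, 2.14)
  dn <- fung_fiber_energy(1 - d, 665.6, 2.14)
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(dn) > 0))
  expect_true(all(fung_fiber_energy(1.3, 665.6, c(1, 2, 4, 8)) ==
                    cummax(fung_fiber_energy(1.3, 665.6, c(1, 2, 4, 8)))))
})

test_that("mixture energy: zero-deformation identity and additivity", {
  # all deposition stretches 1: W = 0 and stress = 0 at P = 0
  par1 <- vessel_params(G_theta_e = 1, G_z_e = 1, Gm = 1 + 1e-12,
                        Gc = 1 + 1e-12)
  st <- vessel_state(par1, pressure = 0)
  expect_equal(mixture_stored_energy(st), 0, tolerance = 1e-15)
  expect_equal(unname(mixture_cauchy_stress(st, pressure = 0)), c(0, 0, 0),
               tolerance = 1e-9)
  # additivity: removing a constituent removes exactly its contribution
  par <- vessel_params()
  st <- vessel_state(par, lt = 0.97, lz = 1, pressure = 100)
  W_full <- mixture_stored_energy(st)
  # per-constituent energies recomputed from the formulas
  I1 <- (par$G_r_e / 0.97)^2 + (0.97 * par$G_theta_e)^2 + par$G_z_e^2
  We <- neo_hookean_energy(I1, par$ce)
  Wm <- fung_fiber_energy((0.97 * par$Gm)^2, par$c1m, par$c2m)
  ang <- c(pi / 2, 0, par$alpha0, par$alpha0)
  bfr <- c(par$beta_theta, par$beta_z, par$beta_d / 2, par$beta_d / 2)
  I4c <- par$Gc^2 * (0.97^2 * sin(ang)^2 + cos(ang)^2)
  Wc <- sum(bfr * fung_fiber_energy(I4c, par$c1c, par$c2c))
  expect_equal(W_full,
               par$phi_e * We + par$phi_m * Wm + par$phi_c * Wc,
               tolerance = 1e-12)
})

test_that("baseline vessel unloaded to 80 mmHg reproduces the stored-energy
           and stiffness anchors", {
  b <- test_baseline()
  dia <- solve_elastic_state(b$state, 80)
  expect_equal(mixture_stored_energy(dia), 51.9, tolerance = 0.02)
  cc <- small_on_large_stiffness(dia)
  expect_gt(cc[["c_tttt"]], 1.4)
  expect_lt(cc[["c_tttt"]], 1.65)
  expect_gt(cc[["c_zzzz"]], 0)
})

test_that("stress equals the centred finite difference of stored energy for
           isochoric biaxial perturbations", {
  par <- vessel_params()
  for (lt in c(0.96, 1, 1.05)) {
    for (lz in c(0.98, 1.02)) {
      st <- vessel_state(par, lt = lt, lz = lz, pressure = 100)
      sig <- mixture_cauchy_stress(st)
      dW_t <- fd_central(function(l)
        mixture_stored_energy(vessel_state(par, lt = l, lz = lz,
                                           pressure = 100)), lt)
      dW_z <- fd_central(function(l)
        mixture_stored_energy(vessel_state(par, lt = lt, lz = l,
                                           pressure = 100)), lz)
      expect_equal(sig[["sig_tt"]] - sig[["sig_rr"]], lt * dW_t,
                   tolerance = 1e-5)
      expect_equal(sig[["sig_zz"]] - sig[["sig_rr"]], lz * dW_z,
                   tolerance = 1e-5)
    }
  }
})

test_that("analytic small-on-large stiffness matches the stress-stretch
           finite-difference oracle", {
  par <- vessel_params()
  b <- test_baseline()
  states <- list(vessel_state(par, lt = 0.96, pressure = 80),
                 vessel_state(par, lt = 1, pressure = 120),
                 solve_elastic_state(b$state, 80))
  for (st in states) {
    cc <- small_on_large_stiffness(st)
    fd_t <- fd_central(function(l) {
      s <- vessel_state(par, lt = l, lz = st$lz, pressure = st$pressure,
                        composition = st$comp)
      mixture_cauchy_stress(s)[["sig_tt"]]
    }, st$lt) * st$lt / 1000
    fd_z <- fd_central(function(l) {
      s <- vessel_state(par, lt = st$lt, lz = l, pressure = st$pressure,
                        composition = st$comp)
      mixture_cauchy_stress(s)[["sig_zz"]]
    }, st$lz) * st$lz / 1000
    expect_equal(cc[["c_tttt"]], fd_t, tolerance = 1e-4)
    expect_equal(cc[["c_zzzz"]], fd_z, tolerance = 1e-4)
  }
})

test_that("pure neo-Hookean mixture stiffness matches the closed form", {
  par <- vessel_params(c1m_kPa = 0, c1c_kPa = 0)
  st <- vessel_state(par, lt = 1.02, lz = 0.99, pressure = 90)
  cc <- small_on_large_stiffness(st)
  lre2 <- (par$G_r_e / (1.02 * 0.99))^2
  closed_t <- (par$phi_e * 2 * par$ce * (1.02 * par$G_theta_e)^2 +
                 par$phi_e * 2 * par$ce * lre2) / 1000
  closed_z <- (par$phi_e * 2 * par$ce * (0.99 * par$G_z_e)^2 +
                 par$phi_e * 2 * par$ce * lre2) / 1000
  expect_equal(cc[["c_tttt"]], closed_t, tolerance = 1e-12)
  expect_equal(cc[["c_zzzz"]], closed_z, tolerance = 1e-12)
})

test_that("a circumferential fibre family loads only the circumferential
           stress, and stiffness grows with pressure", {
  # orientation selectivity: smooth muscle (90 deg) contributes to sig_tt only
  par_m <- vessel_params(c1c_kPa = 0, ce_kPa = 0)
  st <- vessel_state(par_m, lt = 1.01, pressure = 0)
  sig <- mixture_cauchy_stress(st, pressure = 0)
  expect_gt(sig[["sig_tt"]], 0)
  expect_equal(sig[["sig_zz"]], 0, tolerance = 1e-12)
  # exponential fibres: circumferential stiffness increases from diastole to
  # systole at fixed composition
  b <- test_baseline()
  cs <- vapply(c(80, 100, 120), function(P) {
    small_on_large_stiffness(solve_elastic_state(b$state, P))[["c_tttt"]]
  }, numeric(1))
  expect_true(all(diff(cs) > 0))
})
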