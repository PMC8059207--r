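# Post-Zimm / Flory-Huggins theory: chain construction, free energy,
# collapse solver, chemical potentials, binodal.

test_that("dna_chain derives parameters with the documented scalings", {
  ch1 <- dna_chain(1000)
  ch2 <- dna_chain(2000)
  # N proportional to M proportional to bp
  expect_equal(ch2$segment_number_N, 2 * ch1$segment_number_N)
  expect_equal(ch1$molecular_weight, 1000 * 650)

  # <h0^2> ~ M^{8/7} and omega ~ M^{-5/7}, checked against the power
  # laws evaluated independently
  a <- dna_chain(200)
  b <- dna_chain(48500)
  ratio <- 48500 / 200
  expect_equal(b$h0_squared / a$h0_squared, ratio^(8 / 7), tolerance = 1e-12)
  expect_equal(a$omega / b$omega, ratio^(5 / 7), tolerance = 1e-12)

  expect_true(all(unlist(ch1[c("segment_number_N", "omega", "h0_squared")]) > 0))
  expect_error(dna_chain(0), "positive")
  expect_error(dna_chain(-5), "positive")
})

test_that("B3 default stays positive where the series grouping fails", {
  chis <- seq(0.5, 2, by = 0.1)
  expect_true(all(virial_B3_regularized(chis, 10) > 0))
  # the series grouping goes negative just above chi ~ 0.52 at q = 10,
  # which would unbound the free energy; that is why it is not default
  expect_true(virial_B3_series(0.7, 10) < 0)
  sv <- solvent_condition(0.7)
  expect_equal(sv$B2, 0.5 - 0.7)
  expect_equal(sv$B3, virial_B3_regularized(0.7, 10))
})

test_that("intensive free energy has the right limits and matches a re-derivation", {
  ch <- dna_chain(2500)
  sv <- solvent_condition(0.8)
  # pure solvent
  expect_identical(free_energy_intensive(0, 1, ch, sv), 0)

  # with both virial terms zeroed and alpha = 1, only the mixing terms
  # plus the residual phi*(chi-1) contact term remain
  sv0 <- solvent_condition(0.5, B3_fun = function(chi, q) 0)  # B2 = 0 too
  phi <- c(0.05, 0.3, 0.7)
  N <- ch$segment_number_N
  mixing <- (1 - phi) * log(1 - phi) + phi / N * log(phi) +
    0.5 * phi * (1 - phi)
  expect_equal(free_energy_intensive(phi, 1, ch, sv0),
               mixing + phi * (0.5 - 1), tolerance = 1e-12)

  # random states against an independent re-typing of the formula
  set.seed(42)
  for (i in 1:25) {
    chx <- dna_chain(10^runif(1, 2, 6))
    svx <- solvent_condition(runif(1, 0.3, 1.5))
    p <- runif(1, 1e-6, 0.95)
    al <- runif(1, 0.05, 1.5)
    expect_equal(free_energy_intensive(p, al, chx, svx),
                 free_energy_retyped(p, al, chx$segment_number_N, chx$omega,
                                     svx$chi, svx$B2, svx$B3),
                 tolerance = 1e-12)
  }

  expect_error(free_energy_intensive(1, 1, ch, sv), "phi")
  expect_error(free_energy_intensive(0.5, 0, ch, sv), "alpha")
})

test_that("stationarity residual matches direct arithmetic and locates extrema", {
  ch <- dna_chain(2500)
  sv0 <- solvent_condition(0.5, B3_fun = function(chi, q) 0)
  expect_equal(alpha_stationarity_residual(1, ch, sv0), 0)
  expect_equal(alpha_stationarity_residual(0.5, ch, sv0),
               3 * (0.5^8 - 0.5^6))
  expect_lt(alpha_stationarity_residual(0.5, ch, sv0), 0)

  # the residual changes sign across the grid-located internal minimum
  sv <- solvent_condition(0.75)
  a_star <- grid_alpha_oracle(ch, sv)
  res <- alpha_stationarity_residual(c(a_star - 2e-4, a_star + 2e-4), ch, sv)
  expect_lt(res[1] * res[2], 0)
})

test_that("expansion_alpha equals the grid-search oracle and orders by length", {
  ch <- dna_chain(2500)
  sv0 <- solvent_condition(0.5, B3_fun = function(chi, q) 0)
  # B3 = 0 triggers the documented unboundedness warning
  expect_warning(a_theta <- expansion_alpha(ch, sv0), "unbounded")
  expect_equal(a_theta, 1, tolerance = 1e-9)

  # longer DNA collapses more easily: alpha(N2) <= alpha(N1) at fixed chi
  for (chi in c(0.6, 0.7, 0.9)) {
    a_short <- expansion_alpha(dna_chain(1000), solvent_condition(chi))
    a_long <- expansion_alpha(dna_chain(48500), solvent_condition(chi))
    expect_lte(a_long, a_short + 1e-12)
  }

  # alpha non-increasing in chi for a fixed chain
  chis <- seq(0.5, 2, length.out = 31)
  alphas <- vapply(chis, function(chi) {
    expansion_alpha(ch, solvent_condition(chi))
  }, numeric(1))
  expect_true(all(diff(alphas) <= 1e-9))

  # spot-check the grid oracle at a few (length, chi) points; the full
  # sweep lives in the acceptance suite
  set.seed(7)
  for (i in 1:10) {
    chx <- dna_chain(10^runif(1, 2.3, 4.7))
    svx <- solvent_condition(runif(1, 0.55, 1.5))
    expect_lt(abs(expansion_alpha(chx, svx) - grid_alpha_oracle(chx, svx)),
              1.1e-4)
  }
})

test_that("chemical potentials obey limits and match finite differences", {
  ch <- dna_chain(2500)
  sv <- solvent_condition(0.7)
  mu <- chemical_potentials(1e-12, 1, ch, sv)
  expect_equal(mu$mu_solvent, 0, tolerance = 1e-11)
  expect_error(chemical_potentials(0, 1, ch, sv), "phi")
  expect_error(chemical_potentials(1, 1, ch, sv), "phi")

  set.seed(3)
  for (i in 1:20) {
    chx <- dna_chain(10^runif(1, 2, 5))
    svx <- solvent_condition(runif(1, 0.4, 1.2))
    phi <- runif(1, 0.05, 0.9)
    al <- runif(1, 0.3, 1.4)
    mu <- chemical_potentials(phi, al, chx, svx)
    N <- chx$segment_number_N
    nS <- N * (1 - phi) / phi       # per single DNA molecule
    fdD <- fd_mu(function(x) extensive_G(x, nS, al, chx, svx), 1, 1e-5)
    fdS <- fd_mu(function(x) extensive_G(1, x, al, chx, svx), nS, nS * 1e-5)
    expect_equal(fdD, mu$mu_dna, tolerance = 1e-6)
    expect_equal(fdS, mu$mu_solvent, tolerance = 1e-6)
  }

  # mu_DNA non-monotonic in phi above the critical point (lambda DNA)
  chl <- dna_chain(48500)
  a1 <- expansion_alpha(chl, sv)
  phis <- 10^seq(-10, -0.05, length.out = 300)
  mu_d <- chemical_potentials(phis, a1, chl, sv)$mu_dna
  expect_true(any(diff(sign(diff(mu_d))) != 0))
})

test_that("binodal points satisfy equality, ordering and unit conversion", {
  for (bp in c(200, 2500)) {
    b <- binodal_point(dna_chain(bp), 0.7)
    expect_true(b$coexists)
    expect_lt(abs(b$residual_mu_solvent), 1e-8)
    expect_lt(abs(b$residual_mu_dna), 1e-8)
    expect_true(b$phi_dilute > 0 && b$phi_dilute < b$phi_dense)
    expect_lt(b$phi_dense, 1)
    expect_equal(b$c_dilute, b$phi_dilute * 1.8)
    # conversion roundtrip is the identity
    expect_equal(concentration_to_phi(phi_to_concentration(b$phi_dense)),
                 b$phi_dense, tolerance = 4 * .Machine$double.eps)
  }
  # theta solvent: no coexistence for any finite chain, not an error
  b0 <- binodal_point(dna_chain(2500), 0.5)
  expect_false(b0$coexists)
  expect_true(is.na(b0$phi_dilute))

  # dense-phase alpha convention switch
  bt <- binodal_point(dna_chain(2500), 0.7, alpha_dense = "theta")
  bu <- binodal_point(dna_chain(2500), 0.7, alpha_dense = "unity")
  expect_equal(bu$alpha_dense, 1)
  expect_equal(bt$c_dilute, bu$c_dilute, tolerance = 1e-3)
})

test_that("phase_diagram assembles binodal and collapse information", {
  expect_error(phase_diagram(dna_chain(200), numeric(0)), "non-empty")
  expect_error(phase_diagram(dna_chain(200), c(0.7, 0.6)), "sorted")

  pd <- phase_diagram(dna_chain(2500), seq(0.4, 1.0, by = 0.05))
  tab <- pd$table
  expect_false(any(tab$coexists[tab$chi <= 0.5]))
  expect_true(any(tab$coexists[tab$chi >= 0.7]))
  # collapse chi present and consistent with the alpha column
  expect_false(is.na(pd$collapse_chi))
  expect_lt(tab$alpha_dilute[tab$chi == pd$collapse_chi], 0.5)

  # sub-critical grid: no coexistence anywhere
  pd0 <- phase_diagram(dna_chain(200), seq(0.40, 0.50, by = 0.02))
  expect_false(any(pd0$table$coexists))
  expect_true(is.na(pd0$collapse_chi))

  # collapse chi decreases with chain length
  cc <- vapply(c(200, 2500, 48500), function(bp) {
    phase_diagram(dna_chain(bp), seq(0.5, 1.5, by = 0.02))$collapse_chi
  }, numeric(1))
  expect_true(all(diff(cc) < 0))
})
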