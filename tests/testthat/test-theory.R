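# Closed-form theory engine: blob scaling, insertion free energy,
# partition coefficients, composition conversion, recruitment.

test_that("correlation length reproduces the published condensate values", {
  # LAF-1-like condensate (phi = 3.6%) and typical condensate (phi = 5%)
  expect_equal(correlation_length(0.036), 5.24, tolerance = 0.01)
  expect_equal(correlation_length(0.05), 4.1, tolerance = 0.01)
  # identity limit: phi -> 1 with c = d = 1
  expect_equal(correlation_length(1 - 1e-12, d = 1, c = 1), 1,
               tolerance = 1e-9)
  # strictly decreasing in phi
  phis <- seq(0.01, 0.5, length.out = 40)
  expect_true(all(diff(correlation_length(phis)) < 0))
  expect_error(polymer_solution(0), "phi")
  expect_error(polymer_solution(1.2), "phi")
})

test_that("pressure route to the correlation length matches the blob form", {
  # the extreme pressures of the homogeneous-solution study
  expect_equal(correlation_length_from_pressure(0.25e6), 2.79,
               tolerance = 0.005)
  expect_equal(correlation_length_from_pressure(0.024e6), 6.10,
               tolerance = 0.005)
  # cube-root scaling: 8x the pressure halves xi
  xi1 <- correlation_length_from_pressure(1e5)
  expect_equal(correlation_length_from_pressure(8e5), xi1 / 2,
               tolerance = 1e-12)
  expect_error(correlation_length_from_pressure(-1), "positive")
  expect_error(correlation_length_from_pressure(0), "positive")
})

test_that("unified insertion free energy reproduces the worked examples", {
  m <- insertion_model()
  # dextran probes in a LAF-1-like condensate (printed xi = 5.24 nm)
  dF <- insertion_free_energy(c(1.9, 6.5, 8.9), 5.24, 0.036, m)
  expect_equal(dF, c(2.1, 17, 29), tolerance = 0.02)
  # half-blob probe, volume-reduction term neglected
  expect_equal(insertion_free_energy(0.5, 1, 0, m), 3.5, tolerance = 0.01)
  # zero-radius, zero-phi probe costs nothing
  expect_identical(insertion_free_energy(0, 3, 0, m), 0)
  # zero-radius cost is exactly the volume-reduction term
  expect_equal(insertion_free_energy(0, 3, 0.3, m), -log(1 - 0.3))
  # monotone increasing in R and phi
  R <- seq(0, 8, length.out = 50)
  expect_true(all(diff(insertion_free_energy(R, 4, 0.05, m)) > 0))
  ph <- seq(0, 0.4, length.out = 30)
  expect_true(all(diff(insertion_free_energy(2, 4, ph, m)) > 0))
  expect_error(insertion_free_energy(2, 4, 1, m), "phi")
  expect_error(insertion_free_energy(-1, 4, 0.1, m), "R")
})

test_that("insertion free energy attains the two scaling limbs", {
  m <- insertion_model()
  slope <- function(x1, x2, xi = 1) {
    f <- insertion_free_energy(c(x1, x2) * xi, xi, 0, m)
    (log(f[2]) - log(f[1])) / (log(x2) - log(x1))
  }
  expect_equal(slope(1e-5, 2e-5), 3 - 1 / 0.588, tolerance = 1e-3)
  expect_equal(slope(1e4, 2e4), 2, tolerance = 1e-3)
})

test_that("partition coefficient is the Boltzmann factor of the barrier", {
  expect_equal(partition_coefficient(3.5), 0.03, tolerance = 0.01)
  expect_equal(partition_coefficient(3.4), 0.033, tolerance = 0.015)
  expect_identical(partition_coefficient(0), 1)
  dF <- seq(0, 10, length.out = 20)
  p <- partition_coefficient(dF)
  expect_true(all(diff(p) < 0) && all(p > 0 & p <= 1))
  expect_error(partition_coefficient(NaN), "finite")
})

test_that("full prediction chain reproduces the typical-condensate numbers", {
  pred <- predict_partitioning(2, phi = 0.05)
  expect_equal(pred$deltaF_kBT, 3.4, tolerance = 0.02)
  expect_equal(pred$P, 0.033, tolerance = 0.02)
})

test_that("composition conversion gives the direct arithmetic result", {
  # molar route: 2.6 mM scaffold, 250 disordered residues, r = 0.3 nm
  expect_equal(
    phi_from_composition(molar_mM = 2.6, residues_per_scaffold = 250),
    0.0443, tolerance = 0.002)
  # mass route: 250 g/L, 40% IDR content, 110 g/mol residues
  expect_equal(
    phi_from_composition(mass_gL = 250, idr_mass_fraction = 0.4),
    0.0619, tolerance = 0.002)
  expect_identical(
    phi_from_composition(molar_mM = 0, residues_per_scaffold = 10), 0)
  # disagreement with an independently known phi is flagged, not silent
  expect_warning(
    phi_from_composition(molar_mM = 2.6, residues_per_scaffold = 250,
                         target_phi = 0.036), "differs")
  expect_error(phi_from_composition(), "exactly one")
  expect_error(phi_from_composition(molar_mM = 1, residues_per_scaffold = 10,
                                    mass_gL = 1), "exactly one")
  expect_error(phi_from_composition(molar_mM = 1e6,
                                    residues_per_scaffold = 1e3),
               "inconsistent")
})

test_that("recruitment free energy balances binding against exclusion", {
  expect_identical(recruitment_free_energy(0, 1, 3), 3)
  expect_identical(recruitment_free_energy(5, 1, 3), -2)
  # two independent binding-site types add their rho/KD terms
  expect_identical(recruitment_free_energy(c(2, 3), c(1, 1), 4), -1)
  expect_error(recruitment_free_energy(1, 0, 1), "KD")
  expect_error(recruitment_free_energy(-1, 1, 1), "rho")
})

test_that("finite-valency recruitment sum converges to the limiting form", {
  # strong binding (KD << 1/Omega), valency cap far above occupancy
  rho <- 0.05; KD <- 0.01; Omega <- 0.1
  exact <- recruitment_free_energy(rho, KD, 2, method = "exact",
                                   Omega = Omega, nmax = 200)
  limiting <- recruitment_free_energy(rho, KD, 2)
  # exact = rho*(Omega - 1/KD) + dF0 at large nmax
  expect_equal(exact, rho * (Omega - 1 / KD) + 2, tolerance = 1e-10)
  expect_equal(exact, limiting + rho * Omega, tolerance = 1e-10)
  # a binding-saturating cap weakens recruitment (raises the free energy)
  capped <- recruitment_free_energy(rho, KD, 2, method = "exact",
                                    Omega = Omega, nmax = 2)
  expect_gt(capped, exact)
})

test_that("large-intruder limit has surface-area and phi^1.54 scaling", {
  sp <- polymer_solution(0.05)
  # quadrupling with radius doubling
  expect_equal(large_intruder_limit(40, sp) / large_intruder_limit(20, sp),
               4, tolerance = 1e-12)
  # phi doubling: exponent 2*nu/(3*nu - 1) = 1.539
  r <- large_intruder_limit(50, polymer_solution(0.10)) /
    large_intruder_limit(50, polymer_solution(0.05))
  expect_equal(r, 2^(2 * 0.588 / (3 * 0.588 - 1)), tolerance = 1e-12)
  expect_equal(r, 2.906, tolerance = 1e-3)
  # surface term dominates the polymer-entropy contribution asymptotically:
  # the relative gap shrinks with R/xi and is below 5% by R/xi = 100
  m <- insertion_model()
  gap <- function(x) {
    full <- insertion_free_energy(x, 1, 0, m)
    (full - m$a2 * x^2) / full
  }
  expect_true(gap(100) < gap(10))
  expect_lt(gap(100), 0.05)
})
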