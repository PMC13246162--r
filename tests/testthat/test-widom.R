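# Hard-sphere Widom insertion estimator against analytic and brute-force
# Monte Carlo oracles.

test_that("empty box costs nothing at any radius", {
  tr <- generate_fixture("empty_box", box = c(10, 10, 10))
  res <- insert_hard_spheres(tr, radii = c(0, 1, 3), grid = c(20, 20, 20))
  expect_equal(res$F, c(0, 0, 0))
  expect_equal(res$acceptance, c(1, 1, 1))
})

test_that("single-sphere fixture matches the analytic overlap volume", {
  # one bead of radius 1 nm centred in a 10 nm box; probe R = 1 nm is
  # rejected inside a sphere of radius 2 nm
  tr <- generate_fixture("single_sphere", box = c(10, 10, 10), radius = 1)
  res <- insert_hard_spheres(tr, radii = 1, grid = c(100, 100, 100))
  F_exact <- -log(1 - (4 / 3) * pi * 2^3 / 1000)
  expect_equal(res$F, F_exact, tolerance = 0.02)
  expect_equal(res$F, 0.0341, tolerance = 0.02)
  # brute-force Monte Carlo oracle agrees within binomial error
  p_mc <- mc_insertion_oracle(tr$frames[[1]], tr$box, rC = 1, R = 1,
                              npts = 4e4, seed = 2)
  se <- sqrt(p_mc * (1 - p_mc) / 4e4)
  expect_lt(abs(res$acceptance - p_mc), 4 * se)
})

test_that("zero-radius insertion recovers the covered volume fraction", {
  # non-overlapping hard-sphere gas: the R = 0 acceptance is exactly 1 - phi
  tr <- generate_fixture("hs_gas", box = c(20, 20, 20), radius = 1,
                         phi = 0.05, nframes = 3, seed = 4)
  nb <- nrow(tr$frames[[1]])
  phi_true <- nb * (4 / 3) * pi / 8000
  expect_equal(phi_true, 0.05, tolerance = 0.01)
  res <- insert_hard_spheres(tr, radii = 0, grid = c(80, 80, 80))
  expect_equal(res$F, -log(1 - phi_true), tolerance = 0.02)
})

test_that("grid and random sampling agree as both refine", {
  tr <- generate_fixture("hs_gas", box = c(15, 15, 15), radius = 1,
                         phi = 0.08, nframes = 4, seed = 6)
  rg <- insert_hard_spheres(tr, radii = c(0.5, 1), grid = c(60, 60, 60))
  rr <- insert_hard_spheres(tr, radii = c(0.5, 1), grid = NULL,
                            nrandom = 2e5, seed = 8)
  for (k in 1:2) {
    se <- sqrt(rg$se[k]^2 + rr$se[k]^2 +
                 rr$acceptance[k] * (1 - rr$acceptance[k]) / 8e5 /
                   rr$acceptance[k]^2)
    expect_lt(abs(rg$F[k] - rr$F[k]), 4 * se + 0.01)
  }
})

test_that("insertion free energy is non-decreasing in probe radius", {
  for (seed in 1:3) {
    tr <- generate_fixture("hs_gas", box = c(15, 15, 15), radius = 0.8,
                           phi = 0.06, nframes = 2, seed = seed)
    res <- insert_hard_spheres(tr, radii = c(0, 0.3, 0.8, 1.5, 2.5),
                               grid = c(40, 40, 40))
    ok <- !res$lower_bound
    expect_true(all(diff(res$F[ok]) >= 0))
  }
})

test_that("impossible insertions are flagged as lower bounds", {
  tr <- generate_fixture("hs_gas", box = c(12, 12, 12), radius = 1,
                         phi = 0.1, nframes = 1, seed = 3)
  res <- insert_hard_spheres(tr, radii = c(0.5, 25), grid = c(30, 30, 30))
  expect_false(res$lower_bound[1])
  expect_true(res$lower_bound[2])
  expect_equal(res$F[2], log(27000))  # -ln(1/n): bound, not an estimate
})

test_that("insertion region restricts probe centres to the slab", {
  # beads confined to the central slab; probing only the empty edge region
  # must find free volume everywhere
  tr <- generate_fixture("ideal_slab", box = c(40, 10, 10), n = 200,
                         slab_halfwidth = 5, seed = 5)
  res <- insert_hard_spheres(tr, radii = 0.2, grid = c(20, 20, 20),
                             region = c(0, 8))
  expect_equal(res$acceptance, 1)
  expect_error(insert_hard_spheres(tr, radii = 0.2, region = c(-5, 80)),
               "region")
})

test_that("pressure-volume correction subtracts Pi V_probe", {
  # 0.25 MPa on a 2.48-nm probe at 300 K
  corr <- 0.25e6 * (4 / 3) * pi * (2.48e-9)^3 / (1.380649e-23 * 300)
  expect_equal(corr, 3.856, tolerance = 1e-3)
  expect_equal(pv_correction(10, 2.48, 0.25e6), 10 - corr)
  expect_equal(pv_correction(5, 3, 0), 5)
  expect_equal(pv_correction(5, 0, 1e6), 5)
  # widom_result method adds the deltaF column
  tr <- generate_fixture("single_sphere", box = c(10, 10, 10))
  res <- insert_hard_spheres(tr, radii = c(1, 2), grid = c(20, 20, 20))
  res <- pv_correction(res, pressure = 0.1e6)
  expect_true(all(res$deltaF <= res$F))
})

test_that("partition coefficient follows from the dense-dilute difference", {
  expect_equal(partition_from_widom(2, 2), 1)
  expect_equal(partition_from_widom(log(14), 0), 1 / 14, tolerance = 1e-12)
  expect_equal(partition_from_widom(0.5, 1.5), exp(1))
  expect_error(partition_from_widom(Inf, 0), "finite")
})
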