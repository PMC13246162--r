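# Simulator physics: potential identities, force consistency, integrator
# determinism, thermostat temperature, free diffusion, ideal-gas pressure,
# energy conservation, self-avoiding chain statistics.

test_that("pair potentials satisfy their endpoint identities", {
  # WCA: epsilon at sigma, zero at the 2^(1/6) sigma cutoff
  expect_equal(u_wca(1, eps = 1, sigma = 1), 1)
  expect_equal(u_wca(2^(1 / 6), eps = 1, sigma = 1), 0)
  expect_equal(u_wca(2, eps = 3, sigma = 2), 3)
  # sticker attraction: -U0 at contact, zero at the range r0
  expect_equal(u_soft(1e-12, U0 = 18.8, r0 = 0.3), -18.8, tolerance = 1e-6)
  expect_equal(u_soft(0.3, U0 = 18.8, r0 = 0.3), 0)
  # FENE: zero at zero extension, divergence guarded
  expect_equal(u_fene(1e-12), 0, tolerance = 1e-10)
  expect_error(u_fene(14.03), "overextended")
  # client attraction: -eps at the well centre, zero at the edges
  expect_equal(u_client(1.5, eps = 5), -5)
  expect_equal(u_client(1.2, eps = 5), 0)
  expect_equal(u_client(1.8, eps = 5), 0)
})

test_that("compiled energies match the reference potentials pair by pair", {
  ff <- cg_forcefield("compact", client_eps = 4)
  cases <- list(
    # C-C spacers: WCA with sigma = 2
    list(types = c(3, 3), r = seq(1.9, 2.4, by = 0.05),
         ref = function(r) u_wca(r, 1, 2)),
    # A-B stickers: soft attraction only (scale 1)
    list(types = c(1, 2), r = seq(0.05, 0.45, by = 0.05),
         ref = function(r) u_soft(r, 18.8, 0.3) + u_wca(r, 0, 1) * 0),
    # A-A stickers: WCA with sigma = 0.6
    list(types = c(1, 1), r = seq(0.55, 0.75, by = 0.02),
         ref = function(r) u_wca(r, 1, 0.6)),
    # A-D client attraction (no WCA between stickers and particles)
    list(types = c(1, 4), r = seq(1.25, 1.95, by = 0.1),
         ref = function(r) u_client(r, 4, 1.5, 0.3)))
  for (cs in cases) {
    for (r in cs$r) {
      sys <- two_bead_system(cs$types, r)
      expect_equal(potential_energy(sys, ff)$pe, cs$ref(r),
                   tolerance = 1e-10)
    }
  }
  # bonded beads: bond term only, nonbonded excluded (1-2 convention)
  bonds <- matrix(c(1L, 2L, 1L), 1, 3)
  for (r in c(1.0, 3.0, 7.0)) {
    sys <- two_bead_system(c(3, 3), r, bonds = bonds)
    expect_equal(potential_energy(sys, ff)$pe, u_fene(r, 0.129, 14.03),
                 tolerance = 1e-10)
  }
  ffi <- cg_forcefield("idr")
  for (r in c(0.3, 0.38, 0.5)) {
    sys <- two_bead_system(c(3, 3), r, bonds = bonds)
    expect_equal(potential_energy(sys, ffi)$pe, u_harmonic(r, 692, 0.38),
                 tolerance = 1e-10)
  }
})

test_that("forces are the exact negative gradient of each term", {
  ff <- cg_forcefield("compact", client_eps = 4)
  cases <- list(
    list(types = c(3, 3), r = 2.1, dref = function(r) du_wca(r, 1, 2)),
    list(types = c(1, 2), r = 0.2, dref = function(r) du_soft(r, 18.8, 0.3)),
    list(types = c(1, 4), r = 1.6,
         dref = function(r) du_client(r, 4, 1.5, 0.3)))
  for (cs in cases) {
    sys <- two_bead_system(cs$types, cs$r)
    f <- potential_energy(sys, ff)$forces
    # bead 2 sits at larger x: force on it is -dU/dr along +x
    expect_equal(f[2, 1], -cs$dref(cs$r), tolerance = 1e-10)
    expect_equal(f[1, 1], cs$dref(cs$r), tolerance = 1e-10)
    expect_equal(f[, 2:3], matrix(0, 2, 2))
  }
  bonds <- matrix(c(1L, 2L, 1L), 1, 3)
  sys <- two_bead_system(c(3, 3), 5, bonds = bonds)
  f <- potential_energy(sys, ff)$forces
  expect_equal(f[2, 1], -du_fene(5, 0.129, 14.03), tolerance = 1e-10)
})

test_that("total forces agree with finite differences on a many-body state", {
  tr <- generate_fixture("hs_gas", box = c(10, 10, 10), radius = 0.3,
                         phi = 0.05, seed = 12)
  ff <- cg_forcefield("idr")
  sys <- structure(list(pos = tr$frames[[1]],
                        vel = matrix(0, nrow(tr$frames[[1]]), 3),
                        type = tr$type, mol = tr$mol,
                        is_polymer = tr$is_polymer,
                        bonds = matrix(integer(0), 0, 3),
                        box = tr$box), class = "cg_system")
  out <- potential_energy(sys, ff)
  h <- 1e-6
  active <- which(abs(out$forces) > 1e-3, arr.ind = TRUE)
  expect_gt(nrow(active), 0)
  for (k in seq_len(min(12, nrow(active)))) {
    i <- active[k, 1]; d <- active[k, 2]
    sp <- sys; sp$pos[i, d] <- sp$pos[i, d] + h
    sm <- sys; sm$pos[i, d] <- sm$pos[i, d] - h
    fd <- -(potential_energy(sp, ff)$pe - potential_energy(sm, ff)$pe) /
      (2 * h)
    expect_equal(fd, out$forces[i, d],
                 tolerance = 1e-6 * max(1, abs(out$forces[i, d])))
  }
})

test_that("cell-list and all-pairs evaluations agree exactly", {
  topo <- cg_topology("compact_spacer", n_polymers = 4, n_particles = 6)
  ff <- default_forcefield(topo, client_eps = 3)
  cfg <- sim_config(box = c(30, 14, 14), seed = 5)
  sys <- build_system(topo, ff, cfg, relax_steps = 400)
  a <- potential_energy(sys, ff, method = "cells")
  b <- potential_energy(sys, ff, method = "all")
  expect_identical(a$pe, b$pe)
  expect_lt(max(abs(a$forces - b$forces)), 1e-12)
  expect_equal(a$virial, b$virial, tolerance = 1e-12)
})

test_that("identical seeds give bit-identical trajectories", {
  topo <- cg_topology("compact_spacer", n_polymers = 3, n_particles = 4)
  ff <- default_forcefield(topo)
  cfg <- sim_config(box = c(30, 12, 12), seed = 21)
  sys <- build_system(topo, ff, cfg, relax_steps = 400)
  r1 <- run_dynamics(sys, ff, nsteps = 400, seed = 5, record_every = 100)
  r2 <- run_dynamics(sys, ff, nsteps = 400, seed = 5, record_every = 100)
  expect_identical(r1$system$pos, r2$system$pos)
  expect_identical(r1$trajectory$frames, r2$trajectory$frames)
  r3 <- run_dynamics(sys, ff, nsteps = 400, seed = 6, record_every = 100)
  expect_false(identical(r1$system$pos, r3$system$pos))
})

test_that("a force-free, noise-free, velocity-free state does not move", {
  sys <- two_bead_system(c(4, 4), 20, box = c(50, 50, 50))
  ff <- cg_forcefield("compact", eps = 0)
  out <- run_dynamics(sys, ff, nsteps = 100, thermostat = FALSE, seed = 1)
  expect_identical(out$system$pos, sys$pos)
})

test_that("instability is reported, not silently produced", {
  # FENE overextension
  bonds <- matrix(c(1L, 2L, 1L), 1, 3)
  sys <- two_bead_system(c(3, 3), 14.5, bonds = bonds)
  expect_error(potential_energy(sys, cg_forcefield("compact")),
               "overextended")
  # deep WCA overlap at a reckless time step blows up with a clear message
  sys <- two_bead_system(c(3, 3), 0.05)
  expect_error(
    run_dynamics(sys, cg_forcefield("compact"), nsteps = 10, dt = 0.01,
                 seed = 1),
    "blow-up")
})

test_that("microcanonical energy is conserved by the Verlet core", {
  topo <- cg_topology("spacers_only", n_polymers = 3, n_spacers = 12)
  ff <- cg_forcefield("idr")   # heavier beads, dt = 0.01 scale
  cfg <- sim_config(box = c(12, 12, 12), seed = 31)
  sys <- build_system(topo, ff, cfg, relax_steps = 1000, confine = FALSE)
  # thermalise, then switch the thermostat off at dt/10
  sys <- run_dynamics(sys, ff, nsteps = 2000, dt = 0.01, seed = 2)$system
  out <- run_dynamics(sys, ff, nsteps = 1e4, dt = 0.001, seed = 3,
                      thermostat = FALSE, sample_every = 10)
  ekt <- 1.380649e-2 * 300
  E <- out$ke + out$pe * ekt
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-4)
})

test_that("thermostatted kinetic temperature matches the target within 2%", {
  topo <- cg_topology("spacers_only", n_polymers = 4, n_spacers = 25)
  ff <- cg_forcefield("idr")
  cfg <- sim_config(box = c(14, 14, 14), seed = 41)
  sys <- build_system(topo, ff, cfg, relax_steps = 1000, confine = FALSE)
  out <- run_dynamics(sys, ff, nsteps = 5e4, dt = 0.01, seed = 4,
                      sample_every = 20)
  Tkin <- kinetic_temperature(out, n = nrow(sys$pos))
  expect_lt(abs(Tkin - 300) / 300, 0.02)
})

test_that("a free particle diffuses at kBT/(6 pi eta r)", {
  # 48 non-interacting particles of radius 1.5 nm (gamma = m/tau with the
  # published mass gives the Stokes-Einstein D for water viscosity)
  topo <- cg_topology("compact_spacer", n_polymers = 0, n_particles = 48)
  ff <- cg_forcefield("compact", eps = 0)
  cfg <- sim_config(box = c(100, 100, 100), seed = 51)
  sys <- build_system(topo, ff, cfg, relax_steps = 0)
  out <- run_dynamics(sys, ff, nsteps = 4e5, dt = 0.01, seed = 5,
                      record_every = 200, sample_every = 0)
  traj <- out$trajectory
  nf <- length(traj$frames)
  un <- lapply(seq_len(nf), function(i) unwrap_frame(traj, i))
  lags <- c(10, 20, 30, 40, 50)           # frames; 2 ns per frame
  msd <- vapply(lags, function(L) {
    o <- seq(1, nf - L, by = 5)
    mean(vapply(o, function(s) {
      mean(rowSums((un[[s + L]] - un[[s]])^2))
    }, numeric(1)))
  }, numeric(1))
  t_ns <- lags * traj$record_every * traj$dt
  Dhat <- unname(stats::coef(stats::lm(msd ~ t_ns))[2]) / 6
  D0 <- 1.380649e-23 * 300 / (6 * pi * 0.001 * 1.5e-9) * 1e9  # nm^2/ns
  expect_equal(D0, 0.1465, tolerance = 1e-3)
  expect_lt(abs(Dhat - D0) / D0, 0.05)
})

test_that("non-interacting system has exactly the ideal-gas pressure", {
  topo <- cg_topology("compact_spacer", n_polymers = 0, n_particles = 30)
  ff <- cg_forcefield("compact", eps = 0)
  cfg <- sim_config(box = c(20, 20, 20), seed = 61)
  sys <- build_system(topo, ff, cfg, relax_steps = 0)
  out <- run_dynamics(sys, ff, nsteps = 2000, seed = 6, record_every = 500)
  expect_true(all(out$virial == 0))
  p <- osmotic_pressure(out)
  V <- prod(cfg$box) * 1e-27                       # m^3
  p_ideal <- 30 * 1.380649e-23 * 300 / V           # Pa
  expect_equal(p$pressure, p_ideal, tolerance = 1e-10)
  # halving the density halves the pressure
  cfg2 <- sim_config(box = c(40, 20, 20), seed = 61)
  sys2 <- build_system(topo, ff, cfg2, relax_steps = 0)
  out2 <- run_dynamics(sys2, ff, nsteps = 2000, seed = 6,
                       record_every = 500)
  expect_equal(osmotic_pressure(out2)$pressure, p_ideal / 2,
               tolerance = 1e-10)
})

test_that("stickerless chains obey self-avoiding-walk statistics", {
  # end-to-end distance ~ N^nu; friction reduced (tau = 50 ns) purely for
  # sampling speed - equilibrium statistics are independent of gamma.
  # At these chain lengths the effective exponent sits near 0.63 (finite
  # chains approach the asymptotic 0.588 from above), so the acceptance
  # band is centred there; it cleanly excludes ideal-chain (0.5) and
  # collapsed (1/3) statistics.
  ree2 <- vapply(c(25, 50, 100), function(N) {
    topo <- cg_topology("spacers_only", n_polymers = 10, n_spacers = N)
    ff <- cg_forcefield("idr")
    cfg <- sim_config(box = c(120, 120, 120), seed = 70 + N)
    sys <- build_system(topo, ff, cfg, relax_steps = 2000, confine = FALSE)
    sys <- run_dynamics(sys, ff, nsteps = 1e5, dt = 0.01, tau = 50,
                        seed = N, sample_every = 0)$system
    out <- run_dynamics(sys, ff, nsteps = 2.4e5, dt = 0.01, tau = 50,
                        seed = N + 1, record_every = 2000, sample_every = 0)
    traj <- out$trajectory
    # end-to-end vector as the minimum-image sum of bond vectors, immune
    # to chains straddling the periodic boundary
    ends <- vapply(seq_along(traj$frames), function(i) {
      pos <- traj$frames[[i]]
      mean(vapply(0:9, function(p) {
        ch <- pos[p * N + seq_len(N), ]
        d <- apply(ch, 2, diff)
        for (k in 1:3) d[, k] <- mi(d[, k], traj$box[k])
        sum(colSums(d)^2)
      }, numeric(1)))
    }, numeric(1))
    mean(ends)
  }, numeric(1))
  nu_hat <- unname(stats::coef(
    stats::lm(log(ree2) ~ log(c(25, 50, 100))))[2]) / 2
  expect_gt(nu_hat, 0.55)
  expect_lt(nu_hat, 0.68)
})
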