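# System construction, Langevin dynamics driver, coexistence protocol and
# pressure measurement.  Units: nm, ns, ag; energies kBT; pressures Pa at the
# user interface (MPa internally, which is the natural unit of ag/(nm ns^2)).

# kB in ag nm^2 / (ns^2 K); ekt(300) = 4.1419 ag nm^2/ns^2 per kBT
.ekt <- function(temperature) 1.380649e-2 * temperature

#' Simulation configuration
#'
#' Run schedule and integrator settings for the coexistence protocol.
#' Defaults follow the published set-up (T = 300 K, damping tau = m/gamma =
#' 1 ns, dt = 0.01 ns) with desk-scale step counts; `anneal_steps` ramps the
#' sticker attraction linearly from 0 to its target depth while polymers are
#' confined, `wall_equil_steps` equilibrates at full depth still confined,
#' `equil_steps` relaxes after wall removal, and `production_steps` are
#' recorded every `record_every` steps.
#'
#' @param box Box edge lengths (nm), length 3; periodic in all directions.
#' @param temperature Kelvin.
#' @param tau Damping time m/gamma in ns.
#' @param dt Time step in ns.
#' @param anneal_steps,wall_equil_steps,equil_steps,production_steps Phase
#'   step counts.
#' @param record_every Recording interval (steps) during production.
#' @param sample_every Thermo sampling interval (steps).
#' @param confine_frac Initial confinement of polymers to
#'   `|x - Lx/2| < confine_frac * Lx` (centre of the box); the published
#'   protocol confines to the central 60% of the box.
#' @param seed Integer random seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(box = c(100, 25, 25), temperature = 300, tau = 1,
                       dt = 0.01, anneal_steps = 1e5, wall_equil_steps = 5e4,
                       equil_steps = 5e4, production_steps = 1.5e5,
                       record_every = 1000, sample_every = 100,
                       confine_frac = 0.3, seed = 1) {
  stopifnot(length(box) == 3, all(box > 0), dt > 0, tau > 0,
            temperature > 0)
  structure(list(box = box, temperature = temperature, tau = tau, dt = dt,
                 anneal_steps = as.integer(anneal_steps),
                 wall_equil_steps = as.integer(wall_equil_steps),
                 equil_steps = as.integer(equil_steps),
                 production_steps = as.integer(production_steps),
                 record_every = as.integer(record_every),
                 sample_every = as.integer(sample_every),
                 confine_frac = confine_frac, seed = as.integer(seed)),
            class = "sim_config")
}

#' Build an initial system state
#'
#' Places polymers as bond-length random walks (confined to the central
#' `confine_frac` of the box along x when a coexistence protocol will follow)
#' and particles uniformly, then removes steric overlaps by a short
#' force-capped relaxation run.
#'
#' @param topology A [cg_topology()].
#' @param ff A [cg_forcefield()].
#' @param config A [sim_config()]; supplies box, seed and confinement.
#' @param relax_steps Force-capped relaxation steps (0 to skip).
#' @param confine Confine polymer walks along x (default TRUE when the
#'   topology has stickers).
#' @return An object of class `cg_system` with fields `pos`, `vel`, `type`,
#'   `mol`, `is_polymer`, `bonds`, `box`.
#' @export
build_system <- function(topology, ff, config, relax_steps = 4000,
                         confine = NULL) {
  stopifnot(inherits(topology, "cg_topology"), inherits(ff, "cg_forcefield"),
            inherits(config, "sim_config"))
  box <- config$box
  if (is.null(confine)) confine <- topology$preset != "spacers_only"
  npol <- topology$n_polymers
  bpp <- topology$beads_per_polymer
  n <- npol * bpp + topology$n_particles
  if (n == 0) {
    return(structure(list(pos = matrix(0, 0, 3), vel = matrix(0, 0, 3),
                          type = integer(0), mol = integer(0),
                          is_polymer = logical(0),
                          bonds = matrix(integer(0), 0, 3),
                          box = box, topology = topology),
                     class = "cg_system"))
  }
  # crude packing feasibility: total bead volume must fit the box
  radius <- ff$bead_types$radius
  virt <- ff$bead_types$is_virtual_patch
  type_all <- c(rep(topology$template_type, npol),
                rep(4L, topology$n_particles))
  vol <- sum(ifelse(virt[type_all], 0, 4 / 3 * pi * radius[type_all]^3))
  if (vol > 0.55 * prod(box)) {
    stop("infeasible packing: bead volume exceeds 55% of the box")
  }

  set.seed(config$seed)
  Lx <- box[1]
  xrange <- if (confine) {
    c(Lx / 2 - config$confine_frac * Lx, Lx / 2 + config$confine_frac * Lx)
  } else c(0, Lx)

  step_len <- topology$template_bonds
  bl <- ff$bond_classes
  pos <- matrix(0, n, 3)
  mol <- integer(n)
  # spacer backbone walk; stickers next to their host spacer
  nsp <- topology$n_spacers
  walk_step <- if (nrow(bl) && bl$style[1] == 0L) 3.0 else bl$p2[1]
  for (p in seq_len(npol)) {
    off <- (p - 1) * bpp
    start <- c(stats::runif(1, xrange[1], xrange[2]),
               stats::runif(1, 0, box[2]), stats::runif(1, 0, box[3]))
    cur <- start
    for (i in seq_len(nsp)) {
      if (i > 1) {
        dir <- stats::rnorm(3)
        cur <- cur + walk_step * dir / sqrt(sum(dir^2))
        # keep the walk inside the confinement slab along x
        if (cur[1] < xrange[1]) cur[1] <- xrange[1] + (xrange[1] - cur[1])
        if (cur[1] > xrange[2]) cur[1] <- xrange[2] - (cur[1] - xrange[2])
      }
      pos[off + i, ] <- cur
    }
    if (bpp > nsp) { # stickers: small offset from host spacer
      host <- topology$template_bonds[
        topology$template_bonds[, 3] == 2L, 1]
      st <- (nsp + 1):bpp
      for (k in seq_along(st)) {
        pos[off + st[k], ] <- pos[off + host[k], ] + stats::rnorm(3, 0, 0.1)
      }
    }
    mol[off + seq_len(bpp)] <- p
  }
  if (topology$n_particles > 0) {
    idx <- npol * bpp + seq_len(topology$n_particles)
    pos[idx, ] <- cbind(stats::runif(length(idx), 0, box[1]),
                        stats::runif(length(idx), 0, box[2]),
                        stats::runif(length(idx), 0, box[3]))
    mol[idx] <- npol + seq_along(idx)
  }
  pos <- sweep(pos, 2, box, function(x, L) x - L * floor(x / L))

  bonds <- do.call(rbind, c(
    lapply(seq_len(npol), function(p) {
      b <- topology$template_bonds
      if (nrow(b)) b[, 1:2] <- b[, 1:2] + (p - 1) * bpp
      b
    }), list(matrix(integer(0), 0, 3))))
  storage.mode(bonds) <- "integer"

  sys <- structure(list(pos = pos, vel = matrix(0, n, 3), type = type_all,
                        mol = mol,
                        is_polymer = mol <= npol & mol > 0,
                        bonds = bonds, box = box, topology = topology),
                   class = "cg_system")
  if (relax_steps > 0) {
    # staged capped-force push-off with the sticker attraction off; the cap
    # is raised gradually so deeply overlapping random-walk starts inflate
    # smoothly instead of exploding
    nst <- max(200L, as.integer(relax_steps / 4))
    for (fcap in c(5, 50, 500, 5000)) {
      out <- .run_ld(sys, ff, dt = config$dt / 10, nsteps = nst,
                     tau = config$tau, temperature = config$temperature,
                     seed = config$seed + 7L, ramp = c(0, 0), fcap = fcap,
                     sample_every = 0L)
      sys <- out$system
    }
    # extra rounds until residual forces are integrable at the working dt
    for (round in 1:30) {
      pe <- potential_energy(sys, ff, soft_scale = 0)
      if (max(abs(pe$forces)) < 300) break
      sys <- .run_ld(sys, ff, dt = config$dt / 20, nsteps = nst,
                     tau = config$tau, temperature = config$temperature,
                     seed = config$seed + 17L + round, ramp = c(0, 0),
                     fcap = 5000, sample_every = 0L)$system
    }
    # thermalised settle at reduced dt so the run proper starts from an
    # equilibrium-scale force distribution
    sys <- .run_ld(sys, ff, dt = config$dt / 10, nsteps = 2 * nst,
                   tau = config$tau, temperature = config$temperature,
                   seed = config$seed + 57L, ramp = c(0, 0),
                   sample_every = 0L)$system
    sys$vel[] <- 0
  }
  sys
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("cg_system: %d beads in %g x %g x %g nm box (%d bonds)\n",
              nrow(x$pos), x$box[1], x$box[2], x$box[3], nrow(x$bonds)))
  invisible(x)
}

#' Potential energy and forces of a configuration
#'
#' Sums bond (FENE/harmonic), WCA repulsion, sticker attraction and client
#' attraction terms; forces are the exact negative gradient.  Directly bonded
#' (1-2) pairs are excluded from nonbonded terms, the standard bead-spring
#' convention.
#'
#' @param system A `cg_system`.
#' @param ff A [cg_forcefield()].
#' @param soft_scale Multiplier on the sticker attraction (annealing ramp
#'   state), default 1.
#' @param method Neighbour search: `"auto"`, `"cells"` or `"all"` (all-pairs;
#'   the two must agree exactly).
#' @return List with `pe` (kBT), `forces` (kBT/nm) and `virial`
#'   (sum of r.f over interactions, kBT).
#' @export
potential_energy <- function(system, ff, soft_scale = 1,
                             method = c("auto", "cells", "all")) {
  method <- match.arg(method)
  m <- c(auto = 0L, cells = 1L, all = 2L)[[method]]
  bc <- ff$bond_classes
  out <- cs_forces(system$pos, system$type, system$box, .ff_cpp(ff),
                   system$bonds, bc$style, bc$p1, bc$p2, soft_scale, m)
  list(pe = out$pe, forces = out$forces, virial = out$virial)
}

# low-level dynamics driver; returns updated system + samples + frames
.run_ld <- function(system, ff, dt, nsteps, tau, temperature, seed,
                    thermostat = TRUE, ramp = c(1, 1), walls = NULL,
                    fcap = -1, record_every = 0L, sample_every = 100L,
                    method = 0L) {
  bc <- ff$bond_classes
  mass <- ff$bead_types$mass
  wall_mask <- integer(0)
  wlo <- NA_real_; whi <- NA_real_
  if (!is.null(walls)) {
    wlo <- walls[1]; whi <- walls[2]
    wall_mask <- as.integer(system$is_polymer)
  }
  out <- cs_run(system$pos, system$vel, system$type, mass, system$box,
                .ff_cpp(ff), system$bonds, bc$style, bc$p1, bc$p2,
                dt, as.integer(nsteps), tau, .ekt(temperature),
                as.integer(seed), thermostat, ramp[1], ramp[2],
                wlo, whi, 10.0, wall_mask, fcap,
                as.integer(record_every), as.integer(sample_every),
                as.integer(method))
  system$pos <- out$pos
  system$vel <- out$vel
  list(system = system, frames = out$frames, rec_steps = out$rec_steps,
       pe = out$pe, ke = out$ke, virial = out$virial)
}

#' Run Langevin dynamics on a system
#'
#' Advances underdamped Langevin dynamics (BAOAB splitting of the equation
#' of motion `m r'' = -gamma r' - grad U + noise`, with per-bead friction
#' `gamma_i = m_i / tau`).  With `thermostat = FALSE` the integrator reduces
#' to plain velocity Verlet (microcanonical).
#'
#' @param system A `cg_system` (updated state is returned).
#' @param ff A [cg_forcefield()].
#' @param nsteps Number of steps.
#' @param dt Time step, ns.
#' @param tau Damping time, ns.
#' @param temperature Kelvin.
#' @param seed Integer seed for the thermal noise.
#' @param thermostat Langevin thermostat on/off.
#' @param record_every Record frames every so many steps (0 = none).
#' @param sample_every Sample thermo (pe, ke, virial) every so many steps.
#' @return List with the updated `system`, a `trajectory` (when frames were
#'   recorded) and samples `pe` (kBT), `ke` (ag nm2/ns2), `virial` (kBT).
#' @export
run_dynamics <- function(system, ff, nsteps, dt = 0.01, tau = 1,
                         temperature = 300, seed = 1, thermostat = TRUE,
                         record_every = 0, sample_every = 100) {
  out <- .run_ld(system, ff, dt = dt, nsteps = nsteps, tau = tau,
                 temperature = temperature, seed = seed,
                 thermostat = thermostat, record_every = record_every,
                 sample_every = sample_every)
  traj <- NULL
  if (record_every > 0 && length(out$frames)) {
    traj <- .make_trajectory(out, system, ff, dt, record_every, temperature)
  }
  list(system = out$system, trajectory = traj, pe = out$pe, ke = out$ke,
       virial = out$virial)
}

.make_trajectory <- function(out, system, ff, dt, record_every,
                             temperature) {
  structure(list(
    frames = lapply(out$frames, `[[`, "pos"),
    images = lapply(out$frames, `[[`, "img"),
    steps = out$rec_steps,
    type = system$type, mol = system$mol, is_polymer = system$is_polymer,
    box = system$box,
    radius_by_type = ff$bead_types$radius,
    virtual_by_type = ff$bead_types$is_virtual_patch,
    dt = dt, record_every = record_every, temperature = temperature,
    pe = out$pe, ke = out$ke, virial = out$virial,
    client_R = max(ff$client_R), client_ra = max(ff$client_ra)
  ), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "cg_trajectory: %d frames x %d beads, box %g x %g x %g nm\n",
    length(x$frames), length(x$type), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Coexistence simulation protocol
#'
#' Full condensate-formation schedule: polymers start confined to the
#' central slab of the box; the sticker attraction is ramped linearly from 0
#' to its target depth (`anneal_steps`), the condensate is equilibrated at
#' full depth still confined (`wall_equil_steps`), the walls are removed and
#' the system relaxes (`equil_steps`), and finally production frames are
#' recorded.
#'
#' @param topology A [cg_topology()].
#' @param ff A [cg_forcefield()]; NULL picks the preset default.
#' @param config A [sim_config()].
#' @param system Optional pre-built/equilibrated `cg_system` (skips
#'   [build_system()] and, when `skip_anneal = TRUE`, the anneal phases).
#' @param skip_anneal Start directly from the free-equilibration phase.
#' @return A `cg_trajectory` of the production phase; the final state is
#'   attached as attribute `"system"`.
#' @export
run_protocol <- function(topology, ff = NULL, config = sim_config(),
                         system = NULL, skip_anneal = FALSE) {
  if (is.null(ff)) ff <- default_forcefield(topology)
  if (is.null(system)) system <- build_system(topology, ff, config)
  n <- nrow(system$pos)
  if (n == 0 || config$production_steps == 0) {
    out <- list(frames = list(list(pos = system$pos,
                                   img = matrix(0L, n, 3))),
                rec_steps = 0L, pe = numeric(0), ke = numeric(0),
                virial = numeric(0), system = system)
    traj <- .make_trajectory(out, system, ff, config$dt,
                             config$record_every, config$temperature)
    attr(traj, "system") <- system
    return(traj)
  }
  Lx <- config$box[1]
  walls <- Lx / 2 + c(-1, 1) * config$confine_frac * Lx
  seed <- config$seed
  if (!skip_anneal) {
    if (config$anneal_steps > 0) {
      system <- .run_ld(system, ff, config$dt, config$anneal_steps,
                        config$tau, config$temperature, seed + 1L,
                        ramp = c(0, 1), walls = walls,
                        sample_every = 0L)$system
    }
    if (config$wall_equil_steps > 0) {
      system <- .run_ld(system, ff, config$dt, config$wall_equil_steps,
                        config$tau, config$temperature, seed + 2L,
                        walls = walls, sample_every = 0L)$system
    }
  }
  if (config$equil_steps > 0) {
    system <- .run_ld(system, ff, config$dt, config$equil_steps,
                      config$tau, config$temperature, seed + 3L,
                      sample_every = 0L)$system
  }
  out <- .run_ld(system, ff, config$dt, config$production_steps,
                 config$tau, config$temperature, seed + 4L,
                 record_every = config$record_every,
                 sample_every = config$sample_every)
  traj <- .make_trajectory(out, system, ff, config$dt, config$record_every,
                           config$temperature)
  attr(traj, "system") <- out$system
  traj
}

#' Osmotic pressure from production samples
#'
#' Time-averaged virial pressure
#' \deqn{\Pi = \frac{N k_B T + \frac{1}{3}\sum \vec r_{ij}\cdot\vec f_{ij}}{V},}
#' using the thermostat target temperature for the ideal term (so a
#' non-interacting system gives exactly `N kBT / V`) and the pair+bond
#' virial sampled during the run.  The standard error is estimated by block
#' averaging (10 blocks); a warning is issued if the first- and second-half
#' block means differ by more than 3 combined standard errors
#' (non-stationarity).
#'
#' @param run A `cg_trajectory` (or the list returned by [run_dynamics()])
#'   carrying `virial` samples.
#' @param nblocks Number of blocks for the error estimate.
#' @return List with `pressure` (Pa), `se` (Pa), `n_samples`.
#' @export
osmotic_pressure <- function(run, nblocks = 10) {
  vir <- run$virial
  if (is.null(vir) || !length(vir)) stop("no virial samples in this run")
  traj <- if (inherits(run, "cg_trajectory")) run else run$trajectory
  N <- length(traj$type)
  V <- prod(traj$box)
  ekt <- .ekt(traj$temperature)
  p_inst <- (N * ekt + ekt * vir / 3) / V  # MPa
  nb <- max(2, min(nblocks, length(p_inst)))
  blocks <- split(p_inst, cut(seq_along(p_inst), nb, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  se <- stats::sd(bm) / sqrt(length(bm))
  h1 <- bm[seq_len(length(bm) %/% 2)]
  h2 <- bm[(length(bm) %/% 2 + 1):length(bm)]
  if (length(h1) > 1 && length(h2) > 1) {
    d <- abs(mean(h1) - mean(h2))
    sd2 <- sqrt(stats::sd(h1)^2 / length(h1) + stats::sd(h2)^2 / length(h2))
    if (is.finite(sd2) && sd2 > 0 && d > 3 * sd2) {
      warning("pressure blocks look non-stationary; extend equilibration")
    }
  }
  list(pressure = mean(p_inst) * 1e6, se = se * 1e6,
       n_samples = length(p_inst))
}

#' Kinetic temperature of sampled frames
#'
#' Equipartition estimate `T = 2 <KE> / (3 N kB)` from the kinetic-energy
#' samples of a run.
#'
#' @param run Output of [run_dynamics()] or a `cg_trajectory` with `ke`
#'   samples.
#' @param n Number of beads (taken from the trajectory if present).
#' @return Temperature in K.
#' @export
kinetic_temperature <- function(run, n = NULL) {
  ke <- run$ke
  if (is.null(ke) || !length(ke)) stop("no kinetic-energy samples")
  if (is.null(n)) {
    traj <- if (inherits(run, "cg_trajectory")) run else run$trajectory
    n <- length(traj$type)
  }
  mean(ke) * 2 / (3 * n * 1.380649e-2)
}

#' Unwrapped coordinates of a trajectory frame
#' @param traj A `cg_trajectory`.
#' @param i Frame index.
#' @return N x 3 matrix of unwrapped positions (nm).
#' @export
unwrap_frame <- function(traj, i) {
  traj$frames[[i]] + traj$images[[i]] %*% diag(traj$box)
}

#' Largest-cluster fraction of polymers
#'
#' Single-linkage clustering of polymer molecules (beads within
#' `scale * (ri + rj)`); returns the fraction of polymers in the largest
#' cluster, the standard condensation diagnostic.
#'
#' @param traj A `cg_trajectory`.
#' @param i Frame index.
#' @param scale Contact-distance scale factor (default 1.2).
#' @return Fraction in `[0, 1]`.
#' @export
largest_cluster_fraction <- function(traj, i = length(traj$frames),
                                     scale = 1.2) {
  mol <- ifelse(traj$is_polymer, traj$mol, 0L)
  npol <- max(c(0L, mol))
  if (npol == 0) return(NA_real_)
  rad <- traj$radius_by_type[traj$type]
  rad[traj$virtual_by_type[traj$type]] <- 0.15  # patches barely reach
  lab <- cs_cluster(traj$frames[[i]], as.integer(mol), rad, traj$box, scale)
  max(table(lab)) / npol
}
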