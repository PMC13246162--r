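# Shared scaled-down coexistence runs, computed once per test session and
# reused across test files.  The conditions (counts, box sizes, schedules)
# are the package's desk-scale study conditions; see the methods vignette.

.coex_cache <- new.env(parent = emptyenv())

.cached <- function(name, fn) {
  if (!exists(name, envir = .coex_cache)) {
    assign(name, fn(), envir = .coex_cache)
  }
  get(name, envir = .coex_cache)
}

compact_mini_topology <- function() {
  cg_topology("compact_spacer", n_polymers = 20, n_particles = 24)
}

compact_mini_config <- function() {
  sim_config(box = c(80, 18, 18), anneal_steps = 8e4,
             wall_equil_steps = 4e4, equil_steps = 4e4,
             production_steps = 1.2e5, record_every = 1000,
             confine_frac = 0.2, seed = 42)
}

# compact-spacer condensate + neutral particles
compact_coex <- function() .cached("compact", function() {
  topo <- compact_mini_topology()
  run_protocol(topo, default_forcefield(topo), compact_mini_config())
})

# IDR-spacer condensate + neutral particles (shortened 64-mer chains)
idr_coex <- function() .cached("idr", function() {
  topo <- cg_topology("idr_spacer", n_polymers = 30, n_particles = 24,
                      n_spacers = 64)
  cfg <- sim_config(box = c(60, 15, 15), anneal_steps = 2e5,
                    wall_equil_steps = 5e4, equil_steps = 4e4,
                    production_steps = 1e5, record_every = 1000,
                    confine_frac = 0.15, seed = 11)
  run_protocol(topo, default_forcefield(topo), cfg)
})

# client-attraction sweep: continue the compact condensate with the
# client-sticker attraction switched on at depth eps.  Client uptake into
# the condensate is diffusion-limited (and nearly irreversible at strong
# attraction), so the production leg is long and analyses use its second
# half (see second_half()).
recruit_run <- function(eps) .cached(paste0("recruit", eps), function() {
  base <- compact_coex()
  topo <- compact_mini_topology()
  ff <- default_forcefield(topo, client_eps = eps)
  cfg <- compact_mini_config()
  cfg$equil_steps <- 1e5
  cfg$production_steps <- 6e5
  cfg$record_every <- 2000
  cfg$seed <- cfg$seed + round(100 * eps)
  run_protocol(topo, ff, cfg, system = attr(base, "system"),
               skip_anneal = TRUE)
})

# drop the first half of a trajectory's frames (burn-in)
second_half <- function(traj) {
  keep <- seq(length(traj$frames) %/% 2 + 1, length(traj$frames))
  traj$frames <- traj$frames[keep]
  if (!is.null(traj$images)) traj$images <- traj$images[keep]
  traj$steps <- traj$steps[keep]
  traj
}

# dense-phase Widom insertion on a coexistence trajectory (probe centres in
# the recentred dense slab)
dense_widom <- function(traj, radii = 1.5, halfwidth = 6) {
  insert_hard_spheres(traj, radii = radii, grid = c(40, 36, 36),
                      region = traj$box[1] / 2 + c(-halfwidth, halfwidth),
                      recenter = TRUE)
}

# per-frame particle counts in the dense/dilute regions (for block errors)
particle_region_counts <- function(traj, regions) {
  Lx <- traj$box[1]
  is_par <- !traj$is_polymer & traj$type == 4L
  t(vapply(seq_along(traj$frames), function(i) {
    pos <- traj$frames[[i]]
    cx <- condsieve:::.circ_center(pos[traj$is_polymer, 1], Lx)
    xr <- (pos[, 1] - cx + Lx / 2) %% Lx - Lx / 2
    c(dense = sum(is_par & abs(xr) < regions$dense),
      dilute = sum(is_par & abs(xr) > regions$dilute))
  }, numeric(2)))
}
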