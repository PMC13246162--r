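# Synthetic bead configurations with known statistical structure, used by
# the Widom and profile analyses (and their tests) as controlled inputs.

# bare-bones trajectory container around explicit frames
.fixture_traj <- function(frames, types, box, radius_by_type,
                          virtual_by_type = rep(FALSE,
                                                length(radius_by_type)),
                          mol = NULL, is_polymer = NULL) {
  n <- length(types)
  structure(list(
    frames = frames, images = NULL, steps = seq_along(frames),
    type = types,
    mol = if (is.null(mol)) rep(0L, n) else mol,
    is_polymer = if (is.null(is_polymer)) rep(FALSE, n) else is_polymer,
    box = box, radius_by_type = radius_by_type,
    virtual_by_type = virtual_by_type,
    dt = NA_real_, record_every = NA_integer_, temperature = 300,
    client_R = 0, client_ra = 0
  ), class = "cg_trajectory")
}

#' Generate a synthetic test configuration
#'
#' Deterministic (given `seed`) fixtures with documented structure:
#' \describe{
#'   \item{`"empty_box"`}{no beads.}
#'   \item{`"single_sphere"`}{one type-C bead of radius `radius` at the box
#'     centre.}
#'   \item{`"hs_gas"`}{non-overlapping type-C spheres placed by rejection
#'     sampling to volume fraction `phi` (error if `phi` is infeasible for
#'     rejection placement).}
#'   \item{`"ideal_slab"`}{`n` ideal (non-interacting) beads uniform in the
#'     central slab `|x - Lx/2| < slab_halfwidth`.}
#'   \item{`"mini_polymer_box"`}{a small spacers-only system equilibrated by
#'     a short Langevin run; `...` is passed to [cg_topology()].}
#' }
#'
#' @param kind Fixture name.
#' @param box Box edges, nm.
#' @param n Bead count (hs_gas is derived from `phi` instead).
#' @param radius Bead radius, nm.
#' @param phi Target volume fraction (hs_gas).
#' @param slab_halfwidth Slab half-width, nm (ideal_slab).
#' @param nframes Number of (independent) frames.
#' @param seed Integer seed.
#' @param ... Extra arguments for `"mini_polymer_box"`.
#' @return A `cg_trajectory`.
#' @export
generate_fixture <- function(kind = c("empty_box", "single_sphere", "hs_gas",
                                      "ideal_slab", "mini_polymer_box"),
                             box = c(20, 20, 20), n = 100, radius = 1,
                             phi = 0.05, slab_halfwidth = 5, nframes = 1,
                             seed = 1, ...) {
  kind <- match.arg(kind)
  set.seed(seed)
  rbt <- c(0.3, 0.3, radius, 1.5)
  virt <- c(TRUE, TRUE, FALSE, FALSE)
  if (kind == "empty_box") {
    return(.fixture_traj(list(matrix(0, 0, 3)), integer(0), box, rbt, virt))
  }
  if (kind == "single_sphere") {
    fr <- lapply(seq_len(nframes), function(i) {
      matrix(box / 2, 1, 3, byrow = TRUE)
    })
    return(.fixture_traj(fr, 3L, box, rbt, virt))
  }
  if (kind == "hs_gas") {
    vb <- 4 / 3 * pi * radius^3
    nb <- round(phi * prod(box) / vb)
    if (phi > 0.3) stop("infeasible phi for rejection placement")
    fr <- lapply(seq_len(nframes), function(f) {
      pos <- matrix(NA_real_, nb, 3)
      placed <- 0L
      tries <- 0L
      while (placed < nb) {
        tries <- tries + 1L
        if (tries > 2e5) stop("rejection placement failed to converge")
        cand <- stats::runif(3) * box
        ok <- TRUE
        if (placed > 0) {
          d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand)
          for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
          ok <- all(rowSums(d^2) >= (2 * radius)^2)
        }
        if (ok) {
          placed <- placed + 1L
          pos[placed, ] <- cand
        }
      }
      pos
    })
    return(.fixture_traj(fr, rep(3L, nb), box, rbt, virt,
                         mol = seq_len(nb), is_polymer = rep(TRUE, nb)))
  }
  if (kind == "ideal_slab") {
    fr <- lapply(seq_len(nframes), function(f) {
      cbind(stats::runif(n, box[1] / 2 - slab_halfwidth,
                         box[1] / 2 + slab_halfwidth),
            stats::runif(n, 0, box[2]), stats::runif(n, 0, box[3]))
    })
    return(.fixture_traj(fr, rep(3L, n), box, rbt, virt,
                         mol = seq_len(n), is_polymer = rep(TRUE, n)))
  }
  # mini_polymer_box: short equilibrated spacers-only system
  topo <- cg_topology("spacers_only", ...)
  ff <- cg_forcefield("spacers_only")
  cfg <- sim_config(box = box, dt = 1e-4, tau = 0.01, seed = seed,
                    anneal_steps = 0, wall_equil_steps = 0, equil_steps = 0,
                    production_steps = 0)
  sys <- build_system(topo, ff, cfg, confine = FALSE)
  out <- run_dynamics(sys, ff, nsteps = 2e4, dt = 1e-4, tau = 0.01,
                      seed = seed, record_every = max(1L, 2e4 / nframes))
  out$trajectory
}
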