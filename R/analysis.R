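# Coexistence-trajectory analysis: density profiles along x, measured
# partition coefficients, and dissociation-constant extraction for the
# recruitment model.

# circular mean along a periodic axis -> centre position in [0, L)
.circ_center <- function(x, L) {
  th <- 2 * pi * x / L
  (atan2(mean(sin(th)), mean(cos(th))) / (2 * pi) * L) %% L
}

#' Phase-region definition for profile averaging
#'
#' Dense phase: `|x| < dense` (after recentring the condensate at x = 0);
#' dilute phase: `|x| > dilute`.  Defaults follow the published convention
#' for a 100-nm box (dense within 10 nm of the centre, dilute beyond 40 nm);
#' `scale_to_box()` rescales both bounds proportionally for other box sizes.
#'
#' @param dense Half-width of the dense interval, nm.
#' @param dilute Inner bound of the dilute intervals, nm.
#' @return An object of class `phase_regions`.
#' @export
phase_regions <- function(dense = 10, dilute = 40) {
  if (dense <= 0 || dilute <= dense) {
    stop("need 0 < dense < dilute")
  }
  structure(list(dense = dense, dilute = dilute), class = "phase_regions")
}

#' @rdname phase_regions
#' @param regions A `phase_regions` defined for a reference box length.
#' @param Lx Target box length, nm.
#' @param Lx_ref Reference box length the defaults correspond to.
#' @export
scale_to_box <- function(regions = phase_regions(), Lx, Lx_ref = 100) {
  phase_regions(regions$dense * Lx / Lx_ref, regions$dilute * Lx / Lx_ref)
}

#' Volume-fraction profile along x
#'
#' Histograms bead centres into `bins` slabs along x (bin width = box
#' length / bins), converting counts to volume fractions with the single-bead
#' volume (no partial-overlap apportioning).  Each frame is recentred to the
#' polymer centre of mass along x (circular mean under periodicity) so the
#' condensate sits at x = 0, then averaged over frames and optionally
#' symmetrized about x = 0.  Frames whose largest polymer cluster holds less
#' than `min_cluster_frac` of the polymers are excluded and counted.
#'
#' @param traj A `cg_trajectory` from a coexistence run.
#' @param bins Number of bins (default 50).
#' @param recenter Recentre each frame to the polymer centre of mass.
#' @param symmetrize Average the profile with its mirror image.
#' @param check_clusters Flag and drop multi-cluster frames.
#' @param min_cluster_frac Threshold for the largest-cluster fraction.
#' @return A data.frame of class `profile_table` with columns `x` (bin
#'   centre, nm, condensate-centred), `phi_polymer`, `phi_particle`;
#'   attributes `n_frames`, `n_excluded`, `bin_width`.
#' @export
density_profile <- function(traj, bins = 50, recenter = TRUE,
                            symmetrize = TRUE, check_clusters = TRUE,
                            min_cluster_frac = 0.5) {
  stopifnot(inherits(traj, "cg_trajectory"))
  Lx <- traj$box[1]
  bw <- Lx / bins
  vbin <- bw * traj$box[2] * traj$box[3]
  rad <- traj$radius_by_type[traj$type]
  virt <- traj$virtual_by_type[traj$type]
  vol <- ifelse(virt, 0, 4 / 3 * pi * rad^3)
  is_pol <- traj$is_polymer & !virt
  is_par <- !traj$is_polymer & traj$type == 4L
  edges <- seq(-Lx / 2, Lx / 2, length.out = bins + 1)

  acc_pol <- numeric(bins); acc_par <- numeric(bins)
  used <- 0L; excluded <- 0L
  for (i in seq_along(traj$frames)) {
    if (check_clusters && any(traj$is_polymer)) {
      if (largest_cluster_fraction(traj, i) < min_cluster_frac) {
        excluded <- excluded + 1L
        next
      }
    }
    pos <- traj$frames[[i]]
    x <- pos[, 1]
    if (recenter && any(traj$is_polymer)) {
      cx <- .circ_center(x[traj$is_polymer], Lx)
    } else {
      cx <- Lx / 2
    }
    xr <- (x - cx + Lx / 2) %% Lx - Lx / 2  # condensate-centred in [-L/2,L/2)
    bi <- pmin(bins, pmax(1L, findInterval(xr, edges, all.inside = TRUE)))
    if (any(is_pol)) {
      acc_pol <- acc_pol +
        vapply(seq_len(bins),
               function(b) sum(vol[is_pol][bi[is_pol] == b]), numeric(1))
    }
    if (any(is_par)) {
      acc_par <- acc_par +
        vapply(seq_len(bins),
               function(b) sum(vol[is_par][bi[is_par] == b]), numeric(1))
    }
    used <- used + 1L
  }
  if (used == 0) stop("no usable frames (all flagged as multi-cluster)")
  phi_pol <- acc_pol / (used * vbin)
  phi_par <- acc_par / (used * vbin)
  if (symmetrize) {
    phi_pol <- (phi_pol + rev(phi_pol)) / 2
    phi_par <- (phi_par + rev(phi_par)) / 2
  }
  res <- data.frame(x = (edges[-1] + edges[-(bins + 1)]) / 2,
                    phi_polymer = phi_pol, phi_particle = phi_par)
  attr(res, "n_frames") <- used
  attr(res, "n_excluded") <- excluded
  attr(res, "bin_width") <- bw
  class(res) <- c("profile_table", "data.frame")
  res
}

#' Measured partition coefficient from a profile
#'
#' Dense/dilute ratio of region-averaged volume fractions,
#' `P = phi_den / phi_dil`, together with the corresponding free energy
#' `deltaF = -ln P` (kBT).
#'
#' @param profile A `profile_table` from [density_profile()].
#' @param regions A [phase_regions()].
#' @param species `"particle"` (default) or `"polymer"`.
#' @return List with `P`, `deltaF`, `phi_den`, `phi_dil` and `lower_bound`
#'   (TRUE when the dilute region is empty, making P a lower bound).
#' @export
partition_coefficient_measured <- function(profile,
                                           regions = phase_regions(),
                                           species = c("particle",
                                                       "polymer")) {
  species <- match.arg(species)
  col <- paste0("phi_", species)
  dense <- abs(profile$x) < regions$dense
  dilute <- abs(profile$x) > regions$dilute
  if (!any(dense) || !any(dilute)) {
    stop("regions select no bins; check bounds against the box")
  }
  phi_den <- mean(profile[[col]][dense])
  phi_dil <- mean(profile[[col]][dilute])
  lower <- phi_dil == 0
  if (lower) {
    # bound: pretend a single bead-volume count in the dilute region
    warning("empty dilute region; P reported as a lower bound")
    phi_dil <- .Machine$double.xmin
  }
  P <- phi_den / phi_dil
  list(P = P, deltaF = -log(P), phi_den = phi_den, phi_dil = phi_dil,
       lower_bound = lower)
}

#' Plateau volume fraction of the dense phase
#' @param profile A `profile_table`.
#' @param regions A [phase_regions()]; the dense interval defines the
#'   plateau.
#' @return Mean polymer volume fraction over the dense bins.
#' @export
dense_phase_phi <- function(profile, regions = phase_regions()) {
  mean(profile$phi_polymer[abs(profile$x) < regions$dense])
}

#' Dissociation constant and binding-site density from a client run
#'
#' Extracts, in the dense phase, the total client density, the sticker
#' (binding-site) density and the bound-sticker density, and forms
#' \deqn{K_D = \rho_{client} \rho_{sticker}^{free} / \rho_{sticker}^{bound}}
#' (the total client density stands in for the free-client density, since a
#' multivalent client is never saturated).  A sticker counts as bound when
#' its centre lies within `binding_range` of a client centre; the default
#' range `R + ra` is the reach of the client-sticker attraction.
#'
#' @param traj A `cg_trajectory` from a run with client attraction.
#' @param regions A [phase_regions()]; densities are measured in
#'   `|x| < dense` after recentring.
#' @param binding_range Bound/free distance criterion, nm (default: the
#'   attraction reach recorded in the trajectory, else 1.8).
#' @return List with `KD` (nm^-3), `rho` (binding sites, nm^-3),
#'   `rho_client`, `rho_bound`, `rho_free`, `n_frames`; `KD` is `Inf`
#'   (flagged `undefined`) when no sticker is ever bound.
#' @export
measure_KD <- function(traj, regions = phase_regions(),
                       binding_range = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (is.null(binding_range)) {
    binding_range <- if (!is.null(traj$client_R) && traj$client_R > 0) {
      traj$client_R + traj$client_ra
    } else 1.8
  }
  Lx <- traj$box[1]
  is_sticker <- traj$virtual_by_type[traj$type]
  is_client <- !traj$is_polymer & traj$type == 4L
  if (!any(is_client)) stop("no client particles in this trajectory")
  if (!any(is_sticker)) stop("no stickers in this trajectory")
  vden <- 2 * regions$dense * traj$box[2] * traj$box[3]

  n_cl <- n_st <- n_bound <- 0
  for (i in seq_along(traj$frames)) {
    pos <- traj$frames[[i]]
    cx <- .circ_center(pos[traj$is_polymer, 1], Lx)
    xr <- (pos[, 1] - cx + Lx / 2) %% Lx - Lx / 2
    in_den <- abs(xr) < regions$dense
    st <- which(is_sticker & in_den)
    cl <- which(is_client & in_den)
    n_st <- n_st + length(st)
    n_cl <- n_cl + length(cl)
    if (length(st) && length(cl)) {
      sp <- pos[st, , drop = FALSE]
      cp <- pos[cl, , drop = FALSE]
      bound <- logical(length(st))
      for (d in seq_len(nrow(cp))) {
        dx <- sp - matrix(cp[d, ], nrow(sp), 3, byrow = TRUE)
        for (k in 1:3) {
          dx[, k] <- dx[, k] - traj$box[k] * round(dx[, k] / traj$box[k])
        }
        bound <- bound | rowSums(dx^2) <= binding_range^2
      }
      n_bound <- n_bound + sum(bound)
    }
  }
  nf <- length(traj$frames)
  rho_client <- n_cl / nf / vden
  rho_st <- n_st / nf / vden
  rho_bound <- n_bound / nf / vden
  rho_free <- rho_st - rho_bound
  undefined <- n_bound == 0
  KD <- if (undefined) Inf else rho_client * rho_free / rho_bound
  list(KD = KD, rho = rho_st, rho_client = rho_client,
       rho_bound = rho_bound, rho_free = rho_free, n_frames = nf,
       undefined = undefined)
}
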