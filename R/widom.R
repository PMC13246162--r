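# Hard-sphere Widom insertion: the free-energy cost of inserting a ghost
# sphere is F(R) = -kBT ln <exp(-U/kBT)>, and for a hard-sphere probe the
# Boltzmann factor is the indicator that no volume-excluding bead centre
# lies within R + rC of the probe centre.

#' Hard-sphere Widom insertion into trajectory frames
#'
#' Estimates the insertion free energy `F(R) = -ln(acceptance fraction)` in
#' kBT for each probe radius by test insertions on a deterministic uniform
#' grid (default, matching the published protocol) or at seeded random
#' positions.  Probes interact only with volume-excluding bead types
#' (stickers, being virtual patches, are ignored); an insertion is accepted
#' when no excluding bead centre lies within `R + rC` of the probe centre
#' (minimum-image distances, periodic in all directions).  The insertion
#' region restricts probe centres to an x slab, e.g. the bulk dense phase.
#'
#' @param traj A `cg_trajectory` (all frames share box and types).
#' @param radii Probe radii, nm (non-negative).
#' @param grid Integer length-3 grid shape `(nx, ny, nz)`, or NULL to use
#'   random sampling.
#' @param nrandom Number of random insertions per frame (random mode).
#' @param seed Seed for random-mode sampling.
#' @param region Optional x-slab `c(xlo, xhi)` for probe centres, in box
#'   coordinates `[0, Lx]`; NULL = whole box.
#' @param recenter Recentre each frame to the polymer centre of mass along x
#'   before applying `region` (so a region like `Lx/2 + c(-10, 10)` tracks
#'   the dense phase).
#' @param excluding Optional integer vector of excluding bead types;
#'   default: all non-virtual types, with their force-field radii.
#' @return A data.frame of class `widom_result` with columns `R`, `F`
#'   (kBT), `acceptance`, `se` (kBT, from per-frame block averaging) and
#'   `lower_bound` (TRUE where no insertion was accepted and `F` is only a
#'   lower bound, `-ln(1/n)`).
#' @export
insert_hard_spheres <- function(traj, radii, grid = c(64L, 64L, 64L),
                                nrandom = 1e5, seed = 1, region = NULL,
                                recenter = FALSE, excluding = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (any(radii < 0)) stop("probe radii must be non-negative")
  excl_rad <- traj$radius_by_type
  excl_rad[traj$virtual_by_type] <- NA_real_
  if (!is.null(excluding)) {
    keep <- rep(NA_real_, length(excl_rad))
    keep[excluding] <- traj$radius_by_type[excluding]
    excl_rad <- keep
  }
  Lx <- traj$box[1]
  if (is.null(region)) {
    reg <- c(0, Lx)
  } else {
    if (region[1] < 0 || region[2] > Lx || region[1] >= region[2]) {
      stop("region must be an increasing interval within [0, Lx]")
    }
    reg <- region
  }
  gd <- if (is.null(grid)) integer(0) else as.integer(grid)
  nf <- length(traj$frames)
  nr <- length(radii)
  acc <- matrix(0, nf, nr)
  tot <- numeric(nf)
  for (i in seq_len(nf)) {
    pos <- traj$frames[[i]]
    r0 <- reg
    if (recenter) {
      cx <- .circ_center(pos[traj$is_polymer, 1], Lx)
      shift <- Lx / 2 - cx
      pos[, 1] <- (pos[, 1] + shift) %% Lx
    }
    out <- cs_widom(pos, traj$type, traj$box, excl_rad, radii, gd,
                    as.integer(nrandom), as.integer(seed + i), r0[1], r0[2])
    acc[i, ] <- out$accepted
    tot[i] <- out$total
  }
  p <- colSums(acc) / sum(tot)
  lower <- p == 0
  Fk <- ifelse(lower, log(sum(tot)), -log(p))
  # per-frame (block) standard error of F via the delta method
  se <- rep(NA_real_, nr)
  if (nf > 1) {
    pf <- sweep(acc, 1, tot, "/")
    se_p <- apply(pf, 2, stats::sd) / sqrt(nf)
    se <- ifelse(p > 0, se_p / p, NA_real_)
  }
  res <- data.frame(R = radii, F = Fk, acceptance = p, se = se,
                    lower_bound = lower)
  class(res) <- c("widom_result", "data.frame")
  res
}

#' Pressure-volume correction of insertion free energies
#'
#' Homogeneous polymer solutions are held at an osmotic pressure `Pi`, so a
#' raw insertion free energy includes the pressure-volume work
#' `Pi * (4 pi/3) R^3`.  Dense and dilute condensate phases coexist at equal
#' pressure, so this term must be subtracted before comparing phases:
#' \deqn{\Delta F(R) = F(R) - \Pi \tfrac{4\pi}{3} R^3 / k_B T.}
#'
#' @param F Insertion free energies in kBT (or a `widom_result`).
#' @param R Probe radii, nm (taken from the `widom_result` if given).
#' @param pressure Osmotic pressure in Pa.
#' @param temperature Kelvin.
#' @return Corrected free energies (kBT); for a `widom_result` input, the
#'   data.frame gains a `deltaF` column.
#' @export
pv_correction <- function(F, R = NULL, pressure, temperature = 300) {
  if (inherits(F, "widom_result")) {
    F$deltaF <- pv_correction(F$F, F$R, pressure, temperature)
    return(F)
  }
  if (is.null(R)) stop("R required when F is a plain vector")
  kT <- 1.380649e-23 * temperature
  F - pressure * 4 / 3 * pi * (R * 1e-9)^3 / kT
}

#' Partition coefficient from dense/dilute insertion free energies
#'
#' `P = exp(-(F_dense - F_dilute))`, the Widom route to the dense/dilute
#' concentration ratio.  If the dense-phase value is only a lower bound
#' (zero acceptances), the result is an upper bound on P.
#'
#' @param F_dense,F_dilute Insertion free energies in kBT.
#' @return Partition coefficient(s).
#' @export
partition_from_widom <- function(F_dense, F_dilute = 0) {
  if (any(!is.finite(F_dense)) || any(!is.finite(F_dilute))) {
    stop("free energies must be finite")
  }
  exp(-(F_dense - F_dilute))
}
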