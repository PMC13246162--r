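# Force field for the sticker-spacer model.  Four bead types:
#   A, B  stickers (virtual patches, radius 0.3 nm): heterotypic A-B soft
#         attraction, homotypic WCA repulsion, no interaction with C or D
#   C     spacers (volume-excluding)
#   D     neutral/client particles (volume-excluding)
# WCA repulsion acts between AA, BB, CC, DD and CD with sigma_ij = ri + rj.

.type_labels <- c("A", "B", "C", "D")

#' Sticker-spacer force field
#'
#' Builds the interaction tables for a coarse-grained sticker-spacer system.
#' Three presets reproduce the published parameterisations:
#' \describe{
#'   \item{`"compact"`}{folded-module spacers of radius 1 nm on loose FENE
#'     backbones (k = 0.129 kBT/nm2, rmax = 14.03 nm), stickers on stiff
#'     harmonic bonds (kb = 100 kBT/nm2, rb = 1 nm), sticker attraction
#'     U0 = 18.8 kBT.}
#'   \item{`"idr"`}{amino-acid-sized spacers of radius 0.3 nm on stiff
#'     harmonic backbones (kb = 692 kBT/nm2, rb = 0.38 nm), sticker bonds
#'     kb = 1111 kBT/nm2, rb = 0.3 nm, U0 = 18 kBT.}
#'   \item{`"spacers_only"`}{the `"idr"` chain with all stickers removed;
#'     lighter beads (0.0565 ag) for the homogeneous-solution runs.}
#' }
#' All repelling pairs use a WCA potential with epsilon = 1 kBT.  An optional
#' client attraction (depth `client_eps`, centred at the particle radius
#' `client_R` with range `client_ra`) acts between stickers and D particles.
#'
#' @param preset One of `"compact"`, `"idr"`, `"spacers_only"`.
#' @param U0 Sticker-sticker attraction depth in kBT (preset default if NULL).
#' @param eps WCA repulsion strength in kBT.
#' @param client_eps Client-sticker attraction depth in kBT (0 = neutral
#'   particles).
#' @param client_R Centre of the client attraction well, nm.
#' @param client_ra Half-range of the client attraction, nm.
#' @return An object of class `cg_forcefield`.
#' @examples
#' ff <- cg_forcefield("compact")
#' ff$bead_types
#' @export
cg_forcefield <- function(preset = c("compact", "idr", "spacers_only"),
                          U0 = NULL, eps = 1,
                          client_eps = 0, client_R = 1.5, client_ra = 0.3) {
  preset <- match.arg(preset)
  nt <- 4L
  radius <- switch(preset,
    compact = c(0.3, 0.3, 1.0, 1.5),
    idr = c(0.3, 0.3, 0.3, 1.5),
    spacers_only = c(0.3, 0.3, 0.3, 1.5))
  mass <- switch(preset,
    compact = c(5.65, 5.65, 18.85, 28.27),
    idr = c(5.65, 5.65, 5.65, 28.27),
    spacers_only = c(5.65, 5.65, 0.0565, 28.27))
  if (is.null(U0)) U0 <- switch(preset, compact = 18.8, idr = 18,
                                spacers_only = 0)

  zero <- matrix(0, nt, nt, dimnames = list(.type_labels, .type_labels))
  pair_eps <- zero; pair_sigma <- zero
  for (p in list(c(1, 1), c(2, 2), c(3, 3), c(4, 4), c(3, 4))) {
    i <- p[1]; j <- p[2]
    pair_eps[i, j] <- pair_eps[j, i] <- eps
    pair_sigma[i, j] <- pair_sigma[j, i] <- radius[i] + radius[j]
  }
  soft_u0 <- zero; soft_r0 <- zero
  if (U0 > 0) {
    soft_u0[1, 2] <- soft_u0[2, 1] <- U0
    soft_r0[1, 2] <- soft_r0[2, 1] <- 0.3
  }
  cl_eps <- zero; cl_R <- zero; cl_ra <- zero
  if (client_eps != 0) {
    for (i in 1:2) {
      cl_eps[i, 4] <- cl_eps[4, i] <- client_eps
      cl_R[i, 4] <- cl_R[4, i] <- client_R
      cl_ra[i, 4] <- cl_ra[4, i] <- client_ra
    }
  }

  bond_classes <- switch(preset,
    compact = data.frame(
      name = c("backbone", "sticker"),
      style = c(0L, 1L),              # 0 = FENE, 1 = harmonic
      p1 = c(0.129, 100), p2 = c(14.03, 1.0)),
    idr = data.frame(
      name = c("backbone", "sticker"),
      style = c(1L, 1L),
      p1 = c(692, 1111), p2 = c(0.38, 0.3)),
    spacers_only = data.frame(
      name = "backbone", style = 1L, p1 = 692, p2 = 0.38))

  structure(list(
    preset = preset,
    bead_types = data.frame(label = .type_labels, radius = radius,
                            mass = mass,
                            is_virtual_patch = c(TRUE, TRUE, FALSE, FALSE)),
    pair_eps = pair_eps, pair_sigma = pair_sigma,
    soft_u0 = soft_u0, soft_r0 = soft_r0,
    client_eps = cl_eps, client_R = cl_R, client_ra = cl_ra,
    U0 = U0, bond_classes = bond_classes
  ), class = "cg_forcefield")
}

#' @export
print.cg_forcefield <- function(x, ...) {
  cat(sprintf("cg_forcefield (preset '%s'): U0 = %g kBT, client eps = %g kBT\n",
              x$preset, x$U0, max(x$client_eps)))
  print(x$bead_types)
  invisible(x)
}

# list layout the C++ core expects
.ff_cpp <- function(ff) {
  list(pair_eps = ff$pair_eps, pair_sigma = ff$pair_sigma,
       soft_u0 = ff$soft_u0, soft_r0 = ff$soft_r0,
       client_eps = ff$client_eps, client_R = ff$client_R,
       client_ra = ff$client_ra)
}

# --- reference pair/bond potentials (pure R; used for documentation and as
# an independent check of the compiled kernels) ------------------------------

#' Pair and bond potentials of the sticker-spacer model
#'
#' Scalar reference implementations of the individual interaction terms, in
#' kBT: `u_wca()` the purely repulsive truncated-and-shifted 12-6 potential
#' (cutoff at its minimum, `2^(1/6) sigma`), `u_fene()` the finitely
#' extensible backbone bond, `u_harmonic()` the stiff sticker bond
#' `kb (r - rb)^2`, `u_soft()` the sticker-sticker attraction
#' `-U0/2 (1 + cos(pi r / r0))` for `r < r0`, and `u_client()` the
#' client-sticker attraction `-eps/2 (1 + cos(pi (r - R)/ra))` on
#' `R - ra <= r <= R + ra`.
#'
#' @param r Separation, nm (vectorised).
#' @param eps,sigma WCA strength (kBT) and range (nm).
#' @param k,rmax FENE strength (kBT/nm2) and maximum extension (nm).
#' @param kb,rb Harmonic strength (kBT/nm2) and rest length (nm).
#' @param U0,r0 Soft-attraction depth (kBT) and range (nm).
#' @param R,ra Client-attraction well centre and half-range (nm).
#' @return Potential energy in kBT.
#' @name pair_potentials
NULL

#' @rdname pair_potentials
#' @export
u_wca <- function(r, eps = 1, sigma = 1) {
  ifelse(r < 2^(1 / 6) * sigma,
         4 * eps * ((sigma / r)^12 - (sigma / r)^6) + eps, 0)
}

#' @rdname pair_potentials
#' @export
u_fene <- function(r, k = 0.129, rmax = 14.03) {
  if (any(r >= rmax)) stop("FENE bond overextended (r >= rmax)")
  -0.5 * k * rmax^2 * log(1 - (r / rmax)^2)
}

#' @rdname pair_potentials
#' @export
u_harmonic <- function(r, kb, rb) kb * (r - rb)^2

#' @rdname pair_potentials
#' @export
u_soft <- function(r, U0 = 18.8, r0 = 0.3) {
  ifelse(r < r0, -U0 / 2 * (1 + cos(pi * r / r0)), 0)
}

#' @rdname pair_potentials
#' @export
u_client <- function(r, eps, R = 1.5, ra = 0.3) {
  ifelse(r >= R - ra & r <= R + ra,
         -eps / 2 * (1 + cos(pi * (r - R) / ra)), 0)
}
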