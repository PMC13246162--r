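# Polymer architectures.  A topology holds one molecule template (bead types
# and bonds) plus system counts; build_system() replicates it into a box.

#' Sticker-spacer polymer topology
#'
#' Describes the system composition: a polymer template plus a number of free
#' neutral/client particles.  Presets:
#' \describe{
#'   \item{`"compact_spacer"`}{a linear chain of `n_spacers` (default 10)
#'     radius-1-nm C beads on FENE bonds; a type-A sticker on each spacer in
#'     the first half of the chain and a type-B sticker on each spacer in the
#'     second half, attached by harmonic bonds.}
#'   \item{`"idr_spacer"`}{a linear chain of `n_spacers` (default 450)
#'     radius-0.3-nm C beads on stiff harmonic bonds; one sticker attached to
#'     every `sticker_every`-th spacer (default 8), type A in the first half
#'     of the chain, type B in the second half.}
#'   \item{`"spacers_only"`}{the `"idr_spacer"` chain with all stickers
#'     removed (self-avoiding bead-spring chain).}
#' }
#'
#' @param preset Template name.
#' @param n_polymers Number of polymer chains.
#' @param n_particles Number of free type-D particles.
#' @param n_spacers Spacers per chain (preset default if NULL).
#' @param sticker_every Sticker spacing along the IDR chain.
#' @return An object of class `cg_topology`.
#' @examples
#' cg_topology("compact_spacer", n_polymers = 50, n_particles = 50)
#' @export
cg_topology <- function(preset = c("compact_spacer", "idr_spacer",
                                   "spacers_only"),
                        n_polymers = 1, n_particles = 0,
                        n_spacers = NULL, sticker_every = 8) {
  preset <- match.arg(preset)
  if (n_polymers < 0 || n_particles < 0) stop("counts must be non-negative")
  if (is.null(n_spacers)) {
    n_spacers <- if (preset == "compact_spacer") 10L else 450L
  }
  n_spacers <- as.integer(n_spacers)

  type <- integer(0); bonds <- matrix(integer(0), 0, 3)
  if (n_spacers > 0 && preset == "compact_spacer") {
    type <- rep(3L, n_spacers)                      # C backbone
    if (n_spacers > 1) {
      bonds <- cbind(1:(n_spacers - 1), 2:n_spacers, 1L)
    }
    half <- n_spacers / 2
    st_type <- ifelse(seq_len(n_spacers) <= half, 1L, 2L)
    st_idx <- n_spacers + seq_len(n_spacers)
    type <- c(type, st_type)
    bonds <- rbind(bonds, cbind(seq_len(n_spacers), st_idx, 2L))
  } else if (n_spacers > 0) {
    type <- rep(3L, n_spacers)
    if (n_spacers > 1) {
      bonds <- cbind(1:(n_spacers - 1), 2:n_spacers, 1L)
    }
    if (preset == "idr_spacer") {
      host <- seq(sticker_every, n_spacers, by = sticker_every)
      if (length(host)) {
        st_type <- ifelse(host <= n_spacers / 2, 1L, 2L)
        st_idx <- n_spacers + seq_along(host)
        type <- c(type, st_type)
        bonds <- rbind(bonds, cbind(host, st_idx, 2L))
      }
    }
  }
  storage.mode(bonds) <- "integer"
  structure(list(
    preset = preset, n_polymers = as.integer(n_polymers),
    n_particles = as.integer(n_particles), n_spacers = n_spacers,
    sticker_every = as.integer(sticker_every),
    template_type = type, template_bonds = bonds,
    beads_per_polymer = length(type)
  ), class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf(
    "cg_topology '%s': %d polymers x %d beads (%d spacers) + %d particles\n",
    x$preset, x$n_polymers, x$beads_per_polymer, x$n_spacers, x$n_particles))
  invisible(x)
}

#' Matching force-field preset for a topology
#' @param topology A [cg_topology()].
#' @param ... Passed to [cg_forcefield()] (e.g. `client_eps`).
#' @return A `cg_forcefield`.
#' @export
default_forcefield <- function(topology, ...) {
  cg_forcefield(switch(topology$preset,
    compact_spacer = "compact", idr_spacer = "idr",
    spacers_only = "spacers_only"), ...)
}
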