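# Independent oracles used across test files.  These deliberately avoid the
# package's compiled kernels: plain-R distance arithmetic only.

# minimum-image displacement
mi <- function(d, L) d - L * round(d / L)

# brute-force Monte Carlo hard-sphere insertion: fraction of `npts` random
# probe centres with no bead centre within R + rC
mc_insertion_oracle <- function(pos, box, rC, R, npts, seed) {
  set.seed(seed)
  hits <- 0L
  for (k in seq_len(npts)) {
    p <- stats::runif(3) * box
    if (nrow(pos) == 0) {
      hits <- hits + 1L
      next
    }
    dx <- mi(pos[, 1] - p[1], box[1])
    dy <- mi(pos[, 2] - p[2], box[2])
    dz <- mi(pos[, 3] - p[3], box[3])
    if (min(sqrt(dx^2 + dy^2 + dz^2) - rC) > R) hits <- hits + 1L
  }
  hits / npts
}

# analytic derivatives of the pair potentials (closed forms for force checks)
du_wca <- function(r, eps = 1, sigma = 1) {
  ifelse(r < 2^(1 / 6) * sigma,
         4 * eps * (-12 * sigma^12 / r^13 + 6 * sigma^6 / r^7), 0)
}
du_soft <- function(r, U0, r0) {
  ifelse(r < r0, U0 / 2 * sin(pi * r / r0) * pi / r0, 0)
}
du_harmonic <- function(r, kb, rb) 2 * kb * (r - rb)
du_fene <- function(r, k, rmax) k * r / (1 - (r / rmax)^2)
du_client <- function(r, eps, R, ra) {
  ifelse(r >= R - ra & r <= R + ra,
         eps / 2 * sin(pi * (r - R) / ra) * pi / ra, 0)
}

# two-bead system helper: one pair at distance r along x in a large box
two_bead_system <- function(types, r, box = c(30, 30, 30),
                            bonds = matrix(integer(0), 0, 3)) {
  storage.mode(bonds) <- "integer"
  structure(list(
    pos = rbind(c(10, 10, 10), c(10 + r, 10, 10)),
    vel = matrix(0, 2, 3), type = as.integer(types),
    mol = c(1L, 2L), is_polymer = c(FALSE, FALSE),
    bonds = bonds, box = box), class = "cg_system")
}
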