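# Closed-form size-exclusion and recruitment theory for condensates whose
# scaffolds carry intrinsically disordered regions (IDRs).  Lengths are in nm,
# energies in units of kBT, pressures in Pa at the SI interface only.

#' Boltzmann constant, SI
#' @keywords internal
.kB <- 1.380649e-23

#' Default Flory exponent for self-avoiding chains in 3D
#' @keywords internal
.nu_default <- 0.588

#' Semidilute polymer solution specification
#'
#' Bundles the quantities needed to convert an IDR volume fraction into a
#' correlation length (blob size): the volume fraction `phi`, the monomer
#' diameter `d` (nm), the dimensionless scaling prefactor `c`, and the Flory
#' exponent `nu`.
#'
#' @param phi IDR volume fraction, strictly inside (0, 1).
#' @param d Monomer diameter in nm (default 0.6 nm, twice the 0.3 nm radius of
#'   an average amino acid).
#' @param c Dimensionless prefactor of the blob-scaling law (default 0.68,
#'   calibrated on fully flexible self-avoiding chains).
#' @param nu Flory exponent (default 0.588).
#' @return An object of class `polymer_solution`.
#' @examples
#' ps <- polymer_solution(phi = 0.036)
#' correlation_length(ps)
#' @export
polymer_solution <- function(phi, d = 0.6, c = 0.68, nu = .nu_default) {
  stopifnot(is.numeric(phi), is.numeric(d), is.numeric(c), is.numeric(nu))
  if (any(phi <= 0 | phi >= 1)) {
    stop("phi must lie strictly inside (0, 1)")
  }
  if (d <= 0 || c <= 0) stop("d and c must be positive")
  if (nu <= 0.5 || nu >= 1) stop("nu must lie in (0.5, 1)")
  structure(list(phi = phi, d = d, c = c, nu = nu),
            class = "polymer_solution")
}

#' @export
print.polymer_solution <- function(x, ...) {
  cat(sprintf(
    "polymer_solution: phi = %s, d = %g nm, c = %g, nu = %g -> xi = %s nm\n",
    paste(signif(x$phi, 4), collapse = ", "), x$d, x$c, x$nu,
    paste(signif(correlation_length(x), 4), collapse = ", ")))
  invisible(x)
}

#' Correlation length (blob size) from the IDR volume fraction
#'
#' Evaluates the semidilute blob-scaling law
#' \deqn{\xi = c\, d\, \phi^{-\nu/(3\nu - 1)},}
#' the mesh scale of a solution of self-avoiding chains at volume fraction
#' \eqn{\phi} with monomer diameter \eqn{d}.  \eqn{\xi} is the operative size
#' cutoff for entropic exclusion: particles larger than about \eqn{\xi/2}
#' in radius pay a steep free-energy cost to enter.
#'
#' @param spec A [polymer_solution()], or a numeric vector of volume fractions
#'   (in which case `d`, `c`, `nu` supply the remaining parameters).
#' @param d,c,nu Used only when `spec` is numeric; see [polymer_solution()].
#' @return Correlation length(s) in nm, strictly decreasing in `phi`.
#' @examples
#' correlation_length(0.036)           # ~5.24 nm (LAF-1-like condensate)
#' correlation_length(0.05)            # ~4.1 nm  (typical condensate)
#' @export
correlation_length <- function(spec, d = 0.6, c = 0.68, nu = .nu_default) {
  if (!inherits(spec, "polymer_solution")) {
    spec <- polymer_solution(spec, d = d, c = c, nu = nu)
  }
  spec$c * spec$d * spec$phi^(-spec$nu / (3 * spec$nu - 1))
}

#' Correlation length from the osmotic pressure
#'
#' In the blob picture the osmotic pressure of a semidilute solution is
#' \eqn{\Pi = (3\nu - 1) k_B T / \xi^3} (unit prefactor), so
#' \deqn{\xi = \left[\frac{k_B T}{(3\nu - 1)\,\Pi}\right]^{1/3}.}
#' This is how \eqn{\xi} is extracted from simulated spacers-only systems,
#' whose pressure is directly measurable.
#'
#' @param pressure Osmotic pressure in Pa (vectorised).
#' @param temperature Temperature in K (default 300).
#' @param nu Flory exponent (default 0.588).
#' @return Correlation length(s) in nm.
#' @examples
#' correlation_length_from_pressure(0.25e6)   # ~2.79 nm
#' correlation_length_from_pressure(0.024e6)  # ~6.10 nm
#' @export
correlation_length_from_pressure <- function(pressure, temperature = 300,
                                             nu = .nu_default) {
  if (any(!is.finite(pressure)) || any(pressure <= 0)) {
    stop("pressure must be positive and finite")
  }
  if (temperature <= 0) stop("temperature must be positive")
  xi_m <- (.kB * temperature / ((3 * nu - 1) * pressure))^(1 / 3)
  xi_m * 1e9
}

#' Insertion-model parameters
#'
#' The two dimensionless prefactors of the unified insertion free-energy
#' expression (see [insertion_free_energy()]) together with the Flory
#' exponent.  Defaults are the values obtained from a global fit to Widom
#' insertion into simulated self-avoiding polymer solutions.
#'
#' @param a1 Prefactor of the small-particle (correlation-hole) term.
#' @param a2 Prefactor of the large-particle (surface) term.
#' @param nu Flory exponent.
#' @return An object of class `insertion_model`.
#' @export
insertion_model <- function(a1 = 4.18, a2 = 7.24, nu = .nu_default) {
  if (a1 <= 0 || a2 <= 0) stop("a1 and a2 must be positive")
  if (nu <= 0.5 || nu >= 1) stop("nu must lie in (0.5, 1)")
  structure(list(a1 = a1, a2 = a2, nu = nu), class = "insertion_model")
}

#' @export
print.insertion_model <- function(x, ...) {
  cat(sprintf("insertion_model: a1 = %g, a2 = %g, nu = %g\n",
              x$a1, x$a2, x$nu))
  invisible(x)
}

#' Free-energy cost of inserting a neutral sphere into an IDR solution
#'
#' The unified expression
#' \deqn{\Delta F / k_B T = a_1 (R/\xi)^{3 - 1/\nu} + a_2 (R/\xi)^2
#'   - \ln(1 - \phi)}
#' interpolates between the small-particle scaling \eqn{(R/\xi)^{3-1/\nu}}
#' and the large-particle surface scaling \eqn{(R/\xi)^2}, augmented by the
#' volume-reduction cost \eqn{-\ln(1-\phi)} of inserting even a point
#' particle.
#'
#' @param R Probe radius in nm (vectorised).
#' @param xi Correlation length in nm.
#' @param phi Polymer volume fraction in `[0, 1)`; the `-ln(1-phi)` term is
#'   dropped when `phi = 0`.
#' @param model An [insertion_model()].
#' @return Free energy in kBT; zero at `R = 0`, `phi = 0`, monotone
#'   increasing in both `R` and `phi`.
#' @examples
#' xi <- correlation_length(0.036)
#' insertion_free_energy(c(1.9, 6.5, 8.9), xi, 0.036)  # ~2.1, 17, 29 kBT
#' @export
insertion_free_energy <- function(R, xi, phi = 0, model = insertion_model()) {
  stopifnot(inherits(model, "insertion_model"))
  if (any(R < 0)) stop("R must be non-negative")
  if (any(xi <= 0)) stop("xi must be positive")
  if (any(phi < 0 | phi >= 1)) stop("phi must lie in [0, 1)")
  x <- R / xi
  model$a1 * x^(3 - 1 / model$nu) + model$a2 * x^2 - log1p(-phi)
}

#' Large-intruder (surface-scaling) limit of the insertion free energy
#'
#' For probes much larger than the correlation length the insertion cost is
#' dominated by the surface term \eqn{a_2 (R/\xi)^2}; with \eqn{\xi} from the
#' blob-scaling law this gives
#' \eqn{\Delta F/k_B T \sim R^2 \phi^{2\nu/(3\nu-1)}}, i.e. scaling with the
#' intruder surface area and steeply (exponent ~1.54) with volume fraction.
#'
#' @param R Probe radius in nm (intended for `R >> xi`).
#' @param spec A [polymer_solution()] (or a numeric `phi`).
#' @param model An [insertion_model()].
#' @inheritParams correlation_length
#' @return The surface term in kBT.
#' @export
large_intruder_limit <- function(R, spec, model = insertion_model(),
                                 d = 0.6, c = 0.68, nu = .nu_default) {
  if (!inherits(spec, "polymer_solution")) {
    spec <- polymer_solution(spec, d = d, c = c, nu = nu)
  }
  xi <- correlation_length(spec)
  model$a2 * (R / xi)^2
}

#' Partition coefficient from an insertion free energy
#'
#' \deqn{P = e^{-\Delta F / k_B T},}
#' the dense/dilute concentration ratio of a species whose transfer free
#' energy into the dense phase is `deltaF` (in kBT).
#'
#' @param deltaF Free-energy difference in kBT (vectorised).
#' @return Dimensionless partition coefficient.
#' @examples
#' partition_coefficient(3.5)  # ~0.03
#' @export
partition_coefficient <- function(deltaF) {
  if (any(!is.finite(deltaF))) stop("deltaF must be finite")
  exp(-deltaF)
}

#' IDR volume fraction from a condensate composition
#'
#' Converts a measured scaffold concentration into the volume fraction of
#' IDR monomers, modelling each residue as a sphere of radius
#' `monomer_radius`.  Two routes are supported and exactly one must be given:
#' \describe{
#'   \item{molar}{`molar_mM` (scaffold concentration in mM) together with
#'     `residues_per_scaffold` (number of residues in the scaffold's
#'     disordered regions).}
#'   \item{mass}{`mass_gL` (scaffold concentration in g/L) together with
#'     `idr_mass_fraction` and the residue mass `monomer_mass` (g/mol).}
#' }
#'
#' The arithmetic result can differ from independently reported volume
#' fractions for the same system (concentration estimates carry their own
#' uncertainty); when a `target_phi` is supplied the function warns if the
#' two disagree by more than 10%, and reported volume fractions should then
#' be preferred as direct inputs to [correlation_length()].
#'
#' @param molar_mM Scaffold concentration, mM (molar route).
#' @param residues_per_scaffold IDR residues per scaffold molecule.
#' @param mass_gL Scaffold concentration, g/L (mass route).
#' @param idr_mass_fraction Fraction of scaffold mass in IDRs, in `[0, 1]`.
#' @param monomer_mass Residue mass in g/mol (default 110).
#' @param monomer_radius Residue radius in nm (default 0.3).
#' @param target_phi Optional independently known volume fraction to compare
#'   against.
#' @return Volume fraction (dimensionless).
#' @examples
#' phi_from_composition(molar_mM = 2.6, residues_per_scaffold = 250)
#' phi_from_composition(mass_gL = 250, idr_mass_fraction = 0.4)
#' @export
phi_from_composition <- function(molar_mM = NULL, residues_per_scaffold = NULL,
                                 mass_gL = NULL, idr_mass_fraction = NULL,
                                 monomer_mass = 110, monomer_radius = 0.3,
                                 target_phi = NULL) {
  molar <- !is.null(molar_mM)
  mass <- !is.null(mass_gL)
  if (molar == mass) {
    stop("supply exactly one of molar_mM or mass_gL")
  }
  if (monomer_radius <= 0 || monomer_mass <= 0) {
    stop("monomer_radius and monomer_mass must be positive")
  }
  v_mono <- 4 / 3 * pi * monomer_radius^3      # nm^3
  avogadro <- 6.02214076e23
  if (molar) {
    if (is.null(residues_per_scaffold) || residues_per_scaffold <= 0) {
      stop("molar route requires residues_per_scaffold > 0")
    }
    if (molar_mM < 0) stop("concentration must be non-negative")
    # mM -> molecules per nm^3: 1e-3 mol/L * NA / 1e24 nm^3/L
    rho <- molar_mM * 1e-3 * avogadro / 1e24
    phi <- rho * residues_per_scaffold * v_mono
  } else {
    if (is.null(idr_mass_fraction) || idr_mass_fraction < 0 ||
        idr_mass_fraction > 1) {
      stop("mass route requires idr_mass_fraction in [0, 1]")
    }
    if (mass_gL < 0) stop("concentration must be non-negative")
    rho_res <- mass_gL * idr_mass_fraction / monomer_mass * avogadro / 1e24
    phi <- rho_res * v_mono
  }
  if (phi >= 1) {
    stop("composition implies volume fraction >= 1; inputs are inconsistent")
  }
  if (!is.null(target_phi) && phi > 0 &&
      abs(phi - target_phi) / target_phi > 0.1) {
    warning(sprintf(
      "computed phi = %.4f differs from target phi = %.4f by more than 10%%; %s",
      phi, target_phi,
      "prefer the directly reported volume fraction as input"))
  }
  phi
}

#' Recruitment free energy of a client
#'
#' Balances the favourable multivalent attraction to binding sites against
#' the entropic exclusion barrier:
#' \deqn{\Delta F_{client}/k_B T = -\sum_i \rho_i / K_{D,i} + \Delta F_0/k_B T,}
#' where \eqn{\rho_i} is the concentration of binding sites of type i,
#' \eqn{K_{D,i}} the per-site dissociation constant (same concentration
#' units), and \eqn{\Delta F_0} the neutral-particle exclusion free energy.
#' `method = "exact"` evaluates the finite-valency Poisson sum
#' \deqn{F_{attr}/k_BT = -\ln\!\big[e^{-\rho\Omega}\textstyle
#'   \sum_{n=0}^{n_{max}} (\rho/K_D)^n/n!\big]}
#' from which the limiting form follows when the typical number of bound
#' sites is far below the valency cap and \eqn{K_D \ll 1/\Omega}.
#'
#' @param rho Binding-site concentration(s), one per site type (nm^-3, or any
#'   units matching `KD`).
#' @param KD Dissociation constant(s), same length and units as `rho`.
#' @param deltaF0 Exclusion free energy in kBT.
#' @param method `"limiting"` (default) or `"exact"`.
#' @param Omega Interaction volume per binding site (nm^3), exact method only.
#' @param nmax Valency cap, exact method only.
#' @return Client recruitment free energy in kBT (negative = recruited).
#' @examples
#' recruitment_free_energy(rho = 0.05, KD = 0.01, deltaF0 = 3)
#' @export
recruitment_free_energy <- function(rho, KD, deltaF0,
                                    method = c("limiting", "exact"),
                                    Omega = NULL, nmax = NULL) {
  method <- match.arg(method)
  if (length(rho) != length(KD)) stop("rho and KD must have equal length")
  if (any(rho < 0)) stop("rho must be non-negative")
  if (any(KD <= 0)) stop("KD must be positive")
  if (!is.finite(deltaF0)) stop("deltaF0 must be finite")
  if (method == "limiting") {
    return(-sum(rho / KD) + deltaF0)
  }
  if (is.null(Omega) || is.null(nmax)) {
    stop("exact method requires Omega and nmax")
  }
  f_attr <- vapply(seq_along(rho), function(i) {
    n <- 0:nmax
    # log-sum-exp over the truncated Poisson-weighted binding series
    terms <- n * log(rho[i] / KD[i]) - lgamma(n + 1)
    m <- max(terms)
    -(-rho[i] * Omega + m + log(sum(exp(terms - m))))
  }, numeric(1))
  sum(f_attr) + deltaF0
}

#' Predict exclusion of probe particles from a condensate
#'
#' Convenience wrapper chaining the blob-scaling correlation length, the
#' unified insertion free energy and the Boltzmann partition coefficient for
#' a set of probe radii.
#'
#' @param R Probe radii in nm.
#' @param phi IDR volume fraction.
#' @param d,c,nu Blob-scaling parameters, see [polymer_solution()].
#' @param model An [insertion_model()].
#' @return A data.frame with columns `R`, `deltaF_kBT`, `P`.
#' @examples
#' predict_partitioning(c(1.9, 6.5, 8.9), phi = 0.036)
#' @export
predict_partitioning <- function(R, phi, d = 0.6, c = 0.68,
                                 nu = .nu_default, model = insertion_model()) {
  spec <- polymer_solution(phi, d = d, c = c, nu = nu)
  xi <- correlation_length(spec)
  dF <- insertion_free_energy(R, xi, phi, model)
  data.frame(R = R, deltaF_kBT = dF, P = partition_coefficient(dF))
}
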