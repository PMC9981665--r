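#' Internal unit system
#'
#' The package works throughout in the internal unit system of the CHARMM
#' force-field ecosystem: lengths in Angstrom, energies in kcal/mol, charges
#' in elementary charges e, time in ps and temperature in K. The Coulomb
#' constant \eqn{1/(4\pi\epsilon_0)} in these units is 332.0716
#' kcal Angstrom / (mol e^2) and the Boltzmann constant is
#' 0.0019872041 kcal/(mol K).
#'
#' @param coulomb_constant Coulomb prefactor in kcal Angstrom mol^-1 e^-2.
#' @param boltzmann_constant Boltzmann constant in kcal mol^-1 K^-1.
#' @return An object of class `unit_system`: a list with fields
#'   `coulomb_constant`, `boltzmann_constant` and the conversion factors
#'   `kcal_per_akma` (1 kcal/mol expressed in u Angstrom^2/ps^2, used by the
#'   Brownian propagator), `A2ps_to_m2s` (Angstrom^2/ps to m^2/s) and
#'   `cond_to_mS_cm` (internal conductivity units to mS/cm).
#' @examples
#' u <- charmm_units()
#' u$coulomb_constant
#' @export
charmm_units <- function(coulomb_constant = 332.0716,
                         boltzmann_constant = 0.0019872041) {
  stopifnot(is.numeric(coulomb_constant), coulomb_constant > 0,
            is.numeric(boltzmann_constant), boltzmann_constant > 0)
  # SI anchors used for reporting conversions
  e_C <- 1.602176634e-19      # C
  N_A <- 6.02214076e23        # 1/mol
  kcal_J <- 4184              # J per kcal
  # internal conductivity unit: e^2 mol / (ps Angstrom kcal)  ->  S/m
  cond_SI <- e_C^2 * 1e12 * 1e10 * N_A / kcal_J
  structure(list(
    length = "angstrom", energy = "kcal/mol", charge = "e",
    time = "ps", temperature = "K",
    coulomb_constant = coulomb_constant,
    boltzmann_constant = boltzmann_constant,
    kcal_per_akma = kcal_J / 10,      # 1 kcal/mol = 418.4 u A^2 / ps^2
    A2ps_to_m2s = 1e-8,
    cond_to_mS_cm = cond_SI * 10      # S/m -> mS/cm is a factor 10
  ), class = "unit_system")
}

#' Drude charge from atomic polarizability
#'
#' In the Drude-oscillator model of electronic polarization, a mobile charged
#' particle is bound to its parent atom by a harmonic spring whose force
#' constant k relates the Drude charge q and the atomic polarizability alpha
#' via k = C q^2 / alpha, with C the Coulomb constant. This inverts the
#' relation for the (negative, by convention) Drude charge.
#'
#' @param alpha Atomic polarizability in Angstrom^3 (> 0).
#' @param k Spring force constant in kcal mol^-1 Angstrom^-2 (> 0); the
#'   customary simulation value is 1000.
#' @param units A [charmm_units()] object.
#' @return The Drude charge in e, negative.
#' @examples
#' drude_charge(1.0, 1000)  # about -1.7353 e
#' @export
drude_charge <- function(alpha, k = 1000, units = charmm_units()) {
  if (!is.numeric(alpha) || any(alpha <= 0))
    stop("polarizability `alpha` must be > 0", call. = FALSE)
  if (!is.numeric(k) || any(k <= 0))
    stop("force constant `k` must be > 0", call. = FALSE)
  -sqrt(k * alpha / units$coulomb_constant)
}

#' Drude spring force constant from charge and polarizability
#'
#' Companion to [drude_charge()]: k = C q^2 / alpha.
#'
#' @param q Drude charge in e (sign ignored).
#' @param alpha Atomic polarizability in Angstrom^3 (> 0).
#' @param units A [charmm_units()] object.
#' @return Force constant in kcal mol^-1 Angstrom^-2.
#' @export
drude_force_constant <- function(q, alpha, units = charmm_units()) {
  if (!is.numeric(alpha) || any(alpha <= 0))
    stop("polarizability `alpha` must be > 0", call. = FALSE)
  units$coulomb_constant * q^2 / alpha
}

#' Polarizability-dependent Lennard-Jones epsilon scaling
#'
#' When Drude particles carry part of the dispersion interaction, the
#' Lennard-Jones well depths of the polarizable atoms are reduced to avoid
#' double counting. The reduction is a smooth function of the atomic
#' polarizability:
#' \deqn{\epsilon = \epsilon^{nonpol} \frac{\Delta\alpha + s\,\alpha_{max}}
#'       {s\,\Delta\alpha + \alpha_{max}}, \qquad
#'       \Delta\alpha = \alpha_{max} - \alpha}
#' so that an atom with zero polarizability keeps its full epsilon and the
#' most polarizable atom (alpha = alpha_max) has it scaled by s.
#'
#' @param eps_nonpol Unscaled well depth (kcal/mol, magnitude).
#' @param alpha Polarizability of the atom, Angstrom^3, in `[0, alpha_max]`.
#' @param alpha_max Largest atomic polarizability in the system, Angstrom^3.
#' @param s Scaling factor in (0, 1]; the study systems use 0.25 and 0.4.
#' @return Scaled epsilon, between `s * eps_nonpol` and `eps_nonpol`.
#' @examples
#' scale_lj_epsilon(0.10, 1.0, 2.0, 0.25)  # 0.0667
#' @export
scale_lj_epsilon <- function(eps_nonpol, alpha, alpha_max, s) {
  stopifnot(is.numeric(eps_nonpol), is.numeric(alpha),
            is.numeric(alpha_max), is.numeric(s))
  if (any(s <= 0) || any(s > 1))
    stop("scaling factor `s` must be in (0, 1]", call. = FALSE)
  if (any(alpha < 0) || any(alpha > alpha_max))
    stop("`alpha` must lie in [0, alpha_max]", call. = FALSE)
  d_alpha <- alpha_max - alpha
  eps_nonpol * (d_alpha + s * alpha_max) / (s * d_alpha + alpha_max)
}

#' Total Drude self-polarization energy
#'
#' The energy stored in all Drude springs, U = sum_i k_i |d_i|^2, with d_i
#' the displacement between the mobile Drude particle and its parent atom.
#'
#' @param displacements Numeric matrix (n x 3) of displacement vectors in
#'   Angstrom, or a numeric vector of displacement magnitudes.
#' @param k Spring force constant(s), kcal mol^-1 Angstrom^-2; recycled.
#' @return Self-polarization energy in kcal/mol (>= 0).
#' @examples
#' self_polarization_energy(matrix(c(0.1, 0, 0), 1, 3), 1000)  # 10
#' @export
self_polarization_energy <- function(displacements, k = 1000) {
  if (!is.numeric(k) || any(k <= 0))
    stop("force constant `k` must be > 0", call. = FALSE)
  if (is.matrix(displacements)) {
    d2 <- rowSums(displacements^2)
  } else {
    d2 <- as.numeric(displacements)^2
  }
  sum(k * d2)
}
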