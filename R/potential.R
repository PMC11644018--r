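#' Stand-in flexible 3-site water potential
#'
#' Interaction model used both by the MD engine and by the energetic bond
#' criterion.  Electrostatics use partial charges of -0.66 e (O) and
#' +0.33 e (H), which with the gas-phase geometry give a molecular dipole
#' moment of about 1.86 D.  Intramolecular flexibility is harmonic (two OH
#' stretches plus one HOH bend); the intermolecular short-range term is a
#' Lennard-Jones O-O interaction.  The intramolecular stiffnesses are
#' deliberately moderate so that a 0.1 fs velocity-Verlet step resolves all
#' internal modes to a total-energy stability of order 1e-5 or better; the
#' model is a documented stand-in, not a literature water potential.
#'
#' @param q_o,q_h partial charges (e); must satisfy `q_o + 2*q_h == 0`.
#' @param k_bond OH stretch stiffness (kJ/mol/nm^2).
#' @param r_bond equilibrium OH length (nm).
#' @param k_angle HOH bend stiffness (kJ/mol/rad^2).
#' @param theta0_deg equilibrium HOH angle (degrees).
#' @param lj_eps,lj_sigma Lennard-Jones O-O well depth (kJ/mol) and size (nm).
#' @param c_ohrep coefficient of the steep intermolecular O-H repulsion
#'   `c/r^16` (kJ/mol nm^16) that shields the bare Coulomb attraction
#'   between unlike sites, as in central-force-family flexible models; the
#'   default arrests O..H approach near 0.15 nm while adding well under
#'   1 kJ/mol at hydrogen-bonding separations (>= 0.18 nm).
#' @param cutoff real-space/short-range cutoff (nm); shifted-force applied.
#' @param ewald_accuracy dimensionless damping parameter s: the Ewald
#'   splitting is `alpha = s / cutoff` and the reciprocal sum includes wave
#'   vectors up to `k_max = 2 s alpha`.
#' @return list of class `hb_potential`.
#' @export
water_potential <- function(q_o = -0.66, q_h = 0.33,
                            k_bond = 2e4, r_bond = 0.09572,
                            k_angle = 300, theta0_deg = 104.52,
                            lj_eps = 0.65, lj_sigma = 0.3166,
                            c_ohrep = 8.4e-13,
                            cutoff = 0.6, ewald_accuracy = 3.2) {
  if (abs(q_o + 2 * q_h) > 1e-12)
    stop("molecule must be charge neutral: q_o + 2*q_h == 0")
  stopifnot(k_bond > 0, r_bond > 0, k_angle > 0, lj_sigma > 0, cutoff > 0,
            ewald_accuracy > 0)
  structure(list(q_o = q_o, q_h = q_h, k_bond = k_bond, r_bond = r_bond,
                 k_angle = k_angle, theta0 = theta0_deg * pi / 180,
                 lj_eps = lj_eps, lj_sigma = lj_sigma, c_ohrep = c_ohrep,
                 cutoff = cutoff,
                 ewald_accuracy = ewald_accuracy,
                 ewald_alpha = ewald_accuracy / cutoff,
                 ewald_kmax = NA_integer_),
            class = "hb_potential")
}

# Fill box-dependent Ewald parameters; kmax covers |k| <= 2*s*alpha.
finalize_potential <- function(potential, box_length) {
  stopifnot(inherits(potential, "hb_potential"))
  if (potential$cutoff >= box_length / 2)
    stop(sprintf("cutoff (%.3f nm) must be below half the box (%.3f nm)",
                 potential$cutoff, box_length / 2))
  s <- potential$ewald_accuracy
  alpha <- s / potential$cutoff
  potential$ewald_alpha <- alpha
  potential$ewald_kmax <-
    max(4L, as.integer(ceiling(2 * s * alpha * box_length / (2 * pi))))
  potential
}
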