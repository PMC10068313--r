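#' Laminar flow chamber geometry
#'
#' Rectangular channel dimensions. Defaults are a 12 mm long channel with a
#' 2 x 0.250 mm cross-section.
#'
#' @param length_mm channel length, mm.
#' @param width_mm channel width l, mm.
#' @param height_mm channel height H, mm.
#' @return Object of class `chamber_geometry`.
#' @export
chamber_geometry <- function(length_mm = 12, width_mm = 2, height_mm = 0.25) {
  stopifnot(length_mm > 0, width_mm > 0, height_mm > 0)
  structure(list(length_mm = length_mm, width_mm = width_mm, height_mm = height_mm),
            class = "chamber_geometry")
}

#' Microsphere and tether model
#'
#' Bead radius, medium viscosity, bond (tether) length and the hydrodynamic
#' coefficients for a sphere held at a wall in shear flow: translational drag
#' `R = drag_coeff * mu * a^2 * G` with `drag_coeff = 1.7005 * 6 pi` (the
#' "~32" prefactor) and torque contribution `Gamma = torque_coeff * mu * a^3
#' * G` with `torque_coeff = 0.9440 * 4` by default (`torque_includes_pi =
#' TRUE` switches to the 4 pi form). `c_t` is the translation factor relating
#' the velocity of a wall-touching sphere to the shear rate, `v = c_t * a *
#' G`.
#'
#' @param radius_um bead radius a, um (default 2.25: Dynal M-450 are 4.5 um
#'   diameter).
#' @param viscosity_Pa_s medium viscosity mu, Pa s.
#' @param bond_length_nm tether length L, nm.
#' @param drag_coeff translational drag prefactor.
#' @param torque_coeff torque prefactor.
#' @param torque_includes_pi use `0.9440 * 4 * pi` for the torque term.
#' @param c_t wall-touching sphere translation factor.
#' @return Object of class `bead_model`.
#' @export
bead_model <- function(radius_um = 2.25, viscosity_Pa_s = 1e-3,
                       bond_length_nm = 30,
                       drag_coeff = 1.7005 * 6 * pi,
                       torque_coeff = 0.9440 * 4,
                       torque_includes_pi = FALSE,
                       c_t = 0.7431) {
  stopifnot(radius_um > 0, viscosity_Pa_s > 0, bond_length_nm > 0, c_t > 0)
  if (torque_includes_pi) torque_coeff <- 0.9440 * 4 * pi
  structure(list(radius_um = radius_um, viscosity_Pa_s = viscosity_Pa_s,
                 bond_length_nm = bond_length_nm, drag_coeff = drag_coeff,
                 torque_coeff = torque_coeff, c_t = c_t),
            class = "bead_model")
}

#' Wall shear rate from volumetric flow rate
#'
#' Plane-Poiseuille wall shear in a thin rectangular channel:
#' `G = 6 Q / (l H^2)` with the channel width l included for dimensional
#' consistency.
#'
#' @param Q_ul_s flow rate, ul/s (>= 0).
#' @param geom a [chamber_geometry()].
#' @return shear rate G, 1/s.
#' @examples
#' shear_from_flow(1, chamber_geometry())  # 48 1/s
#' @export
shear_from_flow <- function(Q_ul_s, geom = chamber_geometry()) {
  stopifnot(inherits(geom, "chamber_geometry"))
  if (any(Q_ul_s < 0)) stop("flow rate must be non-negative")
  Q <- Q_ul_s * 1e-9           # m^3/s
  l <- geom$width_mm * 1e-3    # m
  H <- geom$height_mm * 1e-3   # m
  6 * Q / (l * H^2)
}

#' Wall shear rate from bead velocity
#'
#' A sphere rolling/sliding at the wall translates at `v = c_t * a * G`;
#' inverting gives the shear rate from the measured bead velocity.
#'
#' @param v_um_s bead velocity, um/s (>= 0).
#' @param bead a [bead_model()].
#' @return shear rate G, 1/s.
#' @export
shear_from_bead_velocity <- function(v_um_s, bead = bead_model()) {
  stopifnot(inherits(bead, "bead_model"))
  if (any(v_um_s < 0)) stop("velocity must be non-negative")
  (v_um_s * 1e-6) / (bead$c_t * bead$radius_um * 1e-6)
}

#' Tensile force on a single bond tethering a bead in shear flow
#'
#' The flow exerts a drag force `R = drag_coeff * mu * a^2 * G` and a torque
#' `Gamma = torque_coeff * mu * a^3 * G` on the arrested bead; the short
#' tether acts as a lever, amplifying the load on the bond:
#' `F = (R + Gamma/a) * sqrt(a / (2 L))`.
#'
#' @param G shear rate, 1/s (>= 0, vectorized).
#' @param bead a [bead_model()].
#' @return bond force, pN.
#' @export
bond_force <- function(G, bead = bead_model()) {
  stopifnot(inherits(bead, "bead_model"))
  if (any(G < 0)) stop("shear rate must be non-negative")
  a <- bead$radius_um * 1e-6          # m
  mu <- bead$viscosity_Pa_s
  L <- bead$bond_length_nm * 1e-9     # m
  R <- bead$drag_coeff * mu * a^2 * G       # N
  Gamma_over_a <- bead$torque_coeff * mu * a^2 * G
  (R + Gamma_over_a) * sqrt(a / (2 * L)) * 1e12
}

#' Bond force for a velocity bin
#'
#' Composition of [shear_from_bead_velocity()] and [bond_force()]: converts
#' the mean bead velocity of a velocity bin into the tensile force on the
#' bond.
#'
#' @param mean_velocity_um_s bin-mean bead velocity, um/s.
#' @param bead a [bead_model()].
#' @return force, pN.
#' @examples
#' force_for_velocity_bin(100)  # ~ 66 pN with default bead parameters
#' @export
force_for_velocity_bin <- function(mean_velocity_um_s, bead = bead_model()) {
  bond_force(shear_from_bead_velocity(mean_velocity_um_s, bead), bead)
}
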