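# Simulation unit system and parameter derivations.
#
# All simulations are run in reduced units: length unit `l` (one twelfth of
# the cavity diameter), energy unit e = kB*T at physiological temperature,
# and time unit tau = eta*l^3/e from the nucleoplasmic viscosity.

KB_PN_NM_PER_K <- 1.380649e-2  # Boltzmann constant, pN*nm/K (1.380649e-23 J/K)

#' Thermal energy in pN nm
#'
#' @param T_K Absolute temperature in kelvin.
#' @return Thermal energy `kB * T` in pN nm.  At 310 K this is 4.28 pN nm,
#'   the simulation energy unit.
#' @examples
#' thermal_energy(310)
#' @export
thermal_energy <- function(T_K) {
  if (!is.numeric(T_K) || any(T_K <= 0)) {
    stop("`T_K` must be a positive temperature in kelvin", call. = FALSE)
  }
  KB_PN_NM_PER_K * T_K
}

#' Simulation length unit from the cavity diameter
#'
#' The cavity diameter is fixed at `divisor` length units (12 by default),
#' so the unit of length is the cavity diameter divided by 12.
#'
#' @param d_ct_nm Cavity diameter in nm.
#' @param divisor Number of length units per cavity diameter.
#' @return Length unit in nm (117.6 nm for the 1411.2 nm cavity).
#' @export
length_unit_from_cavity <- function(d_ct_nm, divisor = 12L) {
  stopifnot(d_ct_nm > 0, divisor >= 1)
  d_ct_nm / divisor
}

#' Simulation time unit from viscosity, length and energy units
#'
#' The time unit is `tau = eta * l^3 / e` expressed in ms; with the
#' nucleoplasmic viscosity 1.5 cP, `l` = 117.6 nm and `e` = 4.28 pN nm this
#' gives 0.57 ms.
#'
#' @param eta_cP Viscosity in centipoise.
#' @param l_nm Length unit in nm.
#' @param e_pNnm Energy unit in pN nm.
#' @return Time unit in milliseconds.
#' @export
time_unit <- function(eta_cP, l_nm, e_pNnm) {
  stopifnot(eta_cP > 0, l_nm > 0, e_pNnm > 0)
  # SI: eta [Pa s] * l^3 [m^3] / e [J] -> s; 1 cP = 1e-3 Pa s,
  # 1 nm = 1e-9 m, 1 pN nm = 1e-21 J.
  seconds <- (eta_cP * 1e-3) * (l_nm * 1e-9)^3 / (e_pNnm * 1e-21)
  seconds * 1e3
}

#' Cavity diameter at constant genomic packing density
#'
#' Scales a nucleus of diameter `nucleus_diameter_um` containing
#' `genome_bp` base pairs down to the cavity holding `chromatin_bp`,
#' keeping DNA density constant (diameter scales as the cube root of the
#' base-pair content).
#'
#' @param chromatin_bp Base pairs of chromatin in the cavity.
#' @param genome_bp Diploid genome size in bp.
#' @param nucleus_diameter_um Nuclear diameter in micrometres.
#' @return Cavity diameter in micrometres.
#' @export
cavity_diameter <- function(chromatin_bp, genome_bp = 6.2e9,
                            nucleus_diameter_um = 7) {
  stopifnot(chromatin_bp > 0, genome_bp > 0, nucleus_diameter_um > 0)
  nucleus_diameter_um * (chromatin_bp / genome_bp)^(1 / 3)
}

#' DNA content per bead
#'
#' @param total_bp Total chromatin in bp.
#' @param N Number of beads.
#' @return Base pairs represented by one bead.
#' @export
bead_bp <- function(total_bp, N) {
  stopifnot(N >= 1, total_bp > 0)
  total_bp / N
}

#' Bead diameter from base-pair content
#'
#' Assumes close compaction of nucleosomes (spheres of diameter
#' `d_nucleosome_nm` holding `bp_per_nucleosome` bp each) inside a bead, so
#' the bead diameter scales as the cube root of the nucleosome count.
#'
#' @param bp_per_bead Base pairs per bead.
#' @param d_nucleosome_nm Nucleosome diameter in nm.
#' @param bp_per_nucleosome DNA content of one nucleosome in bp.
#' @return Bead diameter in nm.
#' @export
bead_diameter_from_bp <- function(bp_per_bead, d_nucleosome_nm = 22,
                                  bp_per_nucleosome = 200) {
  stopifnot(bp_per_bead > 0, d_nucleosome_nm > 0, bp_per_nucleosome > 0)
  d_nucleosome_nm * (bp_per_bead / bp_per_nucleosome)^(1 / 3)
}

#' Construct the simulation unit system
#'
#' @param T_K Temperature (K).
#' @param eta_cP Nucleoplasmic viscosity (cP).
#' @param d_ct_nm Cavity diameter (nm).
#' @param divisor Length units per cavity diameter.
#' @return A `unit_system` list with fields `length_unit_nm`,
#'   `energy_unit_pNnm`, `time_unit_ms`, `temperature_K`, `viscosity_cP`.
#' @examples
#' unit_system()
#' @export
unit_system <- function(T_K = 310, eta_cP = 1.5, d_ct_nm = 1411.2,
                        divisor = 12L) {
  l <- length_unit_from_cavity(d_ct_nm, divisor)
  e <- thermal_energy(T_K)
  structure(
    list(
      length_unit_nm = l,
      energy_unit_pNnm = e,
      time_unit_ms = time_unit(eta_cP, l, e),
      temperature_K = T_K,
      viscosity_cP = eta_cP,
      cavity_diameter_nm = d_ct_nm
    ),
    class = "unit_system"
  )
}

#' @export
print.unit_system <- function(x, ...) {
  cat("<unit_system>\n")
  cat(sprintf("  length l   : %.4g nm\n", x$length_unit_nm))
  cat(sprintf("  energy e   : %.4g pN nm (kB T at %g K)\n",
              x$energy_unit_pNnm, x$temperature_K))
  cat(sprintf("  time tau   : %.4g ms (eta = %g cP)\n",
              x$time_unit_ms, x$viscosity_cP))
  invisible(x)
}

#' Topoisomerase-II transition rates
#'
#' Bundles the three Poisson rates of the catch-and-release scheme:
#' `lambda_ra` (repulsion -> attraction, the catch rate), `lambda_an`
#' (attraction -> no-interaction) and `lambda_nr` (no-interaction ->
#' repulsion, release).  All rates are in 1/tau.
#'
#' @param lambda_ra,lambda_an,lambda_nr Non-negative rates (1/tau).
#' @return An `enzyme_rates` list; its `activity` element caches
#'   [activity()].
#' @export
enzyme_rates <- function(lambda_ra, lambda_an = 16.7, lambda_nr = 500) {
  stopifnot(lambda_ra >= 0, lambda_an > 0, lambda_nr > 0)
  r <- structure(
    list(lambda_ra = lambda_ra, lambda_an = lambda_an,
         lambda_nr = lambda_nr),
    class = "enzyme_rates"
  )
  r$activity <- activity(r)
  r
}

#' @export
print.enzyme_rates <- function(x, ...) {
  cat(sprintf(
    "<enzyme_rates> lambda_ra = %g, lambda_an = %g, lambda_nr = %g (1/tau); Lambda = %.4f\n",
    x$lambda_ra, x$lambda_an, x$lambda_nr, x$activity))
  invisible(x)
}

#' Enzymatic activity
#'
#' The dimensionless activity `Lambda = lambda_ra * (1/lambda_an +
#' 1/lambda_nr)`: the catch rate multiplied by the mean bound duration.
#'
#' @param rates An [enzyme_rates()] object (or a list with the three rate
#'   fields).
#' @return Dimensionless activity.
#' @examples
#' activity(enzyme_rates(10))     # 0.6188
#' activity(enzyme_rates(0.5))    # 0.0309
#' @export
activity <- function(rates) {
  if (rates$lambda_an <= 0 || rates$lambda_nr <= 0) {
    stop("`lambda_an` and `lambda_nr` must be strictly positive", call. = FALSE)
  }
  rates$lambda_ra * (1 / rates$lambda_an + 1 / rates$lambda_nr)
}

#' Mean dwell times of the bound states
#'
#' @param rates An [enzyme_rates()] object.
#' @return Named numeric vector: mean time in the attraction state
#'   (`1/lambda_an`) and in the no-interaction state (`1/lambda_nr`), in tau.
#' @export
dwell_means <- function(rates) {
  if (rates$lambda_an <= 0 || rates$lambda_nr <= 0) {
    stop("`lambda_an` and `lambda_nr` must be strictly positive", call. = FALSE)
  }
  c(attraction = 1 / rates$lambda_an, none = 1 / rates$lambda_nr)
}

#' Solve the excluded-volume width from the potential-matching constraint
#'
#' The bead size is fixed by requiring that the minimum of the bonded
#' potential `h_spring + h_vex` sits at `rm = (d_i + d_j)/2`.  With the
#' FENE parameters `k`, `r0 = d_i + d_j` this yields the constraint
#' `k*rm^2/(1 - rm^2/r0^2) = 2*eps_vex*alpha*rm^2*exp(-alpha*rm^2)`, a
#' transcendental equation in the Gaussian width `alpha`.  Its right-hand
#' side has a single maximum at `alpha = 1/rm^2`; of the two positive roots
#' the larger one (the narrower, steeper Gaussian) is returned, which is
#' the branch used by the model's parameter table.
#'
#' @param k FENE spring constant (e/l^2).
#' @param eps_vex Gaussian amplitude (e).
#' @param d_i,d_j Diameters of the two bonded beads (l).
#' @return The larger root `alpha_vex` in 1/l^2, with attributes
#'   `smaller_root` and `G` (the matched constant).
#' @examples
#' d <- 50.5086 / 117.6
#' solve_alpha_vex(22, 8, d, d)   # ~7.9585
#' @export
solve_alpha_vex <- function(k, eps_vex, d_i, d_j) {
  stopifnot(k > 0, eps_vex > 0, d_i > 0, d_j > 0)
  rm2 <- ((d_i + d_j) / 2)^2
  r02 <- (d_i + d_j)^2
  G <- k * rm2 / (1 - rm2 / r02)        # = (4/3) k rm^2
  # substitute u = alpha * rm^2: 2 eps u exp(-u) = G
  target <- G / (2 * eps_vex)
  if (target > exp(-1)) {
    stop(sprintf(
      paste0("potential-matching constraint infeasible: requires ",
             "G = %.6g but the right-hand side cannot exceed ",
             "2*eps_vex*exp(-1) = %.6g"),
      G, 2 * eps_vex * exp(-1)),
      call. = FALSE)
  }
  f <- function(u) u * exp(-u) - target
  u_small <- stats::uniroot(f, c(1e-12, 1), tol = 1e-14)$root
  # larger root: bracket on (1, U) with U large enough that f(U) < 0
  U <- 1
  repeat {
    U <- U * 2
    if (f(U) < 0 || U > 1e6) break
  }
  u_large <- stats::uniroot(f, c(1, U), tol = 1e-14)$root
  alpha <- u_large / rm2
  attr(alpha, "smaller_root") <- u_small / rm2
  attr(alpha, "G") <- G
  alpha
}
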