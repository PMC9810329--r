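# Interaction potentials and their analytic radial forces.
#
# Conventions: energies in e, lengths in l.  A `*_force()` function
# returns the radial component f(r) = -dE/dr, so a positive value pushes
# the pair apart (repulsion) and, for the wall term, pushes the bead away
# from the wall.

#' FENE bond potential
#'
#' `-(1/2) k r0^2 log(1 - (r/r0)^2)`, finite extensibility: requires separation below `r0`.
#'
#' @param r Bond length (l), `0 <= r < r0`.
#' @param k Spring constant (e/l^2).
#' @param r0 Maximum extension (l); the sum of the two bonded bead
#'   diameters.
#' @return Energy in e.
#' @export
fene_energy <- function(r, k, r0) {
  check_overstretch(r, r0)
  -0.5 * k * r0^2 * log(1 - (r / r0)^2)
}

#' @rdname fene_energy
#' @return `fene_force()`: radial force `-dE/dr = -k r / (1 - (r/r0)^2)`
#'   (always attractive/restoring).
#' @export
fene_force <- function(r, k, r0) {
  check_overstretch(r, r0)
  -k * r / (1 - (r / r0)^2)
}

check_overstretch <- function(r, r0) {
  if (any(r < 0)) stop("negative bond length", call. = FALSE)
  if (any(r >= r0)) {
    stop(sprintf("FENE bond overstretched: r = %.6g >= r0 = %.6g",
                 max(r), r0), call. = FALSE)
  }
  invisible(TRUE)
}

#' Three-state Gaussian excluded-volume potential
#'
#' `+eps * exp(-alpha r^2)` for an unbound pair (repulsion),
#' `-eps * exp(-alpha r^2)` for an enzyme-bound pair in the attraction
#' state, and 0 in the no-interaction state; truncated to 0 beyond the
#' cutoff.
#'
#' @param r Separation (l).
#' @param state `"REPULSION"`, `"ATTRACTION"` or `"NONE"`.
#' @param eps Amplitude (e).
#' @param alpha Gaussian width (1/l^2).
#' @param cutoff Interaction range (l).
#' @return Energy in e.
#' @export
vex_energy <- function(r, state = "REPULSION", eps = 8, alpha = 7.9585,
                       cutoff = 1) {
  sgn <- vex_sign(state)
  ifelse(r > cutoff, 0, sgn * eps * exp(-alpha * r^2))
}

#' @rdname vex_energy
#' @export
vex_force <- function(r, state = "REPULSION", eps = 8, alpha = 7.9585,
                      cutoff = 1) {
  sgn <- vex_sign(state)
  ifelse(r > cutoff, 0, sgn * 2 * eps * alpha * r * exp(-alpha * r^2))
}

vex_sign <- function(state) {
  switch(match.arg(state, c("REPULSION", "ATTRACTION", "NONE")),
         REPULSION = 1, ATTRACTION = -1, NONE = 0)
}

#' Heterochromatin affinity potential (BB pairs)
#'
#' `-eps_HC r^2 exp[-alpha_HC (c - r)^2]` with `c = d_B - 1/(alpha_HC
#' d_B)`, truncated beyond the cutoff.  The well minimum sits exactly at
#' separation `d_B`, coinciding with the minimum of the bonded `spring + vex`
#' pair potential so that the affinity does not shift the bead size.
#'
#' @param r Separation (l).
#' @param eps_HC Affinity amplitude (same dimension as the spring
#'   constant, e/l^2).
#' @param alpha_HC Width about the minimum (1/l^2).
#' @param d_B B-bead diameter (l).
#' @param cutoff Interaction range (l).
#' @return Energy in e.
#' @export
hc_energy <- function(r, eps_HC, alpha_HC = 100, d_B = 50.5086 / 117.6,
                      cutoff = 1) {
  cshift <- d_B - 1 / (alpha_HC * d_B)
  ifelse(r > cutoff, 0, -eps_HC * r^2 * exp(-alpha_HC * (cshift - r)^2))
}

#' @rdname hc_energy
#' @export
hc_force <- function(r, eps_HC, alpha_HC = 100, d_B = 50.5086 / 117.6,
                     cutoff = 1) {
  cshift <- d_B - 1 / (alpha_HC * d_B)
  gauss <- exp(-alpha_HC * (cshift - r)^2)
  # dE/dr = -eps*(2r + 2*alpha*r^2*(c - r))*gauss ; force = -dE/dr
  ifelse(r > cutoff, 0,
         eps_HC * gauss * (2 * r + 2 * alpha_HC * r^2 * (cshift - r)))
}

#' Star-polymer wall confinement potential
#'
#' Models each bead as a two-arm star polymer of gyration radius `d/2`
#' pressed against a hard wall: logarithmic repulsion inside the corona
#' radius `Rs`, an erfc tail outside, matched so the potential is C1 at
#' `Rs`.
#'
#' @param r_wall Distance from the wall (l), strictly positive.
#' @param cp Confinement parameter list with `p`, `s`, `Rs`, `kappa`,
#'   `gamma` (see [model_params()]).
#' @return Energy in e.
#' @export
confinement_energy <- function(r_wall, cp) {
  if (any(r_wall <= 0)) stop("bead at or through the wall", call. = FALSE)
  pref <- cp$p * cp$s^1.5
  a2 <- 1 / (1 + 2 * cp$kappa^2 * cp$Rs^2) - 0.5
  inner <- pref * (-log(r_wall / cp$Rs) -
                     (r_wall^2 / cp$Rs^2 - 1) * a2 + cp$gamma)
  outer <- pref * cp$gamma * erfc(cp$kappa * r_wall) / erfc(cp$kappa * cp$Rs)
  ifelse(r_wall <= cp$Rs, inner, outer)
}

#' @rdname confinement_energy
#' @return `confinement_force()`: `-dE/dr_wall`, positive (pushes the
#'   bead away from the wall).
#' @export
confinement_force <- function(r_wall, cp) {
  if (any(r_wall <= 0)) stop("bead at or through the wall", call. = FALSE)
  pref <- cp$p * cp$s^1.5
  a2 <- 1 / (1 + 2 * cp$kappa^2 * cp$Rs^2) - 0.5
  inner <- pref * (1 / r_wall + 2 * r_wall / cp$Rs^2 * a2)
  outer <- pref * cp$gamma / erfc(cp$kappa * cp$Rs) *
    2 * cp$kappa / sqrt(pi) * exp(-(cp$kappa * r_wall)^2)
  ifelse(r_wall <= cp$Rs, inner, outer)
}

#' Total system energy
#'
#' Sum of FENE bonds, pairwise Gaussian excluded volume (with each pair's
#' current enzyme state), BB heterochromatin affinity and per-bead wall
#' confinement.  Pair terms are counted once per pair.
#'
#' @param state A [sim_state()] object.
#' @param params A [model_params()] object.
#' @return Energy in e.
#' @export
total_energy <- function(state, params) {
  cpp_total_energy(state$positions, species_code(state$species),
                   registry_matrix(state$registry), cpp_params(params))
}

#' Per-bead forces
#'
#' Minus the gradient of [total_energy()] with respect to each bead.
#'
#' @inheritParams total_energy
#' @return An N x 3 matrix of forces (e/l).
#' @export
total_forces <- function(state, params) {
  cpp_total_forces(state$positions, species_code(state$species),
                   registry_matrix(state$registry), cpp_params(params))
}

species_code <- function(species) {
  if (is.integer(species)) return(species)
  as.integer(species == "B")   # A -> 0, B -> 1
}

registry_matrix <- function(registry) {
  if (is.null(registry) || nrow(registry) == 0) {
    return(matrix(integer(0), ncol = 3))
  }
  cbind(registry$i, registry$j,
        ifelse(registry$state == "ATTRACTION", 1L, 2L))
}

# flatten model_params into the list the C++ kernels expect
cpp_params <- function(params) {
  g <- params$geometry
  eff_AA <- if (params$variant == "NONTRANSIENT") {
    nontransient_eps(params)
  } else params$eps_vex[["AA"]]
  list(
    eps_vex = as.numeric(params$eps_vex[c("AA", "AB", "BB")]),
    alpha_vex = as.numeric(params$alpha_vex[c("AA", "AB", "BB")]),
    k = params$k,
    r0 = as.numeric(params$r0[c("AA", "AB", "BB")]),
    eps_HC = params$eps_HC,
    alpha_HC = params$alpha_HC,
    d_B = params$d_B,
    cutoff = params$cutoff,
    d_bead = c(params$d_A, params$d_B),
    conf = rbind(
      unlist(params$conf_A[c("p", "s", "Rs", "kappa", "gamma")]),
      unlist(params$conf_B[c("p", "s", "Rs", "kappa", "gamma")])
    ),
    geom_type = if (g$type == "sphere") 0L else 1L,
    geom = if (g$type == "sphere") c(g$radius, 0, 0) else c(g$Lx, g$Ly, g$Lz),
    variant = match(params$variant,
                    c("RANR", "RAR", "RNR", "PHANTOM", "NONTRANSIENT",
                      "PASSIVE")) - 1L,
    eps_AA_effective = eff_AA,
    rates = c(params$rates$lambda_ra, params$rates$lambda_an,
              params$rates$lambda_nr),
    exclude_neighbors = params$exclude_neighbors,
    exclusive_binding = params$exclusive_binding
  )
}

#' Cycle-averaged AA amplitude of the non-transient attraction variant
#'
#' The permanent AA Gaussian amplitude obtained by weighting the three
#' kinetic states by their mean dwell times: `[(1/lambda_ra)(+eps) +
#' (1/lambda_an)(-eps) + (1/lambda_nr)(0)] / (1/lambda_ra + 1/lambda_an +
#' 1/lambda_nr)`.
#'
#' @param params A [model_params()] object.
#' @return Effective AA amplitude in e (signed).
#' @export
nontransient_eps <- function(params) {
  r <- params$rates
  if (r$lambda_ra <= 0) return(params$eps_vex[["AA"]])
  w <- c(1 / r$lambda_ra, 1 / r$lambda_an, 1 / r$lambda_nr)
  eps <- params$eps_vex[["AA"]]
  sum(w * c(eps, -eps, 0)) / sum(w)
}
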