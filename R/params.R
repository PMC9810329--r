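# Model parameter assembly: per-pair potential constants, heterochromatin
# affinity, wall confinement, enzyme rates, geometry and variant flags.
# All lengths in l, energies in e, times in tau.

#' Bead volume from diameter
#' @param d Diameter (any length unit).
#' @return Sphere volume `pi/6 * d^3` in the cubed unit of `d`.
#' @export
bead_volume <- function(d) pi / 6 * d^3

# Confinement gamma making the star-polymer wall potential C1 at Rs.
confinement_gamma <- function(kappa, Rs) {
  x <- kappa * Rs
  # erfc(x) * exp(x^2) computed stably via scaled complementary error function
  sqrt(pi) * erfc_exp(x) / (x * (1 + 2 * x^2))
}

# erfc(x) * exp(x^2), stable for moderately large x
erfc_exp <- function(x) {
  exp(x^2 + stats::pnorm(x * sqrt(2), lower.tail = FALSE, log.p = TRUE) +
        log(2))
}

# erfc via pnorm
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

confinement_params <- function(d, p = 4, s = 2) {
  Rg <- d / 2
  Rs <- 0.65 * Rg
  kappa <- 1 / Rg
  list(p = p, s = s, Rs = Rs, kappa = kappa,
       gamma = confinement_gamma(kappa, Rs))
}

#' Assemble the full model parameter set
#'
#' Collects every constant a run needs: per-pair-type Gaussian
#' excluded-volume parameters, FENE spring constants, heterochromatin (BB)
#' affinity, per-species wall confinement, enzyme rates, geometry,
#' model-variant flag and composition target.
#'
#' @param d_A,d_B Bead diameters in l.
#' @param eps_vex Named numeric: Gaussian amplitudes (e) for `AA`, `AB`,
#'   `BB`.  A single unnamed value is recycled.
#' @param alpha_vex Named numeric: Gaussian widths (1/l^2) for the three
#'   pair types, or `NULL` to solve each from the potential-matching
#'   constraint.
#' @param k FENE spring constant (e/l^2).
#' @param eps_HC Heterochromatin affinity amplitude (e/l^2 scale; enters as
#'   `-eps_HC * r^2 * exp(...)`).
#' @param alpha_HC Width of the affinity well (1/l^2).
#' @param rates An [enzyme_rates()] object.
#' @param geometry `geometry_sphere()` or `geometry_slab()`.
#' @param variant One of `"RANR"` (full three-state scheme), `"RAR"`,
#'   `"RNR"` (two-state schemes), `"PHANTOM"` (AA excluded volume
#'   permanently off), `"NONTRANSIENT"` (permanent cycle-averaged AA
#'   potential, no kinetics), `"PASSIVE"` (no enzyme).
#' @param cutoff Interaction cutoff (l).
#' @param exclude_neighbors Disallow enzyme binding of chain-adjacent beads.
#' @param exclusive_binding If `TRUE`, a bead participates in at most one
#'   bound pair at a time (a sensitivity mode).  The default `FALSE`
#'   treats every proximal AA pair as an independent kinetic process, the
#'   reading under which the per-pair rates and the activity `Lambda`
#'   control the bound-pair density.
#' @param phi_A Target A volume fraction (bookkeeping; the sequence fixes
#'   the realized value).
#' @param p_conf Wall potential amplitude (e).
#' @return A `model_params` list.
#' @export
model_params <- function(d_A, d_B = d_A,
                         eps_vex = c(AA = 8, AB = 8, BB = 8),
                         alpha_vex = NULL,
                         k = 22,
                         eps_HC = 0, alpha_HC = 100,
                         rates = enzyme_rates(0),
                         geometry = geometry_sphere(12),
                         variant = c("RANR", "RAR", "RNR", "PHANTOM",
                                     "NONTRANSIENT", "PASSIVE"),
                         cutoff = 1,
                         exclude_neighbors = TRUE,
                         exclusive_binding = FALSE,
                         phi_A = NA_real_,
                         p_conf = 4) {
  variant <- match.arg(variant)
  stopifnot(d_A > 0, d_B > 0, k > 0, cutoff > 0)
  if (length(eps_vex) == 1 && is.null(names(eps_vex))) {
    eps_vex <- c(AA = unname(eps_vex), AB = unname(eps_vex),
                 BB = unname(eps_vex))
  }
  stopifnot(all(c("AA", "AB", "BB") %in% names(eps_vex)))
  diam <- c(AA = 2 * d_A, AB = d_A + d_B, BB = 2 * d_B)  # r0 per pair type
  if (is.null(alpha_vex)) {
    alpha_vex <- vapply(c("AA", "AB", "BB"), function(pt) {
      di <- switch(pt, AA = c(d_A, d_A), AB = c(d_A, d_B), BB = c(d_B, d_B))
      as.numeric(solve_alpha_vex(k, eps_vex[[pt]], di[1], di[2]))
    }, numeric(1))
  }
  stopifnot(all(c("AA", "AB", "BB") %in% names(alpha_vex)))
  structure(
    list(
      d_A = d_A, d_B = d_B,
      eps_vex = eps_vex[c("AA", "AB", "BB")],
      alpha_vex = alpha_vex[c("AA", "AB", "BB")],
      k = k, r0 = diam,
      eps_HC = eps_HC, alpha_HC = alpha_HC,
      conf_A = confinement_params(d_A, p = p_conf),
      conf_B = confinement_params(d_B, p = p_conf),
      rates = rates,
      geometry = geometry,
      variant = variant,
      cutoff = cutoff,
      exclude_neighbors = exclude_neighbors,
      exclusive_binding = exclusive_binding,
      phi_A = phi_A
    ),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>", x$variant, "\n")
  cat(sprintf("  d_A = %.4f l, d_B = %.4f l, k = %g e/l^2\n",
              x$d_A, x$d_B, x$k))
  cat(sprintf("  eps_vex: AA=%g AB=%g BB=%g (e); alpha_vex: AA=%.4f AB=%.4f BB=%.4f (1/l^2)\n",
              x$eps_vex[["AA"]], x$eps_vex[["AB"]], x$eps_vex[["BB"]],
              x$alpha_vex[["AA"]], x$alpha_vex[["AB"]], x$alpha_vex[["BB"]]))
  cat(sprintf("  eps_HC = %g, alpha_HC = %g; Lambda = %.4f\n",
              x$eps_HC, x$alpha_HC, x$rates$activity))
  cat(sprintf("  geometry: %s\n", x$geometry$type))
  invisible(x)
}

#' Spherical cavity geometry
#' @param d_ct Cavity diameter (l).
#' @return A geometry description list.
#' @export
geometry_sphere <- function(d_ct = 12) {
  stopifnot(d_ct > 0)
  list(type = "sphere", d_ct = d_ct, radius = d_ct / 2)
}

#' Slab geometry: closed walls at z = 0 and z = Lz, periodic in x and y
#' @param Lx,Ly Periodic box lengths (l).
#' @param Lz Wall separation (l).
#' @export
geometry_slab <- function(Lx, Ly, Lz) {
  stopifnot(Lx > 0, Ly > 0, Lz > 0)
  list(type = "slab", Lx = Lx, Ly = Ly, Lz = Lz)
}

#' Distance of points from the confining wall
#'
#' @param positions An n x 3 matrix of coordinates (l).
#' @param geometry A geometry description.
#' @return Numeric vector of distances to the nearest closed wall
#'   (positive inside).
#' @export
wall_distance <- function(positions, geometry) {
  positions <- as_position_matrix(positions)
  if (geometry$type == "sphere") {
    geometry$radius - sqrt(rowSums(positions^2))
  } else {
    pmin(positions[, 3], geometry$Lz - positions[, 3])
  }
}

as_position_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  storage.mode(x) <- "double"
  x
}

#' Monodisperse chromatin model preset
#'
#' The reference parameterization: N equal-size beads representing a
#' 50.807 Mbp chromatin territory in a sphere of diameter 12 l, beads of
#' 50.5086 nm (0.4295 l), Gaussian amplitude 8 e with width 7.9585 1/l^2,
#' FENE k = 22 e/l^2.
#'
#' @param N Number of beads (20992 reproduces the full-scale territory;
#'   smaller values shrink the cavity at constant bead density).
#' @param phi_A Target A volume fraction.
#' @param eps_HC Heterochromatin affinity.
#' @param lambda_ra Enzyme catch rate (1/tau); 10 gives Lambda = 0.6188,
#'   0.5 gives 0.0309.
#' @param variant Model variant (see [model_params()]).
#' @param b Block size (beads); used by callers generating sequences.
#' @return A `model_params` object with attribute `b`.
#' @export
monodisperse_params <- function(N = 20992, phi_A = 0.5, eps_HC = 0,
                                lambda_ra = 0, variant = "RANR", b = 4L) {
  us <- unit_system()
  d <- 50.5086 / us$length_unit_nm
  d_ct <- 12 * (N / 20992)^(1 / 3)   # constant bead density
  if (lambda_ra == 0 && variant == "RANR") variant <- "PASSIVE"
  p <- model_params(
    d_A = d, d_B = d,
    eps_vex = c(AA = 8, AB = 8, BB = 8),
    alpha_vex = c(AA = 7.9585, AB = 7.9585, BB = 7.9585),
    k = 22, eps_HC = eps_HC, alpha_HC = 100,
    rates = enzyme_rates(lambda_ra),
    geometry = geometry_sphere(d_ct),
    variant = variant, phi_A = phi_A
  )
  attr(p, "N") <- as.integer(N)
  attr(p, "b") <- as.integer(b)
  p
}

#' Bidisperse chromatin model preset
#'
#' A and B beads sized from the mean cluster sizes of active and
#' repressive histone marks (46 and 61 nm), composition phi_A = 0.3544,
#' N = 17664 beads at full scale.  The pair-type Gaussian constants are
#' the model's printed values, not re-solved.
#'
#' @param N Number of beads.
#' @param phi_A Target A volume fraction.
#' @param eps_HC,lambda_ra,variant,b As in [monodisperse_params()].
#' @export
bidisperse_params <- function(N = 17664, phi_A = 0.3544, eps_HC = 0,
                              lambda_ra = 0, variant = "RANR", b = 4L) {
  us <- unit_system()
  d_A <- 46 / us$length_unit_nm
  d_B <- 61 / us$length_unit_nm
  d_ct <- 12 * (N / 17664)^(1 / 3)
  if (lambda_ra == 0 && variant == "RANR") variant <- "PASSIVE"
  p <- model_params(
    d_A = d_A, d_B = d_B,
    eps_vex = c(AA = 6.6539, AB = 8.9153, BB = 11.507),
    alpha_vex = c(AA = 9.5686, AB = 7.1414, BB = 5.5330),
    k = 22, eps_HC = eps_HC, alpha_HC = 100,
    rates = enzyme_rates(lambda_ra),
    geometry = geometry_sphere(d_ct),
    variant = variant, phi_A = phi_A
  )
  attr(p, "N") <- as.integer(N)
  attr(p, "b") <- as.integer(b)
  p
}

#' Derived parameter table for a preset
#'
#' @param preset `"monodisperse"` or `"bidisperse"`.
#' @return A tibble of named derived constants (unit system, bead sizing,
#'   pair potentials, confinement, rates) for inspection or export.
#' @export
derive_params <- function(preset = c("monodisperse", "bidisperse")) {
  preset <- match.arg(preset)
  us <- unit_system()
  p <- if (preset == "monodisperse") monodisperse_params() else bidisperse_params()
  rows <- list(
    c("length_unit_nm", us$length_unit_nm, "nm"),
    c("energy_unit_pNnm", us$energy_unit_pNnm, "pN nm"),
    c("time_unit_ms", us$time_unit_ms, "ms"),
    c("bp_per_bead", bead_bp(50.807e6, attr(p, "N")), "bp"),
    c("d_A_nm", p$d_A * us$length_unit_nm, "nm"),
    c("d_B_nm", p$d_B * us$length_unit_nm, "nm"),
    c("d_A_l", p$d_A, "l"),
    c("d_B_l", p$d_B, "l"),
    c("V_A_l3", bead_volume(p$d_A), "l^3"),
    c("V_B_l3", bead_volume(p$d_B), "l^3"),
    c("k", p$k, "e/l^2"),
    c("eps_vex_AA", p$eps_vex[["AA"]], "e"),
    c("eps_vex_AB", p$eps_vex[["AB"]], "e"),
    c("eps_vex_BB", p$eps_vex[["BB"]], "e"),
    c("alpha_vex_AA", p$alpha_vex[["AA"]], "1/l^2"),
    c("alpha_vex_AB", p$alpha_vex[["AB"]], "1/l^2"),
    c("alpha_vex_BB", p$alpha_vex[["BB"]], "1/l^2"),
    c("alpha_HC", p$alpha_HC, "1/l^2"),
    c("conf_p", p$conf_A$p, "e"),
    c("conf_Rs_A", p$conf_A$Rs, "l"),
    c("conf_kappa_A", p$conf_A$kappa, "1/l"),
    c("lambda_an", p$rates$lambda_an, "1/tau"),
    c("lambda_nr", p$rates$lambda_nr, "1/tau"),
    c("cavity_diameter_l", p$geometry$d_ct, "l")
  )
  tibble::tibble(
    quantity = vapply(rows, `[`, character(1), 1),
    value = as.numeric(vapply(rows, `[`, character(1), 2)),
    unit = vapply(rows, `[`, character(1), 3)
  )
}
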