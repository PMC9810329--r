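# Lattice mean-field model of a self-avoiding (B) / phantom (A')
# mixture.  Two A' beads may overlap into a doublet (D), freeing an empty
# site (E); with doublet fraction alpha the species volume fractions are
# phi_B, (1-phi_B)(1-2 alpha), (1-phi_B) alpha, (1-phi_B) alpha.  The
# free energy per site (kBT units) combines mixing entropy with a pair
# interaction term whose closed form is
#   f_int = eps [ c(a) Phi^2 - 2 c(a) Phi + (c(a) + 1/2) ],
# c(a) = -a^2 + a - 1/2, equivalent to the pair-energy table eps_BB =
# eps_A'B = eps_A'D = eps, eps_DB = eps_DD = 2 eps under the half-counted
# like-pair convention.

#' Interaction coefficient c(alpha)
#'
#' @param alpha Doublet fraction in \[0, 1/2\].
#' @return `-alpha^2 + alpha - 1/2`, negative throughout the domain.
#' @export
c_of_alpha <- function(alpha) {
  if (any(alpha < 0 | alpha > 0.5)) {
    stop("`alpha` must lie in [0, 1/2]", call. = FALSE)
  }
  -alpha^2 + alpha - 0.5
}

xlogx <- function(x) ifelse(x <= 0, 0, x * log(x))

#' Lattice mean-field free energy per site
#'
#' @param Phi_B Volume fraction of B in (0, 1) (boundaries allowed; the
#'   entropy uses the x log x -> 0 limit).
#' @param alpha Doublet fraction in \[0, 1/2\].
#' @param eps Pair repulsion parameter (kBT).
#' @return Free energy density in kBT per site.
#' @export
mf_free_energy <- function(Phi_B, alpha, eps) {
  if (any(Phi_B < 0 | Phi_B > 1)) stop("`Phi_B` must lie in [0, 1]",
                                       call. = FALSE)
  if (any(alpha < 0 | alpha > 0.5)) stop("`alpha` must lie in [0, 1/2]",
                                         call. = FALSE)
  entropy <- xlogx(Phi_B) + xlogx(1 - Phi_B) +
    (1 - Phi_B) * (2 * xlogx(alpha) + xlogx(1 - 2 * alpha))
  entropy + mf_fint(Phi_B, alpha, eps)
}

#' Closed-form interaction free energy
#' @inheritParams mf_free_energy
#' @export
mf_fint <- function(Phi_B, alpha, eps) {
  ca <- c_of_alpha(alpha)
  eps * (ca * Phi_B^2 - 2 * ca * Phi_B + (ca + 0.5))
}

#' Interaction free energy from the pair-energy table
#'
#' Mean-field pair energy `(1/2) sum_x eps_xx phi_x^2 + sum_{x<y} eps_xy
#' phi_x phi_y` over species A', D, E, B with the default table (all
#' other pairs zero).  Must agree with [mf_fint()] identically; the
#' agreement is the module's algebraic anchor.
#'
#' @inheritParams mf_free_energy
#' @export
mf_fint_pair_table <- function(Phi_B, alpha, eps) {
  phis <- c(Ap = (1 - Phi_B) * (1 - 2 * alpha),
            D = (1 - Phi_B) * alpha,
            E = (1 - Phi_B) * alpha,
            B = Phi_B)
  tab <- matrix(0, 4, 4, dimnames = list(names(phis), names(phis)))
  tab["B", "B"] <- eps
  tab["Ap", "B"] <- tab["B", "Ap"] <- eps
  tab["D", "B"] <- tab["B", "D"] <- 2 * eps
  tab["Ap", "D"] <- tab["D", "Ap"] <- eps
  tab["D", "D"] <- 2 * eps
  total <- 0
  sp <- names(phis)
  for (a in 1:4) {
    total <- total + 0.5 * tab[a, a] * phis[a]^2
    if (a < 4) for (b in (a + 1):4) {
      total <- total + tab[a, b] * phis[a] * phis[b]
    }
  }
  unname(total)
}

#' Critical doublet fraction
#'
#' Minimizes the free energy over alpha in \[0, 1/2\] at fixed `Phi_B`
#' and `eps`, via the interior stationarity condition `2 log(alpha/(1 -
#' 2 alpha)) + eps (1 - Phi_B) (1 - 2 alpha)' ... = 0` solved by
#' bracketed root finding, with a grid-refined fallback.
#'
#' @param Phi_B Volume fraction of B in (0, 1).
#' @param eps Pair repulsion parameter (kBT).
#' @return The minimizing doublet fraction `alpha*`.
#' @export
alpha_star <- function(Phi_B, eps) {
  stopifnot(Phi_B > 0, Phi_B < 1)
  # d f / d alpha = (1 - Phi_B) * [2 log(alpha) - 2 log(1 - 2 alpha)]
  #                 + eps * dc/dalpha * (Phi_B - 1)^2 ,
  # dc/dalpha = 1 - 2 alpha
  dfda <- function(a) {
    (1 - Phi_B) * (2 * log(a) - 2 * log(1 - 2 * a)) +
      eps * (1 - 2 * a) * (Phi_B - 1)^2
  }
  lo <- 1e-12; hi <- 0.5 - 1e-12
  flo <- dfda(lo); fhi <- dfda(hi)
  if (is.finite(flo) && is.finite(fhi) && flo < 0 && fhi > 0) {
    stats::uniroot(dfda, c(lo, hi), tol = 1e-12)$root
  } else {
    # fallback: coarse grid + local refinement of the direct objective
    g <- seq(1e-6, 0.5 - 1e-6, length.out = 2001)
    f <- vapply(g, function(a) mf_free_energy(Phi_B, a, eps), numeric(1))
    a0 <- g[which.min(f)]
    stats::optimize(function(a) mf_free_energy(Phi_B, a, eps),
                    c(max(0, a0 - 5e-4), min(0.5, a0 + 5e-4)),
                    tol = 1e-12)$minimum
  }
}

#' Reduced free energy curve
#'
#' Evaluates `f*(Phi_B) = f(Phi_B, alpha*(Phi_B, eps), eps)` on a grid
#' and estimates its second derivative by central differences.
#'
#' @param eps Pair repulsion parameter (kBT).
#' @param Phi_grid Grid of `Phi_B` values inside (0, 1).
#' @return Tibble with `Phi_B`, `alpha_star`, `f_star`, `d2f` (NA at the
#'   grid ends).
#' @export
f_star_curve <- function(eps, Phi_grid = seq(0.02, 0.98, by = 0.01)) {
  stopifnot(all(Phi_grid > 0), all(Phi_grid < 1))
  astar <- vapply(Phi_grid, alpha_star, numeric(1), eps = eps)
  fstar <- mapply(mf_free_energy, Phi_grid, astar,
                  MoreArgs = list(eps = eps))
  n <- length(Phi_grid)
  d2 <- rep(NA_real_, n)
  if (n >= 3) {
    h <- diff(Phi_grid)
    for (k in 2:(n - 1)) {
      h1 <- h[k - 1]; h2 <- h[k]
      d2[k] <- 2 * (h2 * fstar[k - 1] - (h1 + h2) * fstar[k] +
                      h1 * fstar[k + 1]) / (h1 * h2 * (h1 + h2))
    }
  }
  tibble::tibble(Phi_B = Phi_grid, alpha_star = astar, f_star = fstar,
                 d2f = d2)
}

#' Convex-to-concave transition of the reduced free energy
#'
#' Scans the repulsion parameter and returns the smallest `eps` whose
#' reduced free-energy curve has a concave region (negative second
#' derivative), signalling phase separation, refined by bisection.
#'
#' @param eps_range Length-2 increasing numeric, the scan interval.
#' @param Phi_grid Composition grid.
#' @param tol Bisection tolerance on eps.
#' @return List with `eps_transition` (NA if no concavity in range),
#'   `concave_interval` (range of `Phi_B` concave just above the
#'   transition), and the bracketing values.
#' @export
convexity_transition <- function(eps_range = c(0, 20),
                                 Phi_grid = seq(0.02, 0.98, by = 0.01),
                                 tol = 1e-3) {
  stopifnot(length(eps_range) == 2, diff(eps_range) > 0)
  min_d2 <- function(e) min(f_star_curve(e, Phi_grid)$d2f, na.rm = TRUE)
  lo <- eps_range[1]; hi <- eps_range[2]
  if (min_d2(lo) < 0) {
    return(list(eps_transition = lo, concave_interval = NA,
                bracket = c(NA, lo)))
  }
  if (min_d2(hi) >= 0) {
    return(list(eps_transition = NA_real_, concave_interval = NULL,
                bracket = c(lo, hi)))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (min_d2(mid) < 0) hi <- mid else lo <- mid
  }
  crv <- f_star_curve(hi, Phi_grid)
  conc <- crv$Phi_B[!is.na(crv$d2f) & crv$d2f < 0]
  list(eps_transition = hi, concave_interval = range(conc),
       bracket = c(lo, hi))
}
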