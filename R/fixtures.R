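# Deterministic synthetic configurations used to certify the analysis
# operations: mixtures, phase-separated spheres, oriented bond sets,
# line/ball clusters and Gaussian order-parameter fields.

#' Generate a synthetic snapshot or field
#'
#' Deterministic (seeded) generators exercising known limits of the
#' analysis suite:
#' \describe{
#'   \item{uniform_mixture}{`n` beads uniform in a sphere, species
#'     assigned A/B with probability 1/2: no phase separation, Binder
#'     cumulant near 0, surface ratio near 1.}
#'   \item{two_phase_sphere}{A beads in a concentric shell (a spherical
#'     "wall"), B beads in the core and periphery: strongly bimodal
#'     order parameter.}
#'   \item{shell_wall_bonds}{chain of A beads winding tangentially on a
#'     spherical shell: AA bonds parallel to the wall, negative nematic
#'     order.}
#'   \item{planar_bonds}{A-bead chain whose bonds are isotropic within
#'     the xy plane, all in one cell: S = -1/2.}
#'   \item{line_cluster}{`n` collinear, equally spaced B beads: one
#'     focus with shape anisotropy 1.}
#'   \item{ball_cluster}{`n` B beads uniform in a ball: one focus with
#'     shape anisotropy near 0.}
#'   \item{gaussian_field}{`n` standard-Gaussian draws returned as a
#'     plain numeric vector of order-parameter samples (Binder and
#'     skewness near 0).}
#' }
#'
#' @param generator Generator name.
#' @param n Size parameter (beads / bonds / samples).
#' @param seed Integer seed.
#' @param radius Sphere radius for position generators (l).
#' @param spacing Bead spacing for line/chain generators (l).
#' @return A [sim_state()] (or a numeric vector for `gaussian_field`).
#' @export
make_fixture <- function(generator = c("uniform_mixture",
                                       "two_phase_sphere",
                                       "shell_wall_bonds", "planar_bonds",
                                       "line_cluster", "ball_cluster",
                                       "gaussian_field"),
                         n = 1000L, seed = 1L, radius = 6, spacing = 0.3) {
  generator <- match.arg(generator)
  set.seed(seed)
  switch(generator,
    uniform_mixture = {
      pos <- runif_ball(n, radius)
      sim_state(pos, sample(c("A", "B"), n, replace = TRUE))
    },
    two_phase_sphere = {
      pos <- runif_ball(n, radius)
      r <- sqrt(rowSums(pos^2))
      shell <- r > 0.45 * radius & r < 0.75 * radius
      sim_state(pos, ifelse(shell, "A", "B"))
    },
    shell_wall_bonds = {
      # random tangent walk on a sphere of radius 0.6 * radius: every
      # bond is tangent to the shell and headings are isotropic within
      # the local tangent plane
      rs <- 0.6 * radius
      pos <- matrix(NA_real_, n, 3)
      x <- stats::rnorm(3); x <- rs * x / sqrt(sum(x^2))
      pos[1, ] <- x
      for (i in 2:n) {
        t1 <- stats::rnorm(3)
        t1 <- t1 - sum(t1 * x) * x / rs^2      # project onto tangent plane
        t1 <- t1 / sqrt(sum(t1^2))
        x <- x + spacing * t1
        x <- rs * x / sqrt(sum(x^2))
        pos[i, ] <- x
      }
      sim_state(pos, rep("A", n))
    },
    planar_bonds = {
      # zig-zag chain: bond directions uniform on the unit circle in the
      # xy plane, all midpoints within one cell around the origin
      ang <- stats::runif(n, 0, 2 * pi)
      steps <- cbind(cos(ang), sin(ang), 0) * spacing
      pos <- apply(steps, 2, cumsum)
      pos <- sweep(pos, 2, colMeans(pos))
      pos <- pos * 0.4 / max(abs(pos))   # shrink into one grid cell
      sim_state(pos, rep("A", n + 0L))
    },
    line_cluster = {
      pos <- cbind(seq_len(n) * spacing, 0, 0)
      pos <- sweep(pos, 2, colMeans(pos))
      sim_state(pos, rep("B", n))
    },
    ball_cluster = {
      sim_state(runif_ball(n, radius), rep("B", n))
    },
    gaussian_field = stats::rnorm(n)
  )
}

runif_ball <- function(n, radius) {
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    cand <- matrix(stats::runif(3 * (n - got) * 2, -radius, radius), ncol = 3)
    keep <- rowSums(cand^2) < radius^2
    take <- utils::head(which(keep), n - got)
    if (length(take) > 0) {
      out[(got + 1):(got + length(take)), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  out
}
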