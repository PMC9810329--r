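# Random multiblock copolymer sequences: blocks of b identical beads
# arranged uniformly at random along the chain.

#' Generate a random multiblock A/B sequence
#'
#' Splits the chain into `N/b` blocks, chooses the number of A blocks so
#' that the volume composition is as close as possible to `phi_A_target`
#' (ties broken toward more A blocks), and permutes the blocks uniformly
#' at random.
#'
#' @param N Number of beads (must be divisible by `b`).
#' @param b Block size in beads.
#' @param phi_A_target Target volume fraction of A.
#' @param volumes Length-2 numeric `c(V_A, V_B)` bead volumes.
#' @param seed Integer seed; the sequence is deterministic given the seed.
#' @return A `polymer_sequence` object: list with `species` (character
#'   vector of "A"/"B"), `b` and `N`.
#' @export
generate_sequence <- function(N, b = 4L, phi_A_target = 0.5,
                              volumes = c(1, 1), seed = 1L) {
  N <- as.integer(N); b <- as.integer(b)
  if (N %% b != 0L) stop("`N` must be divisible by the block size `b`",
                         call. = FALSE)
  stopifnot(phi_A_target > 0, phi_A_target < 1, all(volumes > 0))
  n_blocks <- N %/% b
  nA_candidates <- 0:n_blocks
  comp <- nA_candidates * volumes[1] /
    (nA_candidates * volumes[1] + (n_blocks - nA_candidates) * volumes[2])
  dev <- abs(comp - phi_A_target)
  # ties toward more A blocks: pick the largest nA among minimizers
  nA_blocks <- max(nA_candidates[dev <= min(dev) + 1e-15])
  blocks <- c(rep("A", nA_blocks), rep("B", n_blocks - nA_blocks))
  perm <- local_seed_sample(seed, blocks)
  structure(
    list(species = rep(perm, each = b), b = b, N = N),
    class = "polymer_sequence"
  )
}

# permute deterministically under `seed` without touching the caller's RNG
local_seed_sample <- function(seed, x) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample(x)
}

#' @export
print.polymer_sequence <- function(x, ...) {
  nA <- sum(x$species == "A")
  cat(sprintf("<polymer_sequence> N = %d, b = %d, N_A = %d, N_B = %d\n",
              x$N, x$b, nA, x$N - nA))
  invisible(x)
}

#' Volume composition of a sequence
#'
#' @param seq A `polymer_sequence` (or a character vector of "A"/"B").
#' @param volumes `c(V_A, V_B)` bead volumes.
#' @return The A volume fraction: total A volume over total bead volume.
#' @export
composition <- function(seq, volumes = c(1, 1)) {
  sp <- if (inherits(seq, "polymer_sequence")) seq$species else seq
  if (length(sp) == 0) stop("empty sequence", call. = FALSE)
  nA <- sum(sp == "A"); nB <- sum(sp == "B")
  nA * volumes[1] / (nA * volumes[1] + nB * volumes[2])
}

#' Bead counts for the bidisperse preset
#'
#' Finds block-multiple integer counts `(N_A, N_B)` summing to `N` whose
#' volume composition is closest to `phi_A`.
#'
#' @param N Total beads.
#' @param phi_A Target A volume fraction.
#' @param d_A,d_B Bead diameters (any common unit).
#' @param b Block size.
#' @return Named integer vector `c(N_A = , N_B = )`.
#' @examples
#' bidisperse_counts()  # c(N_A = 9916, N_B = 7748)
#' @export
bidisperse_counts <- function(N = 17664L, phi_A = 0.3544, d_A = 46,
                              d_B = 61, b = 4L) {
  N <- as.integer(N); b <- as.integer(b)
  if (N %% b != 0L) stop("`N` must be divisible by `b`", call. = FALSE)
  stopifnot(phi_A >= 0, phi_A <= 1, d_A > 0, d_B > 0)
  VA <- bead_volume(d_A); VB <- bead_volume(d_B)
  nA_blocks <- 0:(N %/% b)
  NA_cand <- nA_blocks * b
  NB_cand <- N - NA_cand
  comp <- ifelse(NA_cand + NB_cand == 0, NA,
                 NA_cand * VA / (NA_cand * VA + NB_cand * VB))
  dev <- abs(comp - phi_A)
  best <- max(NA_cand[dev <= min(dev) + 1e-15])
  c(N_A = as.integer(best), N_B = as.integer(N - best))
}

#' Composition from radial distribution functions
#'
#' Estimates the A volume fraction from tabulated radial distribution
#' functions of the two species, as used to set the bidisperse preset's
#' composition from imaging data.  For each species the mean cluster
#' multiplicity is `m = int_segment 2 pi r g(r) dr / int_core 2 pi r g(r)
#' dr` (2D trapezoidal integration), and `phi_A = m_A V_A / (m_A V_A +
#' m_B V_B)`.
#'
#' @param r Common radial grid (same unit as the diameters).
#' @param g_A,g_B Tabulated radial distribution functions on `r`.
#' @param d_A,d_B Bead diameters; the core domain is `[0, d/2]`.
#' @param segment_domain Length-2 numeric, the integration window of the
#'   chromatin segment.
#' @return Estimated `phi_A`.
#' @export
composition_from_rdf <- function(r, g_A, g_B, d_A, d_B, segment_domain) {
  stopifnot(length(r) == length(g_A), length(r) == length(g_B),
            all(diff(r) > 0), length(segment_domain) == 2)
  rng <- range(r)
  # the core integral runs from the grid start (tabulated curves rarely
  # reach r = 0 exactly)
  need <- c(d_A / 2, d_B / 2, segment_domain)
  if (min(need) < rng[1] - 1e-12 || max(need) > rng[2] + 1e-12) {
    stop("integration domain outside tabulated range", call. = FALSE)
  }
  m_A <- rdf_integral(r, g_A, segment_domain) / rdf_integral(r, g_A, c(rng[1], d_A / 2))
  m_B <- rdf_integral(r, g_B, segment_domain) / rdf_integral(r, g_B, c(rng[1], d_B / 2))
  VA <- bead_volume(d_A); VB <- bead_volume(d_B)
  m_A * VA / (m_A * VA + m_B * VB)
}

# trapezoidal integral of 2*pi*r*g over [lo, hi], with linear
# interpolation of g at the interval end points
rdf_integral <- function(r, g, domain) {
  lo <- domain[1]; hi <- domain[2]
  stopifnot(hi > lo)
  f <- stats::approxfun(r, 2 * pi * r * g)
  knots <- sort(unique(c(lo, r[r > lo & r < hi], hi)))
  y <- f(knots)
  sum(diff(knots) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
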