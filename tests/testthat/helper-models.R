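# Shared builders for small test systems.

# monodisperse-parameter set scaled to n beads, with an oversized cavity
# option for unconfined-style checks
tiny_params <- function(n = 20, eps_HC = 0, lambda_ra = 0,
                        variant = "RANR", cavity = NULL) {
  p <- monodisperse_params(N = n, eps_HC = eps_HC, lambda_ra = lambda_ra,
                           variant = variant)
  if (!is.null(cavity)) p$geometry <- geometry_sphere(cavity)
  p
}

# deterministic random chain configuration inside a sphere, bonds short
# enough never to overstretch
random_chain_state <- function(n, seed, spread = 0.25, species = NULL) {
  set.seed(seed)
  pos <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    step <- stats::rnorm(3)
    pos[i + 1, ] <- pos[i, ] + spread * step / sqrt(sum(step^2))
  }
  pos <- sweep(pos, 2, colMeans(pos))
  if (is.null(species)) {
    species <- rep(c("A", "B"), length.out = n)
  }
  sim_state(pos, species)
}

# brute-force O(n^2) pair scan within a cutoff (no periodicity)
brute_pairs <- function(positions, cutoff) {
  n <- nrow(positions)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sum((positions[i, ] - positions[j, ])^2) <= cutoff^2) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}
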