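# Brownian-dynamics driver: state container, ideal-chain initialization,
# integration protocol, neighbor search and mean-square displacement.

#' Simulation state
#'
#' @param positions N x 3 matrix of bead coordinates (l).
#' @param species Character vector of "A"/"B" (or a `polymer_sequence`).
#' @param registry Enzyme-bound-pair registry tibble.
#' @param time Current simulation clock (tau).
#' @return A `sim_state` object.
#' @export
sim_state <- function(positions, species, registry = empty_registry(),
                      time = 0) {
  if (inherits(species, "polymer_sequence")) species <- species$species
  positions <- as_position_matrix(positions)
  stopifnot(nrow(positions) == length(species))
  structure(
    list(positions = positions, species = species, registry = registry,
         time = time),
    class = "sim_state"
  )
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> N = %d beads (%d A, %d B), t = %g tau, %d bound pairs\n",
              nrow(x$positions), sum(x$species == "A"),
              sum(x$species == "B"), x$time, nrow(x$registry)))
  invisible(x)
}

#' Integration protocol
#'
#' @param dt Time step (tau).
#' @param anneal_duration Equilibration span discarded before statistics
#'   (tau).
#' @param production_duration Production span (tau).
#' @param snapshot_interval Time between stored snapshots (tau).
#' @param seed Integer master seed.
#' @return A `bd_protocol` list.
#' @export
bd_protocol <- function(dt = 1e-4, anneal_duration = 2010,
                        production_duration = 2010,
                        snapshot_interval = 1, seed = 1L) {
  stopifnot(dt > 0, anneal_duration >= 0, production_duration >= 0,
            snapshot_interval > 0)
  structure(list(dt = dt, anneal_duration = anneal_duration,
                 production_duration = production_duration,
                 snapshot_interval = snapshot_interval,
                 seed = as.integer(seed)),
            class = "bd_protocol")
}

# sample one FENE bond length from its Boltzmann weight r^2 exp(-h_spring)
# on (0, r0) by inverse-CDF lookup (vectorized over n)
sample_fene_bond <- function(n, k, r0, grid = 2048L) {
  r <- seq(1e-6, r0 * (1 - 1e-9), length.out = grid)
  dens <- r^2 * (1 - (r / r0)^2)^(k * r0^2 / 2)
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, r, xout = stats::runif(n), yleft = r[1],
                yright = r[length(r)], ties = "ordered")$y
}

#' Initial conformation: equilibrated ideal chain in the cavity
#'
#' Builds a random walk whose bond lengths are drawn from the Boltzmann
#' weight of the FENE spring (the exact equilibrium of an ideal,
#' non-interacting chain) with uniformly random bond directions, rejecting
#' and resampling any step that would leave the geometry.
#'
#' @param seq A `polymer_sequence`.
#' @param params A [model_params()] object.
#' @param seed Integer seed.
#' @param max_retries Resampling budget per step before giving up.
#' @return A [sim_state()].
#' @export
init_conformation <- function(seq, params, seed = 1L, max_retries = 1000L) {
  set.seed(seed)
  sp <- seq$species
  N <- seq$N
  g <- params$geometry
  pos <- matrix(NA_real_, N, 3)
  margin <- 1e-3
  rand_inside <- function() {
    for (t in seq_len(max_retries)) {
      x <- if (g$type == "sphere") stats::runif(3, -g$radius, g$radius)
           else c(stats::runif(1, 0, g$Lx), stats::runif(1, 0, g$Ly),
                  stats::runif(1, 0, g$Lz))
      if (wall_distance(matrix(x, 1), g) > margin) return(x)
    }
    stop("could not place the first bead inside the geometry", call. = FALSE)
  }
  pos[1, ] <- rand_inside()
  sp_code <- species_code(sp)
  for (i in 2:N) {
    t <- sp_code[i - 1] + sp_code[i] + 1L   # 1 AA, 2 AB, 3 BB
    r0 <- params$r0[[t]]
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      len <- sample_fene_bond(1, params$k, r0)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cand <- pos[i - 1, ] + len * dir
      if (g$type == "slab") {
        cand[1] <- cand[1] %% g$Lx
        cand[2] <- cand[2] %% g$Ly
      }
      if (wall_distance(matrix(cand, 1), g) > margin) {
        pos[i, ] <- cand; ok <- TRUE; break
      }
    }
    if (!ok) stop(sprintf("placement failed at bead %d after %d retries",
                          i, max_retries), call. = FALSE)
  }
  sim_state(pos, sp)
}

#' Advance a state by BD steps
#'
#' Runs `n_steps` Euler-Maruyama steps (forces, thermal noise, then one
#' enzyme kinetic step each) through the compiled engine.  Uses R's RNG
#' stream; call [set.seed()] for reproducibility.
#'
#' @param state A [sim_state()].
#' @param params A [model_params()] object.
#' @param dt Time step (tau).
#' @param n_steps Number of steps.
#' @return The advanced [sim_state()].
#' @export
bd_step <- function(state, params, dt = 1e-4, n_steps = 1L) {
  res <- cpp_run_bd(state$positions, species_code(state$species),
                    registry_matrix(state$registry), cpp_params(params),
                    dt, as.numeric(n_steps), 0)
  new_state <- sim_state(res$positions, state$species,
                         registry_from_matrix(res$registry),
                         time = state$time + n_steps * dt)
  new_state
}

registry_from_matrix <- function(m) {
  if (nrow(m) == 0) return(empty_registry())
  tibble::tibble(i = m[, 1], j = m[, 2],
                 state = c("ATTRACTION", "NONE")[m[, 3]],
                 paused = FALSE)
}

#' Run the annealing + production protocol
#'
#' Anneals the state for `anneal_duration`, logs whether the mean-square
#' displacement accumulated during annealing exceeds the cavity radius
#' (a warning if not), then runs production while storing snapshots every
#' `snapshot_interval`.
#'
#' @param state Initial [sim_state()] (see [init_conformation()]).
#' @param params A [model_params()] object.
#' @param protocol A [bd_protocol()].
#' @param track_energy Record the potential energy at each snapshot.
#' @param quiet Suppress progress messages.
#' @return A `bd_trajectory`: list with `frames` (list of N x 3
#'   matrices), `times`, `species`, `bound_pairs`, `energies`, `params`,
#'   `protocol`, `anneal_msd`, and the final `state`.
#' @export
run_bd <- function(state, params, protocol, track_energy = FALSE,
                   quiet = TRUE) {
  set.seed(protocol$seed)
  dt <- protocol$dt
  n_anneal <- round(protocol$anneal_duration / dt)
  n_prod <- round(protocol$production_duration / dt)
  snap_every <- max(1, round(protocol$snapshot_interval / dt))

  anneal_start <- state$positions
  if (n_anneal > 0) {
    res <- cpp_run_bd(state$positions, species_code(state$species),
                      registry_matrix(state$registry), cpp_params(params),
                      dt, n_anneal, 0)
    state <- sim_state(res$positions, state$species,
                       registry_from_matrix(res$registry),
                       time = state$time + n_anneal * dt)
  }
  anneal_msd <- mean(rowSums((state$positions - anneal_start)^2))
  radius <- if (params$geometry$type == "sphere") params$geometry$radius
            else params$geometry$Lz / 2
  if (n_anneal > 0 && anneal_msd < radius) {
    warning(sprintf(
      "annealing MSD %.3g below the cavity radius %.3g; consider a longer anneal",
      anneal_msd, radius), call. = FALSE)
  }
  if (!quiet) message(sprintf("anneal done: MSD = %.3g (radius %.3g)",
                              anneal_msd, radius))

  frames <- list(); times <- numeric(0); bound <- integer(0)
  energies <- numeric(0)
  if (n_prod > 0) {
    res <- cpp_run_bd(state$positions, species_code(state$species),
                      registry_matrix(state$registry), cpp_params(params),
                      dt, n_prod, snap_every, 0.3, track_energy)
    frames <- res$snapshots
    times <- state$time + res$snapshot_times
    bound <- res$bound_pairs
    energies <- res$energies
    state <- sim_state(res$positions, state$species,
                       registry_from_matrix(res$registry),
                       time = state$time + n_prod * dt)
  }
  structure(
    list(frames = frames, times = times, species = state$species,
         bound_pairs = bound, energies = energies,
         params = params, protocol = protocol, anneal_msd = anneal_msd,
         state = state),
    class = "bd_trajectory"
  )
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf("<bd_trajectory> %d frames of %d beads, t in [%g, %g] tau (%s, %s)\n",
              length(x$frames), length(x$species),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA,
              x$params$variant, x$params$geometry$type))
  invisible(x)
}

#' Tidy a trajectory into a long tibble
#'
#' @param x A `bd_trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `frame`, `time`, `bead`, `species`, `x`,
#'   `y`, `z`.
#' @export
tidy.bd_trajectory <- function(x, ...) {
  purrr::imap_dfr(x$frames, function(m, k) {
    tibble::tibble(frame = k, time = x$times[k],
                   bead = seq_along(x$species), species = x$species,
                   x = m[, 1], y = m[, 2], z = m[, 3])
  })
}

#' @export
glance.bd_trajectory <- function(x, ...) {
  tibble::tibble(
    n_frames = length(x$frames),
    n_beads = length(x$species),
    variant = x$params$variant,
    activity = x$params$rates$activity,
    eps_HC = x$params$eps_HC,
    anneal_msd = x$anneal_msd,
    mean_bound_pairs = if (length(x$bound_pairs)) mean(x$bound_pairs) else NA_real_
  )
}

#' Neighbor pairs within a cutoff
#'
#' Exact list of unordered pairs with separation at most `cutoff`
#' (cell-list search, distance-filtered; minimum image in the slab's
#' periodic axes).
#'
#' @param positions N x 3 coordinate matrix.
#' @param cutoff Distance cutoff (l).
#' @param geometry Geometry description (defaults to an unbounded sphere
#'   large enough to hold the points).
#' @return Integer matrix with columns `i`, `j` (i < j, 1-based).
#' @export
neighbor_candidates <- function(positions, cutoff, geometry = NULL) {
  positions <- as_position_matrix(positions)
  if (is.null(geometry)) {
    geometry <- geometry_sphere(2 * (max(abs(positions)) + cutoff + 1))
  }
  gt <- if (geometry$type == "sphere") 0L else 1L
  gv <- if (gt == 0L) c(geometry$radius, 0, 0)
        else c(geometry$Lx, geometry$Ly, geometry$Lz)
  m <- cpp_neighbor_pairs(positions, cutoff, gt, gv)
  colnames(m) <- c("i", "j")
  m
}

#' Mean-square displacement along a trajectory
#'
#' @param traj A `bd_trajectory` (or list of frames).
#' @param reference_frame Index of the reference snapshot.
#' @return Tibble with `time`, `msd` (mean over beads, l^2) per frame.
#' @export
msd <- function(traj, reference_frame = 1L) {
  frames <- if (inherits(traj, "bd_trajectory")) traj$frames else traj
  times <- if (inherits(traj, "bd_trajectory")) traj$times
           else seq_along(frames)
  if (length(frames) < 2) stop("need at least two snapshots", call. = FALSE)
  ref <- frames[[reference_frame]]
  tibble::tibble(
    time = times,
    msd = vapply(frames, function(f) mean(rowSums((f - ref)^2)), numeric(1))
  )
}
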