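# Grid-based order-parameter analysis: the cavity is partitioned into
# cubic cells of linear size 1 l; each cell carries an accessible-volume
# weight v and per-species bead tallies, from which the local order
# parameter delta_phi = (nA*VA - nB*VB)/(nA*VA + nB*VB) and its
# v-weighted distribution (with Binder cumulant and skewness) follow.

#' Build the analysis grid and accessible-volume weights
#'
#' Covers the geometry's bounding box with cubic cells of edge
#' `cell_size` and estimates each cell's accessible-volume fraction `v`
#' as the fraction of a regular midpoint sub-grid of `subdiv^3` points
#' lying inside the geometry (deterministic).
#'
#' @param geometry A geometry description ([geometry_sphere()] /
#'   [geometry_slab()]).
#' @param cell_size Cell edge (l).
#' @param subdiv Sub-grid resolution per axis for the volume estimate.
#' @return A `grid_field` object: list with `origin`, `cell_size`, `dims`
#'   and a `cells` tibble (`ix, iy, iz, cx, cy, cz, v`).
#' @export
build_grid <- function(geometry, cell_size = 1, subdiv = 12L) {
  stopifnot(cell_size > 0, subdiv >= 1)
  if (geometry$type == "sphere") {
    R <- geometry$radius
    # odd cell count so one cell is centered on the cavity center
    n <- ceiling(2 * R / cell_size)
    if (n %% 2 == 0) n <- n + 1
    origin <- c(-n * cell_size / 2, -n * cell_size / 2, -n * cell_size / 2)
    dims <- c(n, n, n)
  } else {
    origin <- c(0, 0, 0)
    dims <- ceiling(c(geometry$Lx, geometry$Ly, geometry$Lz) / cell_size)
  }
  idx <- expand.grid(ix = seq_len(dims[1]), iy = seq_len(dims[2]),
                     iz = seq_len(dims[3]))
  cx <- origin[1] + (idx$ix - 0.5) * cell_size
  cy <- origin[2] + (idx$iy - 0.5) * cell_size
  cz <- origin[3] + (idx$iz - 0.5) * cell_size
  # midpoint sub-grid offsets within a cell
  o <- (seq_len(subdiv) - 0.5) / subdiv - 0.5
  sub <- as.matrix(expand.grid(o, o, o)) * cell_size
  inside <- function(pts) {
    ok <- wall_distance(pts, geometry) > 0
    if (geometry$type == "slab") {
      # periodic axes still bound the primary cell
      ok <- ok & pts[, 1] >= 0 & pts[, 1] < geometry$Lx &
        pts[, 2] >= 0 & pts[, 2] < geometry$Ly
    }
    ok
  }
  v <- vapply(seq_len(nrow(idx)), function(q) {
    pts <- sweep(sub, 2, c(cx[q], cy[q], cz[q]), "+")
    mean(inside(pts))
  }, numeric(1))
  structure(
    list(origin = origin, cell_size = cell_size, dims = dims,
         cells = tibble::tibble(ix = idx$ix, iy = idx$iy, iz = idx$iz,
                                cx = cx, cy = cy, cz = cz, v = v)),
    class = "grid_field"
  )
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %d x %d x %d cells of %g l (accessible volume %.3g l^3)\n",
              x$dims[1], x$dims[2], x$dims[3], x$cell_size,
              sum(x$cells$v) * x$cell_size^3))
  invisible(x)
}

# linear cell index for coordinates; NA outside the grid box
cell_index <- function(grid, positions) {
  positions <- as_position_matrix(positions)
  i <- floor((positions[, 1] - grid$origin[1]) / grid$cell_size) + 1
  j <- floor((positions[, 2] - grid$origin[2]) / grid$cell_size) + 1
  k <- floor((positions[, 3] - grid$origin[3]) / grid$cell_size) + 1
  ok <- i >= 1 & i <= grid$dims[1] & j >= 1 & j <= grid$dims[2] &
    k >= 1 & k <= grid$dims[3]
  out <- rep(NA_integer_, nrow(positions))
  out[ok] <- (i + (j - 1) * grid$dims[1] +
                (k - 1) * grid$dims[1] * grid$dims[2])[ok]
  out
}

#' Per-cell composition order parameter
#'
#' Tallies A and B beads per grid cell and computes `delta_phi = (nA*VA -
#' nB*VB)/(nA*VA + nB*VB)`; cells containing no beads carry `NA`.
#'
#' @param state A [sim_state()] (or anything with `positions` and
#'   `species`).
#' @param grid A [build_grid()] result.
#' @param volumes `c(V_A, V_B)` bead volumes.
#' @return The grid's `cells` tibble with added `nA`, `nB`, `delta_phi`.
#' @export
delta_phi_field <- function(state, grid, volumes = c(1, 1)) {
  ci <- cell_index(grid, state$positions)
  sc <- species_code(state$species)
  ncell <- prod(grid$dims)
  nA <- tabulate(ci[sc == 0L], nbins = ncell)
  nB <- tabulate(ci[sc == 1L], nbins = ncell)
  cells <- grid$cells
  cells$nA <- nA
  cells$nB <- nB
  tot <- nA * volumes[1] + nB * volumes[2]
  cells$delta_phi <- ifelse(tot > 0,
                            (nA * volumes[1] - nB * volumes[2]) / tot,
                            NA_real_)
  cells
}

#' Weighted Binder cumulant
#'
#' `1 - <x^4> / (3 <x^2>^2)` under weights `w`: 0 for Gaussian samples,
#' 2/3 for a symmetric two-point distribution.
#'
#' @param x Samples.
#' @param w Non-negative weights (renormalized internally).
#' @return Dimensionless cumulant.
#' @export
binder_cumulant <- function(x, w = rep(1, length(x))) {
  w <- w / sum(w)
  m2 <- sum(w * x^2); m4 <- sum(w * x^4)
  1 - m4 / (3 * m2^2)
}

#' Weighted moment coefficient of skewness
#'
#' @inheritParams binder_cumulant
#' @return `E[(x - mu)^3] / E[(x - mu)^2]^(3/2)` under weights `w`.
#' @export
skewness <- function(x, w = rep(1, length(x))) {
  w <- w / sum(w)
  mu <- sum(w * x)
  mu2 <- sum(w * (x - mu)^2)
  mu3 <- sum(w * (x - mu)^3)
  mu3 / mu2^1.5
}

#' Order-parameter distribution over a trajectory
#'
#' For each snapshot the per-cell `delta_phi` values are weighted by the
#' cells' accessible volumes `v` (renormalized over the cells that
#' contain beads) and accumulated into a histogram on \[-1, 1\]; the
#' histograms are averaged over snapshots.  The Binder cumulant and the
#' skewness are computed from the raw weighted samples, not the binned
#' histogram.
#'
#' @param traj A `bd_trajectory`, a single [sim_state()], or a list of
#'   states.
#' @param grid A [build_grid()] result.
#' @param volumes `c(V_A, V_B)` bead volumes.
#' @param n_bins Number of uniform histogram bins on \[-1, 1\].
#' @return An `order_param_stats` object: list with `histogram` tibble
#'   (`mid`, `density`), `binder`, `skewness`, `moments`, `n_snapshots`.
#' @export
order_param_stats <- function(traj, grid, volumes = c(1, 1), n_bins = 41L) {
  states <- as_state_list(traj)
  breaks <- seq(-1, 1, length.out = n_bins + 1)
  width <- diff(breaks)[1]
  hist_acc <- numeric(n_bins)
  mom_acc <- numeric(4)
  used <- 0L
  for (st in states) {
    cells <- delta_phi_field(st, grid, volumes)
    sel <- !is.na(cells$delta_phi) & cells$v > 0
    if (!any(sel)) next
    x <- cells$delta_phi[sel]
    w <- cells$v[sel]; w <- w / sum(w)
    bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1),
                n_bins)
    h <- vapply(seq_len(n_bins), function(b) sum(w[bin == b]), numeric(1))
    hist_acc <- hist_acc + h / width
    mom_acc <- mom_acc + c(sum(w * x), sum(w * x^2), sum(w * x^3),
                           sum(w * x^4))
    used <- used + 1L
  }
  if (used == 0L) stop("no occupied grid cells in any snapshot", call. = FALSE)
  hist_acc <- hist_acc / used
  m <- mom_acc / used
  mu2 <- m[2] - m[1]^2
  mu3 <- m[3] - 3 * m[1] * m[2] + 2 * m[1]^3
  structure(
    list(
      histogram = tibble::tibble(mid = (utils::head(breaks, -1) +
                                          utils::tail(breaks, -1)) / 2,
                                 density = hist_acc),
      binder = 1 - m[4] / (3 * m[2]^2),
      skewness = mu3 / mu2^1.5,
      moments = stats::setNames(m, c("m1", "m2", "m3", "m4")),
      n_snapshots = used,
      n_bins = n_bins
    ),
    class = "order_param_stats"
  )
}

as_state_list <- function(traj) {
  if (inherits(traj, "bd_trajectory")) {
    lapply(seq_along(traj$frames), function(k) {
      sim_state(traj$frames[[k]], traj$species, time = traj$times[k])
    })
  } else if (inherits(traj, "sim_state")) {
    list(traj)
  } else if (is.list(traj)) {
    traj
  } else stop("unsupported trajectory object", call. = FALSE)
}

#' @export
print.order_param_stats <- function(x, ...) {
  cat(sprintf("<order_param_stats> %d snapshot(s): Binder = %.4f, skewness = %.4f\n",
              x$n_snapshots, x$binder, x$skewness))
  invisible(x)
}

#' @export
tidy.order_param_stats <- function(x, ...) x$histogram

#' @export
glance.order_param_stats <- function(x, ...) {
  tibble::tibble(binder = x$binder, skewness = x$skewness,
                 mean = x$moments[["m1"]], n_snapshots = x$n_snapshots)
}

#' Radial density profiles
#'
#' Shell-volume-normalized mean bead counts against radius, per species
#' (sphere geometry).
#'
#' @param traj Trajectory or state (see [order_param_stats()]).
#' @param geometry A [geometry_sphere()].
#' @param n_shells Number of equal-width radial shells.
#' @return Tibble with `r_mid`, `species`, `density` (beads / l^3),
#'   averaged over snapshots.
#' @export
radial_density <- function(traj, geometry, n_shells = 12L) {
  stopifnot(geometry$type == "sphere")
  states <- as_state_list(traj)
  R <- geometry$radius
  edges <- seq(0, R, length.out = n_shells + 1)
  vol <- 4 / 3 * pi * diff(edges^3)
  acc <- matrix(0, n_shells, 2)
  for (st in states) {
    r <- sqrt(rowSums(st$positions^2))
    sc <- species_code(st$species)
    sh <- pmin(pmax(findInterval(r, edges, rightmost.closed = TRUE), 1),
               n_shells)
    acc[, 1] <- acc[, 1] + tabulate(sh[sc == 0L], n_shells)
    acc[, 2] <- acc[, 2] + tabulate(sh[sc == 1L], n_shells)
  }
  acc <- acc / length(states)
  tibble::tibble(
    r_mid = rep((utils::head(edges, -1) + utils::tail(edges, -1)) / 2, 2),
    species = rep(c("A", "B"), each = n_shells),
    density = c(acc[, 1] / vol, acc[, 2] / vol)
  )
}

#' Surface localization of B beads
#'
#' Fraction of B beads among all beads in the outermost shell of width
#' `shell_width`, divided by the global B volume fraction.
#'
#' @param traj Trajectory or state.
#' @param geometry Geometry description.
#' @param shell_width Surface shell width (l).
#' @param volumes `c(V_A, V_B)` bead volumes (global phi_B is a volume
#'   fraction).
#' @return The ratio `phi_B,surface / phi_B`; `NA` if the shell is empty
#'   in every snapshot.
#' @export
surface_fraction <- function(traj, geometry, shell_width = 1,
                             volumes = c(1, 1)) {
  states <- as_state_list(traj)
  sc <- species_code(states[[1]]$species)
  phiB <- sum(sc == 1L) * volumes[2] /
    (sum(sc == 0L) * volumes[1] + sum(sc == 1L) * volumes[2])
  if (phiB == 0) stop("no B beads: global phi_B is zero", call. = FALSE)
  fr <- vapply(states, function(st) {
    inshell <- wall_distance(st$positions, geometry) < shell_width
    if (!any(inshell)) return(NA_real_)
    scs <- species_code(st$species)
    nB <- sum(scs[inshell] == 1L) * volumes[2]
    tot <- sum(inshell & scs == 0L) * volumes[1] + nB
    nB / tot
  }, numeric(1))
  if (all(is.na(fr))) return(NA_real_)
  mean(fr, na.rm = TRUE) / phiB
}

#' Density cross-correlation between two runs
#'
#' Pearson correlation of per-cell densities of one species between two
#' trajectories analyzed on the same grid, computed per matched snapshot
#' index and averaged.
#'
#' @param traj1,traj2 Trajectories (or states) on the same geometry.
#' @param grid A shared [build_grid()].
#' @param species Which species to correlate ("A" or "B").
#' @return Mean Pearson correlation over snapshot pairs; pairs where
#'   either field has zero variance are dropped with a warning.
#' @export
density_cross_correlation <- function(traj1, traj2, grid, species = "A") {
  s1 <- as_state_list(traj1); s2 <- as_state_list(traj2)
  n <- min(length(s1), length(s2))
  keep <- grid$cells$v > 0
  dens <- function(st) {
    ci <- cell_index(grid, st$positions)
    sc <- species_code(st$species)
    want <- if (species == "A") 0L else 1L
    cnt <- tabulate(ci[sc == want], nbins = prod(grid$dims))
    (cnt / (grid$cells$v * grid$cell_size^3))[keep]
  }
  vals <- vapply(seq_len(n), function(k) {
    c1 <- dens(s1[[k]]); c2 <- dens(s2[[k]])
    if (stats::sd(c1) == 0 || stats::sd(c2) == 0) return(NA_real_)
    stats::cor(c1, c2)
  }, numeric(1))
  if (anyNA(vals)) {
    warning(sprintf("%d snapshot pair(s) with zero variance dropped",
                    sum(is.na(vals))), call. = FALSE)
  }
  mean(vals, na.rm = TRUE)
}
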