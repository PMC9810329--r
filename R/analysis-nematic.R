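# Local nematic order of chain bonds: per grid cell, the traceless
# alignment tensor Q = <(3 u u' - I)/2> over the unit bond vectors
# assigned to the cell; the cell's order parameter S is the Q eigenvalue
# of largest magnitude (+1 for aligned bonds, -1/2 for bonds isotropic
# within a plane).

#' Local nematic order parameter of AA or BB bonds
#'
#' Bonds are the vectors between consecutive beads that are both of the
#' requested species, normalized to unit length and assigned to grid
#' cells by their midpoints.  Per cell, the bond-averaged tensor
#' `Q = (3<u u'> - I)/2` is diagonalized and the eigenvalue of largest
#' magnitude is the local order parameter `S_j`.  The scalar mean `S` is
#' the bond-count-weighted average of `S_j` over cells away from the
#' wall (cells whose center lies within `surface_width` of the wall are
#' the surface region and are excluded).
#'
#' @param traj Trajectory or state; with multiple snapshots the per-cell
#'   tensors accumulate over all snapshots before diagonalization.
#' @param grid A [build_grid()] result.
#' @param bond_species `"AA"` or `"BB"`.
#' @param geometry Geometry for the surface-shell exclusion (defaults to
#'   a sphere inscribed in the grid).
#' @param surface_width Width of the excluded surface shell (l).
#' @return A `local_nematic` object: list with `cells` tibble (`cell`,
#'   `q` bond count, `S`, `surface`) and scalar `mean_S`.
#' @export
local_nematic <- function(traj, grid, bond_species = c("AA", "BB"),
                          geometry = NULL, surface_width = 1) {
  bond_species <- match.arg(bond_species)
  states <- as_state_list(traj)
  want <- if (bond_species == "AA") 0L else 1L
  ncell <- prod(grid$dims)
  # accumulate the 6 independent components of sum(u u') and counts
  acc <- matrix(0, ncell, 6)
  qn <- numeric(ncell)
  found <- FALSE
  for (st in states) {
    sc <- species_code(st$species)
    pos <- st$positions
    n <- nrow(pos)
    sel <- which(sc[-n] == want & sc[-1] == want)
    if (length(sel) == 0) next
    found <- TRUE
    u <- pos[sel + 1L, , drop = FALSE] - pos[sel, , drop = FALSE]
    if (!is.null(geometry) && geometry$type == "slab") {
      # minimum image across the periodic axes
      u[, 1] <- u[, 1] - geometry$Lx * round(u[, 1] / geometry$Lx)
      u[, 2] <- u[, 2] - geometry$Ly * round(u[, 2] / geometry$Ly)
    }
    len <- sqrt(rowSums(u^2))
    u <- u / len
    mid <- pos[sel, , drop = FALSE] + u * len / 2
    if (!is.null(geometry) && geometry$type == "slab") {
      mid[, 1] <- mid[, 1] %% geometry$Lx
      mid[, 2] <- mid[, 2] %% geometry$Ly
    }
    ci <- cell_index(grid, mid)
    ok <- !is.na(ci)
    ci <- ci[ok]; u <- u[ok, , drop = FALSE]
    comp <- cbind(u[, 1]^2, u[, 2]^2, u[, 3]^2,
                  u[, 1] * u[, 2], u[, 1] * u[, 3], u[, 2] * u[, 3])
    for (cidx in 1:6) {
      acc[, cidx] <- acc[, cidx] +
        unname(rowsum_vec(comp[, cidx], ci, ncell))
    }
    qn <- qn + tabulate(ci, nbins = ncell)
  }
  if (!found) stop(sprintf("no %s bonds in the trajectory", bond_species),
                   call. = FALSE)
  occ <- which(qn > 0)
  S <- rep(NA_real_, ncell)
  for (c0 in occ) {
    m <- acc[c0, ] / qn[c0]
    M <- matrix(c(m[1], m[4], m[5],
                  m[4], m[2], m[6],
                  m[5], m[6], m[3]), 3, 3)
    Q <- (3 * M - diag(3)) / 2
    ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
    S[c0] <- ev[which.max(abs(ev))]
  }
  if (is.null(geometry)) {
    geometry <- geometry_sphere(min(grid$dims) * grid$cell_size)
  }
  centers <- as.matrix(grid$cells[, c("cx", "cy", "cz")])
  surface <- wall_distance(centers, geometry) < surface_width
  inner <- occ[!surface[occ]]
  mean_S <- if (length(inner) > 0) {
    sum(qn[inner] * S[inner]) / sum(qn[inner])
  } else NA_real_
  structure(
    list(cells = tibble::tibble(cell = occ, q = qn[occ], S = S[occ],
                                surface = surface[occ]),
         mean_S = mean_S, bond_species = bond_species),
    class = "local_nematic"
  )
}

# sum of x grouped by integer index (1..n)
rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.local_nematic <- function(x, ...) {
  cat(sprintf("<local_nematic> %s bonds in %d cells; mean S = %.4f\n",
              x$bond_species, nrow(x$cells), x$mean_S))
  invisible(x)
}

#' @export
tidy.local_nematic <- function(x, ...) x$cells

#' @export
glance.local_nematic <- function(x, ...) {
  tibble::tibble(bond_species = x$bond_species, mean_S = x$mean_S,
                 n_cells = nrow(x$cells), n_bonds = sum(x$cells$q))
}
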