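# Heterochromatin focus segmentation: single-linkage clustering of B
# beads at the bead-size cutoff, followed by gyration-tensor shape
# analysis of each retained cluster.

#' Segment heterochromatin foci
#'
#' Connects B beads separated by at most `cutoff` (single-linkage
#' connected components); clusters with fewer than `min_size` members are
#' discarded as noise.  For each focus the gyration tensor `G = (1/n)
#' sum r r'` in the center-of-mass frame is diagonalized into
#' eigenvalues `lambda_m^2`; the radius of gyration is `sqrt(sum
#' lambda^2)` and the relative shape anisotropy `kappa^2 = (3/2) sum
#' lambda^4 / (sum lambda^2)^2 - 1/2` (0 spherical, 1 collinear).
#'
#' @param positions Coordinates of the B beads (n x 3 matrix or a
#'   [sim_state()], from which B beads are extracted).
#' @param cutoff Linking distance (l); defaults to the B bead diameter of
#'   the monodisperse preset.
#' @param min_size Minimum focus size (beads); twice the block size by
#'   default.
#' @return A `foci_set` tibble: one row per focus with `focus`, `size`,
#'   `Rg`, `kappa_sq`, `radial_position`, `lambda_sq` (list of 3
#'   eigenvalues) and `members` (list of row indices).
#' @export
segment_foci <- function(positions, cutoff = 50.5086 / 117.6,
                         min_size = 8L) {
  if (inherits(positions, "sim_state")) {
    positions <- positions$positions[species_code(positions$species) == 1L, ,
                                     drop = FALSE]
  }
  positions <- as_position_matrix(positions)
  n <- nrow(positions)
  empty <- tibble::tibble(focus = integer(), size = integer(),
                          Rg = numeric(), kappa_sq = numeric(),
                          radial_position = numeric(),
                          lambda_sq = list(), members = list())
  class(empty) <- c("foci_set", class(empty))
  if (n == 0) return(empty)
  comp <- single_linkage_components(positions, cutoff)
  keep <- which(tabulate(comp) >= min_size)
  if (length(keep) == 0) return(empty)
  rows <- lapply(seq_along(keep), function(q) {
    members <- which(comp == keep[q])
    pts <- positions[members, , drop = FALSE]
    com <- colMeans(pts)
    centered <- sweep(pts, 2, com)
    G <- crossprod(centered) / nrow(centered)
    lam <- sort(eigen(G, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
    lam[lam < 0] <- 0   # numerical floor
    s2 <- sum(lam)
    tibble::tibble(
      focus = q,
      size = length(members),
      Rg = sqrt(s2),
      kappa_sq = if (s2 > 0) 1.5 * sum(lam^2) / s2^2 - 0.5 else 0,
      radial_position = mean(sqrt(rowSums(pts^2))),
      lambda_sq = list(lam),
      members = list(members)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("foci_set", class(out))
  out
}

# connected components of the distance <= cutoff graph via union-find on
# cell-list neighbor pairs
single_linkage_components <- function(positions, cutoff) {
  n <- nrow(positions)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  pairs <- neighbor_candidates(positions, cutoff)
  for (q in seq_len(nrow(pairs))) {
    ra <- find(pairs[q, 1]); rb <- find(pairs[q, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' @export
glance.foci_set <- function(x, ...) {
  tibble::tibble(n_foci = nrow(x),
                 total_beads = sum(x$size),
                 mean_Rg = mean(x$Rg),
                 mean_kappa_sq = mean(x$kappa_sq))
}
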