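# Configuration-analysis suite: grid weights, order-parameter
# statistics, nematic order, focus segmentation and profiles.

test_that("accessible-volume weights reproduce the sphere volume", {
  g <- geometry_sphere(8)
  grid <- build_grid(g, 1, subdiv = 12)
  # interior cell fully inside: the center cell
  center <- dplyr::filter(grid$cells, cx == 0, cy == 0, cz == 0)
  expect_equal(center$v, 1)
  # corner cell fully outside
  corner <- grid$cells[which.max(abs(grid$cells$cx) + abs(grid$cells$cy) +
                                   abs(grid$cells$cz)), ]
  expect_equal(corner$v, 0)
  vol <- sum(grid$cells$v) * grid$cell_size^3
  expect_equal(vol, pi * 8^3 / 6, tolerance = 5e-3)
})

test_that("per-cell order parameter matches a hand tally", {
  g <- geometry_sphere(6)
  grid <- build_grid(g, 1, subdiv = 4)
  # three beads in one cell (2 A, 1 B), one lone B elsewhere
  pos <- rbind(c(0.2, 0.1, 0.3), c(0.3, 0.2, 0.1), c(0.1, 0.3, 0.2),
               c(-1.6, -1.3, 0.4))
  st <- sim_state(pos, c("A", "A", "B", "B"))
  cells <- delta_phi_field(st, grid, volumes = c(2, 3))
  ci <- chromactive:::cell_index(grid, pos)
  expect_equal(cells$delta_phi[ci[1]], (2 * 2 - 1 * 3) / (2 * 2 + 1 * 3))
  expect_equal(cells$delta_phi[ci[4]], -1)
  expect_equal(sum(cells$nA) + sum(cells$nB), 4)
  # all-A cell is +1; matched-volume cell is 0
  stA <- sim_state(pos[1:2, ], c("A", "A"))
  expect_equal(delta_phi_field(stA, grid)$delta_phi[ci[1]], 1)
  stAB <- sim_state(pos[1:2, ], c("A", "B"))
  expect_equal(delta_phi_field(stAB, grid, c(3, 3))$delta_phi[ci[1]], 0)
})

test_that("order parameter distribution is normalized and delta_phi bounded", {
  st <- make_fixture("uniform_mixture", n = 2000, seed = 3, radius = 5)
  g <- geometry_sphere(10)
  grid <- build_grid(g, 1, subdiv = 6)
  ops <- order_param_stats(st, grid)
  binw <- 2 / ops$n_bins
  expect_equal(sum(ops$histogram$density) * binw, 1, tolerance = 1e-9)
  cells <- delta_phi_field(st, grid)
  dp <- cells$delta_phi[!is.na(cells$delta_phi)]
  expect_true(all(dp >= -1 & dp <= 1))
})

test_that("Binder cumulant hits its two-point and Gaussian anchors", {
  # half the v-weight at +1, half at -1 -> exactly 2/3
  x <- c(1, -1); w <- c(0.5, 0.5)
  expect_equal(binder_cumulant(x, w), 2 / 3)
  expect_equal(skewness(x, w), 0)
  set.seed(10)
  gs <- make_fixture("gaussian_field", n = 1e6, seed = 10)
  expect_lt(abs(binder_cumulant(gs)), 0.01)
  expect_lt(abs(skewness(gs)), 0.01)
  # any symmetric sample has zero skewness
  xs <- c(-2, -1, 0, 1, 2)
  expect_equal(skewness(xs), 0)
  # Binder is at most 2/3 over many random weighted samples
  for (k in 1:20) {
    xx <- stats::runif(50, -1, 1); ww <- stats::runif(50)
    expect_lte(binder_cumulant(xx, ww), 2 / 3 + 1e-12)
  }
})

test_that("two-phase and noisy synthetic fields bracket the Binder scale", {
  g <- geometry_sphere(10)
  grid <- build_grid(g, 1, subdiv = 6)
  two <- make_fixture("two_phase_sphere", n = 6000, seed = 5, radius = 5)
  mixed <- make_fixture("uniform_mixture", n = 6000, seed = 5, radius = 5)
  b_two <- order_param_stats(two, grid)$binder
  b_mixed <- order_param_stats(mixed, grid)$binder
  expect_gt(b_two, 0.4)
  expect_lt(abs(b_mixed), 0.25)
  expect_gt(b_two, b_mixed)
})

test_that("nematic order hits the aligned, planar and isotropic anchors", {
  g <- geometry_sphere(10)
  grid <- build_grid(g, 1, subdiv = 4)
  # perfectly aligned bonds -> S = 1 in the occupied cell
  n <- 40
  pos <- cbind(seq(0, by = 0.05, length.out = n), 0, 0)
  aligned <- local_nematic(sim_state(pos, rep("A", n)), grid, "AA", g)
  expect_equal(max(aligned$cells$S), 1, tolerance = 1e-9)
  # bonds isotropic in a plane -> S = -1/2
  planar <- make_fixture("planar_bonds", n = 6000, seed = 8)
  lp <- local_nematic(planar, grid, "AA", g)
  Sp <- lp$cells$S[which.max(lp$cells$q)]
  expect_equal(Sp, -0.5, tolerance = 0.02)
  # isotropic random bonds -> |S| small
  set.seed(12)
  dirs <- matrix(stats::rnorm(3 * 10000), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pos_iso <- matrix(0, 10001, 3)
  for (i in 1:10000) pos_iso[i + 1, ] <- pos_iso[i, ] + 0.0004 * dirs[i, ]
  iso <- local_nematic(sim_state(pos_iso, rep("A", 10001)), grid, "AA", g)
  expect_lt(abs(iso$cells$S[which.max(iso$cells$q)]), 0.03)
  # spherical-shell chain (bonds tangent to the wall) -> negative S
  # the fixture winds at 0.6 * radius = 3, well inside the surface shell
  shell <- make_fixture("shell_wall_bonds", n = 4000, seed = 9, radius = 5)
  ls <- local_nematic(shell, grid, "AA", g, surface_width = 1)
  expect_lt(ls$mean_S, -0.1)
  expect_error(local_nematic(shell, grid, "BB", g), "BB bonds")
})

test_that("focus segmentation matches brute-force union-find and is rigid-motion invariant", {
  set.seed(14)
  pos <- matrix(stats::runif(900, -3, 3), 300, 3)
  cutoff <- 0.6
  got <- chromactive:::single_linkage_components(pos, cutoff)
  # brute-force union-find over the full distance matrix
  parent <- seq_len(300)
  findr <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  d <- as.matrix(stats::dist(pos))
  for (i in 1:299) for (j in (i + 1):300) {
    if (d[i, j] <= cutoff) {
      ri <- findr(i); rj <- findr(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  want <- vapply(1:300, findr, integer(1))
  expect_equal(length(unique(got)), length(unique(want)))
  expect_true(all(tapply(got, want, function(x) length(unique(x))) == 1))

  foci <- segment_foci(pos, cutoff = cutoff, min_size = 5L)
  # rotation + relabeling leaves sizes, Rg, kappa^2 unchanged
  th <- 1.1
  Rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  perm <- sample(300)
  foci2 <- segment_foci(pos[perm, ] %*% Rot, cutoff = cutoff, min_size = 5L)
  expect_equal(sort(foci2$size), sort(foci$size))
  expect_equal(sort(foci2$Rg), sort(foci$Rg), tolerance = 1e-9)
  expect_equal(sort(foci2$kappa_sq), sort(foci$kappa_sq), tolerance = 1e-9)
})

test_that("focus shape anisotropy separates lines from balls", {
  line <- make_fixture("line_cluster", n = 40, seed = 2, spacing = 0.3)
  f_line <- segment_foci(line, cutoff = 0.43, min_size = 8L)
  expect_equal(nrow(f_line), 1)
  expect_equal(f_line$kappa_sq, 1, tolerance = 1e-9)
  ball <- make_fixture("ball_cluster", n = 10000, seed = 3, radius = 2)
  f_ball <- segment_foci(ball, cutoff = 0.43, min_size = 8L)
  expect_equal(nrow(f_ball), 1)
  expect_lt(f_ball$kappa_sq, 0.01)
  expect_equal(f_ball$Rg^2, sum(f_ball$lambda_sq[[1]]), tolerance = 1e-12)
  # empty input and sub-threshold clusters
  expect_equal(nrow(segment_foci(matrix(0, 0, 3))), 0)
  expect_equal(nrow(segment_foci(matrix(0, 3, 3) + diag(3) * 5,
                                 cutoff = 0.4, min_size = 2L)), 0)
})

test_that("surface fraction is unity for a uniform mixture and handles degenerate input", {
  g <- geometry_sphere(10)
  st <- make_fixture("uniform_mixture", n = 20000, seed = 6, radius = 5)
  expect_equal(surface_fraction(st, g), 1, tolerance = 0.1)
  # all B at the surface, all A in the core
  set.seed(7)
  rA <- runif(500, 0, 2); rB <- runif(500, 4.2, 4.9)
  dirs <- function(n) {
    m <- matrix(stats::rnorm(3 * n), ncol = 3); m / sqrt(rowSums(m^2))
  }
  pos <- rbind(dirs(500) * rA, dirs(500) * rB)
  st2 <- sim_state(pos, rep(c("A", "B"), each = 500))
  expect_equal(surface_fraction(st2, g), 1 / 0.5, tolerance = 1e-9)
  st3 <- sim_state(pos, rep("A", 1000))
  expect_error(surface_fraction(st3, g), "phi_B")
})

test_that("radial density conserves counts and is flat for uniform beads", {
  g <- geometry_sphere(10)
  st <- make_fixture("uniform_mixture", n = 30000, seed = 8, radius = 5)
  prof <- radial_density(st, g, n_shells = 10)
  tot <- sum(prof$density * rep(4 / 3 * pi * diff(seq(0, 5, by = 0.5)^3), 2))
  expect_equal(tot, 30000)
  inner <- dplyr::filter(prof, r_mid > 1, r_mid < 4.6)
  expect_lt(stats::sd(inner$density) / mean(inner$density), 0.15)
  # all beads in one shell
  stshell <- sim_state(cbind(2.5, 0, 0)[rep(1, 10), ], rep("A", 10))
  p2 <- radial_density(stshell, g, n_shells = 5)
  expect_equal(sum(p2$density > 0), 1)
})

test_that("density cross-correlation hits its fixed points", {
  g <- geometry_sphere(8)
  grid <- build_grid(g, 1, subdiv = 4)
  st <- make_fixture("uniform_mixture", n = 3000, seed = 9, radius = 4)
  expect_equal(density_cross_correlation(st, st, grid), 1, tolerance = 1e-12)
  # two independent uniform configurations decorrelate
  st2 <- make_fixture("uniform_mixture", n = 3000, seed = 10, radius = 4)
  expect_lt(abs(density_cross_correlation(st, st2, grid)), 0.15)
  # zero-variance field (no A beads anywhere) is dropped with a warning
  stz <- sim_state(matrix(rep(c(0.1, 0.2, 0.1), 5), 5, 3, byrow = TRUE),
                   rep("B", 5))
  expect_warning(out <- density_cross_correlation(stz, stz, grid, "A"),
                 "zero variance")
  expect_true(is.nan(out) || is.na(out))
})
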