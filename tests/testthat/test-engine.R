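# Brownian-dynamics engine: initialization, neighbor search,
# integration statistics and trajectory plumbing.

test_that("ideal-chain initialization is inside, bonded and deterministic", {
  p <- monodisperse_params(N = 64)
  sq <- generate_sequence(64, 4, 0.5, seed = 5)
  st <- init_conformation(sq, p, seed = 6)
  expect_true(all(wall_distance(st$positions, p$geometry) > 0))
  bonds <- sqrt(rowSums((st$positions[-1, ] - st$positions[-64, ])^2))
  expect_true(all(bonds < p$r0[["BB"]]))
  st2 <- init_conformation(sq, p, seed = 6)
  expect_identical(st$positions, st2$positions)
  st3 <- init_conformation(sq, p, seed = 7)
  expect_false(identical(st$positions, st3$positions))
})

test_that("initial bond lengths follow the FENE Boltzmann weight", {
  p <- monodisperse_params(N = 2)
  p$geometry <- geometry_sphere(60)   # wall rejection negligible
  sq <- generate_sequence(2, 1, 0.5, seed = 1)
  lens <- vapply(1:600, function(k) {
    st <- init_conformation(sq, p, seed = k)
    sqrt(sum((st$positions[2, ] - st$positions[1, ])^2))
  }, numeric(1))
  # numerically normalized Boltzmann density of the FENE bond
  r0 <- p$r0[["AB"]]
  cdf <- function(q) {
    vapply(q, function(x) {
      stats::integrate(function(r) r^2 * (1 - (r / r0)^2)^(p$k * r0^2 / 2),
                       0, min(x, r0 * (1 - 1e-12)))$value
    }, numeric(1)) /
      stats::integrate(function(r) r^2 * (1 - (r / r0)^2)^(p$k * r0^2 / 2),
                       0, r0 * (1 - 1e-12))$value
  }
  ks <- suppressWarnings(stats::ks.test(lens, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("neighbor search equals brute force on random configurations", {
  set.seed(17)
  for (rep in 1:3) {
    pos <- matrix(stats::runif(600, -4, 4), 200, 3)
    got <- neighbor_candidates(pos, 1, geometry_sphere(20))
    want <- brute_pairs(pos, 1)
    o <- order(got[, 1], got[, 2])
    expect_equal(got[o, , drop = FALSE], want, ignore_attr = TRUE)
  }
  expect_equal(nrow(neighbor_candidates(matrix(0, 1, 3), 1)), 0)
})

test_that("slab neighbor search honors the periodic minimum image", {
  g <- geometry_slab(8, 8, 6)
  pos <- rbind(c(0.2, 4, 3), c(7.9, 4, 3),   # 0.3 apart across the seam
               c(4, 0.1, 3), c(4, 7.8, 3))   # 0.3 apart across the seam
  got <- neighbor_candidates(pos, 1, g)
  expect_true(all(c(paste(1, 2), paste(3, 4)) %in%
                    paste(got[, 1], got[, 2])))
})

test_that("a single free bead obeys the Einstein relation", {
  # far from the wall the bead diffuses freely: MSD(t) = 6 D t with
  # D = kBT / (3 pi eta d) (reduced units)
  p1 <- monodisperse_params(N = 1, variant = "PASSIVE")
  p1$geometry <- geometry_sphere(400)
  msds <- vapply(1:200, function(k) {
    set.seed(1000 + k)
    st1 <- sim_state(matrix(0, 1, 3), "A")
    out <- bd_step(st1, p1, dt = 1e-3, n_steps = 100)
    sum(out$positions^2)
  }, numeric(1))
  D <- 1 / (3 * pi * p1$d_A)
  want <- 6 * D * 0.1
  se <- stats::sd(msds) / sqrt(length(msds))
  expect_lt(abs(mean(msds) - want), 3 * se)
})

test_that("passive bonded dimer samples the Boltzmann bond-length density", {
  p <- monodisperse_params(N = 2, variant = "PASSIVE")
  p$geometry <- geometry_sphere(50)
  st <- sim_state(rbind(c(0, 0, 0), c(0.43, 0, 0)), c("A", "A"))
  set.seed(61)
  lens <- numeric(400)
  for (k in seq_along(lens)) {
    st <- bd_step(st, p, dt = 1e-4, n_steps = 2000)  # decorrelating stride
    lens[k] <- sqrt(sum((st$positions[2, ] - st$positions[1, ])^2))
  }
  r0 <- p$r0[["AA"]]
  dens <- function(r) {
    r^2 * exp(-(fene_energy(r, p$k, r0) +
                  vex_energy(r, "REPULSION", p$eps_vex[["AA"]],
                             p$alpha_vex[["AA"]])))
  }
  Z <- stats::integrate(dens, 0, r0 * (1 - 1e-12))$value
  cdf <- function(q) {
    vapply(q, function(x) {
      stats::integrate(dens, 0, min(x, r0 * (1 - 1e-12)))$value / Z
    }, numeric(1))
  }
  ks <- suppressWarnings(stats::ks.test(lens, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("confined single bead samples the wall Boltzmann weight", {
  p <- monodisperse_params(N = 1, variant = "PASSIVE")
  p$geometry <- geometry_sphere(3)   # small cavity: many wall crossings
  st <- sim_state(matrix(0, 1, 3), "A")
  set.seed(71)
  rads <- numeric(300)
  for (k in seq_along(rads)) {
    st <- bd_step(st, p, dt = 1e-4, n_steps = 5000)
    rads[k] <- sqrt(sum(st$positions^2))
  }
  R <- p$geometry$radius
  dens <- function(r) r^2 * exp(-confinement_energy(R - r, p$conf_A))
  Z <- stats::integrate(dens, 1e-9, R - 1e-6)$value
  cdf <- function(q) {
    vapply(q, function(x) {
      stats::integrate(dens, 1e-9, min(x, R - 1e-6))$value / Z
    }, numeric(1))
  }
  ks <- suppressWarnings(stats::ks.test(rads, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("runs are deterministic given the protocol seed and snapshots count correctly", {
  p <- monodisperse_params(N = 32, eps_HC = 2, lambda_ra = 10)
  sq <- generate_sequence(32, 4, 0.5, seed = 2)
  st <- init_conformation(sq, p, seed = 3)
  pr <- bd_protocol(1e-4, anneal_duration = 0.05, production_duration = 0.2,
                    snapshot_interval = 0.05, seed = 12)
  t1 <- suppressWarnings(run_bd(st, p, pr))
  t2 <- suppressWarnings(run_bd(st, p, pr))
  expect_identical(t1$frames, t2$frames)
  expect_equal(length(t1$frames), 4)   # floor(production / interval)
  expect_equal(t1$times, st$time + 0.05 + c(0.05, 0.1, 0.15, 0.2))
  # zero production -> empty trajectory, state still advanced by anneal
  pr0 <- bd_protocol(1e-4, 0.05, 0, seed = 12)
  t0 <- suppressWarnings(run_bd(st, p, pr0))
  expect_equal(length(t0$frames), 0)
  expect_equal(t0$state$time, st$time + 0.05)
  expect_false(identical(t0$state$positions, st$positions))
})

test_that("replaying from a checkpointed state and RNG is bit-for-bit identical", {
  p <- monodisperse_params(N = 32, lambda_ra = 10)
  sq <- generate_sequence(32, 4, 0.5, seed = 2)
  st <- init_conformation(sq, p, seed = 3)
  set.seed(9)
  b1 <- bd_step(st, p, n_steps = 200)      # checkpoint: state + RNG
  rng_mid <- .Random.seed
  b2 <- bd_step(b1, p, n_steps = 200)
  # restore the checkpoint and replay the same segment
  assign(".Random.seed", rng_mid, envir = globalenv())
  b2bis <- bd_step(b1, p, n_steps = 200)
  expect_identical(b2$positions, b2bis$positions)
  expect_identical(b2$registry, b2bis$registry)
  # a different RNG state diverges (the noise is really being used)
  set.seed(10)
  b2other <- bd_step(b1, p, n_steps = 200)
  expect_false(identical(b2$positions, b2other$positions))
})

test_that("msd handles trivial cases and linear drift", {
  frames <- list(matrix(1:12, 4, 3) * 1.0, matrix(1:12, 4, 3) * 1.0)
  expect_equal(msd(frames)$msd, c(0, 0))
  v <- c(0.3, -0.2, 0.1)
  drift <- lapply(0:5, function(t) {
    sweep(matrix(0, 4, 3), 2, v * t, "+")
  })
  out <- msd(drift)
  expect_equal(out$msd, sum(v^2) * (0:5)^2)
  expect_error(msd(list(matrix(0, 2, 3))), "two snapshots")
})

test_that("zero-temperature-like limit: no force means no motion", {
  # one bead exactly at the cavity center feels zero net force; with the
  # noise amplitude suppressed by a tiny dt the displacement is O(sqrt(dt))
  p <- monodisperse_params(N = 1, variant = "PASSIVE")
  p$geometry <- geometry_sphere(6)
  st <- sim_state(matrix(0, 1, 3), "A")
  FF <- total_forces(st, p)
  expect_equal(max(abs(FF)), 0, tolerance = 1e-10)
})

test_that("passive production is stationary (no energy trend)", {
  p <- monodisperse_params(N = 64, eps_HC = 2)
  sq <- generate_sequence(64, 4, 0.5, seed = 21)
  st <- init_conformation(sq, p, seed = 22)
  tr <- suppressWarnings(run_bd(st, p, bd_protocol(1e-4, 3, 4,
                                                   snapshot_interval = 0.1,
                                                   seed = 23),
                                track_energy = TRUE))
  fit <- stats::lm(tr$energies ~ tr$times)
  ci <- stats::confint(fit)["tr$times", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
  # chain extension is stationary too
  rg <- vapply(tr$frames, function(f) {
    sqrt(mean(rowSums(sweep(f, 2, colMeans(f))^2)))
  }, numeric(1))
  fit2 <- stats::lm(rg ~ tr$times)
  ci2 <- stats::confint(fit2)["tr$times", ]
  expect_true(ci2[1] < 0 && ci2[2] > 0)
})

test_that("the non-transient variant applies the cycle-averaged potential with no registry", {
  p <- monodisperse_params(N = 2, lambda_ra = 0.5, variant = "NONTRANSIENT")
  p$geometry <- geometry_sphere(40)
  r <- 0.4
  st <- sim_state(rbind(c(0, 0, 0), c(r, 0, 0)), c("A", "A"))
  eps_eff <- nontransient_eps(p)
  want <- fene_energy(r, p$k, p$r0[["AA"]]) +
    eps_eff * exp(-p$alpha_vex[["AA"]] * r^2) +
    sum(confinement_energy(wall_distance(st$positions, p$geometry),
                           p$conf_A))
  expect_equal(total_energy(st, p), want, tolerance = 1e-9)
  # kinetics never populates the registry in this variant
  set.seed(30)
  out <- bd_step(st, p, n_steps = 500)
  expect_equal(nrow(out$registry), 0)
})
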