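# Catch-and-release state machine: eligibility, transitions, dwell
# statistics and variant behaviour.

test_that("eligibility finds proximal AA pairs under the exclusion rules", {
  p <- tiny_params(12, cavity = 30)
  # no A beads -> nothing eligible
  st_b <- sim_state(matrix(stats::rnorm(30, sd = 0.2), 10), rep("B", 10))
  expect_equal(nrow(find_eligible(st_b, params = p)), 0)
  # two bonded adjacent A beads at 0.43 l: excluded by default,
  # included without the neighbor-exclusion assumption
  st2 <- sim_state(rbind(c(0, 0, 0), c(0.43, 0, 0)), c("A", "A"))
  expect_equal(nrow(find_eligible(st2, params = p)), 0)
  p_nx <- p; p_nx$exclude_neighbors <- FALSE
  el <- find_eligible(st2, params = p_nx)
  expect_equal(nrow(el), 1)
  expect_equal(c(el$i, el$j), c(1, 2))
  # already-bound beads are skipped under exclusive binding
  reg <- tibble::tibble(i = 1L, j = 2L, state = "ATTRACTION",
                        paused = FALSE)
  expect_equal(nrow(find_eligible(st2, reg, p_nx)), 0)
})

test_that("eligibility equals a brute-force scan on a random configuration", {
  set.seed(77)
  n <- 100
  pos <- matrix(stats::runif(3 * n, -3, 3), n, 3)
  species <- sample(c("A", "B"), n, replace = TRUE)
  st <- sim_state(pos, species)
  p <- tiny_params(n, cavity = 30)
  el <- find_eligible(st, params = p)
  # brute force
  want <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (species[i] == "A" && species[j] == "A" && j - i > 1 &&
        sum((pos[i, ] - pos[j, ])^2) <= 1) {
      want <- rbind(want, c(i, j))
    }
  }
  expect_equal(as.matrix(el[, c("i", "j")]), want,
               ignore_attr = TRUE)
})

test_that("pair states dispatch correctly and complete the cycle", {
  reg <- tibble::tibble(i = 2L, j = 7L, state = "ATTRACTION",
                        paused = FALSE)
  expect_equal(pair_state_of(2, 7, reg), "ATTRACTION")
  expect_equal(pair_state_of(7, 2, reg), "ATTRACTION")
  expect_equal(pair_state_of(3, 7, reg), "REPULSION")
  species <- rep(c("A", "B"), 5)
  expect_equal(pair_state_of(2, 7, reg, species), "REPULSION")  # B involved
  # full cycle walk: bind -> advance -> release returns to repulsion
  p <- tiny_params(4, lambda_ra = 1e9)
  p$rates <- enzyme_rates(1e6, 1e6, 1e6)
  elig <- tibble::tibble(i = 1L, j = 3L)
  set.seed(4)
  r1 <- kinetics_step(empty_registry(), elig, p, dt = 1)
  expect_equal(pair_state_of(1, 3, r1), "ATTRACTION")
  r2 <- kinetics_step(r1, elig[0, ], p, dt = 1)
  expect_equal(pair_state_of(1, 3, r2), "NONE")
  r3 <- kinetics_step(r2, elig[0, ], p, dt = 1)
  expect_equal(pair_state_of(1, 3, r3), "REPULSION")
})

test_that("no binding ever occurs at zero catch rate", {
  p <- tiny_params(4, lambda_ra = 0)
  p$variant <- "RANR"
  elig <- tibble::tibble(i = c(1L, 2L), j = c(3L, 4L))
  reg <- empty_registry()
  set.seed(8)
  for (k in 1:50) reg <- kinetics_step(reg, elig, p, dt = 0.1)
  expect_equal(nrow(reg), 0)
})

test_that("paused pairs do not transition until back in range", {
  p <- tiny_params(4, lambda_ra = 1)
  p$rates <- enzyme_rates(1, 1e9, 1e9)   # instant exit when unpaused
  reg <- tibble::tibble(i = 1L, j = 3L, state = "ATTRACTION",
                        paused = FALSE)
  far <- function(i, j) 2.5   # beyond the capture radius
  near <- function(i, j) 0.5
  set.seed(3)
  r1 <- kinetics_step(reg, empty_registry()[0, c("i", "j")], p, dt = 1,
                      separations = far)
  expect_equal(nrow(r1), 1)       # still bound, paused
  expect_true(r1$paused[1])
  r2 <- kinetics_step(r1, empty_registry()[0, c("i", "j")], p, dt = 1,
                      separations = near)
  expect_equal(r2$state, "NONE")  # resumed and advanced
  r3 <- kinetics_step(r2, empty_registry()[0, c("i", "j")], p, dt = 1,
                      separations = near)
  expect_equal(nrow(r3), 0)       # released
})

test_that("registry exclusivity holds through heavy binding when enabled", {
  set.seed(21)
  p <- tiny_params(40, lambda_ra = 50)
  p$exclusive_binding <- TRUE
  elig <- tibble::tibble(
    i = rep(seq(1L, 19L, by = 2L), times = 3),
    j = rep(seq(1L, 19L, by = 2L), times = 3) +
      rep(c(2L, 4L, 6L), each = 10))
  reg <- empty_registry()
  for (k in 1:30) {
    reg <- kinetics_step(reg, elig, p, dt = 0.05)
    beads <- c(reg$i, reg$j)
    expect_equal(anyDuplicated(beads), 0)
  }
})

test_that("dwell means match the configured rates within three standard errors", {
  set.seed(123)
  dw <- dwell_times(enzyme_rates(10), n_pairs = 400, n_steps = 30000,
                    dt = 5e-4)
  att <- dw$dwell[dw$state == "ATTRACTION"]
  expect_gt(length(att), 1e4)
  se <- stats::sd(att) / sqrt(length(att))
  expect_lt(abs(mean(att) - 0.0599), 3 * se + 1e-4)
  non <- dw$dwell[dw$state == "NONE"]
  se_n <- stats::sd(non) / sqrt(length(non))
  expect_lt(abs(mean(non) - 0.0020), 3 * se_n + 1e-4)
})

test_that("dwell distributions are exponential (KS) in every state", {
  set.seed(99)
  rates <- enzyme_rates(5, lambda_an = 8, lambda_nr = 20)
  dw <- dwell_times(rates, n_pairs = 300, n_steps = 20000, dt = 5e-4)
  for (case in list(c("ATTRACTION", 8), c("NONE", 20),
                    c("REPULSION", 5))) {
    x <- dw$dwell[dw$state == case[1]]
    expect_gt(length(x), 500)
    ks <- suppressWarnings(
      stats::ks.test(x, "pexp", rate = as.numeric(case[2])))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("two-state variants reduce from the three-state scheme in the rate limits", {
  set.seed(31)
  # RANR with instant no-interaction exit ~ RAR attraction dwells
  r_fast_nr <- enzyme_rates(5, lambda_an = 10, lambda_nr = 1e7)
  dw_ranr <- dwell_times(r_fast_nr, 200, 20000, 1e-3, variant = "RANR")
  dw_rar <- dwell_times(enzyme_rates(5, lambda_an = 10, lambda_nr = 500),
                        200, 20000, 1e-3, variant = "RAR")
  a1 <- dw_ranr$dwell[dw_ranr$state == "ATTRACTION"]
  a2 <- dw_rar$dwell[dw_rar$state == "ATTRACTION"]
  ks <- suppressWarnings(stats::ks.test(a1, a2))
  expect_gt(ks$p.value, 0.01)
  # RNR never visits the attraction state
  dw_rnr <- dwell_times(enzyme_rates(5), 100, 5000, 1e-3, variant = "RNR")
  expect_false("ATTRACTION" %in% dw_rnr$state)
  expect_true("NONE" %in% dw_rnr$state)
})

test_that("stationary occupancy of bound states follows the dwell ratio", {
  set.seed(55)
  rates <- enzyme_rates(50, lambda_an = 10, lambda_nr = 30)
  p <- tiny_params(40, lambda_ra = 50)
  p$rates <- rates
  elig_all <- tibble::tibble(i = seq(1L, 39L, by = 2L),
                             j = seq(2L, 40L, by = 2L))
  p$exclude_neighbors <- FALSE
  reg <- empty_registry()
  occ_att <- 0; occ_non <- 0
  for (k in 1:4000) {
    elig <- dplyr::anti_join(elig_all, reg[, c("i", "j")],
                             by = c("i", "j"))
    reg <- kinetics_step(reg, elig, p, dt = 2e-3)
    if (k > 500) {
      occ_att <- occ_att + sum(reg$state == "ATTRACTION")
      occ_non <- occ_non + sum(reg$state == "NONE")
    }
  }
  frac <- occ_att / (occ_att + occ_non)
  want <- (1 / 10) / (1 / 10 + 1 / 30)
  expect_lt(abs(frac - want), 0.05)
})
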