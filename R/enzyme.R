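# Topoisomerase-II catch-and-release state machine, R reference
# implementation.  The registry is a tibble with columns i, j (bead
# indices, i < j), state ("ATTRACTION" or "NONE") and paused (logical,
# recomputed each step from the current separation).
#
# The compiled engine runs the same scheme inline; these functions are the
# module's reference surface and are cross-checked against it in tests.

#' Empty enzyme registry
#' @return A zero-row registry tibble.
#' @export
empty_registry <- function() {
  tibble::tibble(i = integer(), j = integer(), state = character(),
                 paused = logical())
}

#' Find AA pairs eligible for enzyme capture
#'
#' Returns every unordered AA pair within the capture radius that
#' satisfies neighbor exclusion (if enabled) and has neither bead already
#' bound (when binding is exclusive).
#'
#' @param state A [sim_state()] object.
#' @param registry Current registry tibble.
#' @param params A [model_params()] object (capture radius = `cutoff`,
#'   plus the `exclude_neighbors` / `exclusive_binding` flags).
#' @return Tibble with columns `i`, `j` (i < j).
#' @export
find_eligible <- function(state, registry = empty_registry(), params) {
  pos <- state$positions
  isA <- species_code(state$species) == 0L
  idx <- which(isA)
  if (length(idx) < 2) return(tibble::tibble(i = integer(), j = integer()))
  pairs <- neighbor_candidates(pos[idx, , drop = FALSE], params$cutoff,
                               params$geometry)
  if (nrow(pairs) == 0) return(tibble::tibble(i = integer(), j = integer()))
  i <- idx[pairs[, 1]]; j <- idx[pairs[, 2]]
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  keep <- rep(TRUE, length(i))
  if (params$exclude_neighbors) keep <- keep & (j - i > 1L)
  bound <- unique(c(registry$i, registry$j))
  if (params$exclusive_binding) {
    keep <- keep & !(i %in% bound) & !(j %in% bound)
  } else {
    key <- paste(i, j); reg_key <- paste(registry$i, registry$j)
    keep <- keep & !(key %in% reg_key)
  }
  out <- tibble::tibble(i = i[keep], j = j[keep])
  dplyr::arrange(out, .data$i, .data$j)
}

#' Advance the enzyme registry by one kinetic step
#'
#' Each eligible pair binds with probability `1 - exp(-lambda_ra dt)`;
#' each bound pair in the attraction state advances (RANR: to the
#' no-interaction state; RAR: directly unbinds) with probability
#' `1 - exp(-lambda_an dt)`; each no-interaction pair unbinds with
#' probability `1 - exp(-lambda_nr dt)`.  Bound pairs whose current
#' separation exceeds the capture radius are paused and do not transition.
#'
#' @param registry Registry tibble.
#' @param eligible Tibble of candidate pairs from [find_eligible()].
#' @param params A [model_params()] object (variant and rates).
#' @param dt Time step (tau).
#' @param separations Optional named access to current pair distances: a
#'   function `(i, j) -> distance`.  Defaults to "all in range" (no
#'   pausing), which is the pure-kinetics setting used for dwell-time
#'   statistics.
#' @return Updated registry tibble.
#' @export
kinetics_step <- function(registry, eligible, params, dt,
                          separations = NULL) {
  stopifnot(dt > 0)
  r <- params$rates
  variant <- params$variant
  if (!variant %in% c("RANR", "RAR", "RNR")) return(registry)
  p_ra <- 1 - exp(-r$lambda_ra * dt)
  p_an <- 1 - exp(-r$lambda_an * dt)
  p_nr <- 1 - exp(-r$lambda_nr * dt)

  if (nrow(registry) > 0) {
    paused <- if (is.null(separations)) rep(FALSE, nrow(registry)) else {
      mapply(separations, registry$i, registry$j) > params$cutoff
    }
    u <- stats::runif(nrow(registry))
    att <- registry$state == "ATTRACTION" & !paused
    non <- registry$state == "NONE" & !paused
    drop <- rep(FALSE, nrow(registry))
    if (variant == "RAR") {
      drop[att & u < p_an] <- TRUE
    } else {
      registry$state[att & u < p_an] <- "NONE"
      # pairs that advanced this step keep their new state until the next
      non <- non & !(att & u < p_an)
    }
    drop[non & u < p_nr] <- TRUE
    registry$paused <- paused
    registry <- registry[!drop, , drop = FALSE]
  }

  if (r$lambda_ra > 0 && nrow(eligible) > 0) {
    if (params$exclusive_binding) {
      bound <- unique(c(registry$i, registry$j))
      new_rows <- list()
      u <- stats::runif(nrow(eligible))
      for (q in seq_len(nrow(eligible))) {
        i <- eligible$i[q]; j <- eligible$j[q]
        if (i %in% bound || j %in% bound) next
        if (u[q] < p_ra) {
          new_rows[[length(new_rows) + 1L]] <- c(i, j)
          bound <- c(bound, i, j)
        }
      }
      if (length(new_rows) > 0) {
        nm <- do.call(rbind, new_rows)
        registry <- dplyr::bind_rows(registry, tibble::tibble(
          i = nm[, 1], j = nm[, 2],
          state = if (variant == "RNR") "NONE" else "ATTRACTION",
          paused = FALSE))
      }
    } else {
      hit <- stats::runif(nrow(eligible)) < p_ra
      registry <- dplyr::bind_rows(registry, tibble::tibble(
        i = eligible$i[hit], j = eligible$j[hit],
        state = if (variant == "RNR") "NONE" else "ATTRACTION",
        paused = FALSE))
    }
  }
  registry
}

#' Interaction state of a bead pair
#'
#' @param i,j Bead indices.
#' @param registry Registry tibble.
#' @param species Species vector (character "A"/"B" or 0/1 codes); pairs
#'   involving a B bead are always in repulsion.
#' @return `"ATTRACTION"`, `"NONE"`, or `"REPULSION"`.
#' @export
pair_state_of <- function(i, j, registry, species = NULL) {
  stopifnot(i != j)
  if (!is.null(species)) {
    sc <- species_code(species)
    if (sc[i] != 0L || sc[j] != 0L) return("REPULSION")
  }
  lo <- min(i, j); hi <- max(i, j)
  hitrow <- which(registry$i == lo & registry$j == hi)
  if (length(hitrow) == 0) return("REPULSION")
  registry$state[hitrow[1]]
}

#' Dwell-time statistics of the kinetic scheme
#'
#' Runs the pure kinetics (all pairs permanently in range) for `n_pairs`
#' independent pairs over `n_steps` steps of size `dt` and records
#' completed dwell intervals in each state.
#'
#' @param rates An [enzyme_rates()] object.
#' @param n_pairs Number of independent pairs simulated.
#' @param n_steps Number of kinetic steps.
#' @param dt Step (tau).
#' @param variant Kinetic scheme.
#' @return Tibble with columns `state` ("REPULSION", "ATTRACTION",
#'   "NONE") and `dwell` (tau), one row per completed interval.  Dwell
#'   times are midpoint-corrected for the step discretization (the
#'   transition occurs somewhere within the firing step, so half a step
#'   is subtracted; the per-step firing probability `1 - exp(-lambda
#'   dt)` then makes the recorded dwell agree with the exponential law
#'   exactly at the grid points).
#' @export
dwell_times <- function(rates, n_pairs = 200, n_steps = 20000, dt = 1e-3,
                        variant = "RANR") {
  stopifnot(variant %in% c("RANR", "RAR", "RNR"))
  p_ra <- 1 - exp(-rates$lambda_ra * dt)
  p_an <- 1 - exp(-rates$lambda_an * dt)
  p_nr <- 1 - exp(-rates$lambda_nr * dt)
  # per-pair state: 0 repulsion, 1 attraction, 2 none
  st <- integer(n_pairs)
  since <- numeric(n_pairs)
  acc_state <- vector("list", n_steps); acc_dwell <- vector("list", n_steps)
  probs <- switch(variant,
    RANR = c(p_ra, p_an, p_nr),
    RAR = c(p_ra, p_an, NA),
    RNR = c(p_ra, NA, p_nr))
  nxt <- switch(variant,
    RANR = c(1L, 2L, 0L),
    RAR = c(1L, 0L, NA),
    RNR = c(2L, NA, 0L))
  for (step in seq_len(n_steps)) {
    u <- stats::runif(n_pairs)
    fire <- u < probs[st + 1L]
    fire[is.na(fire)] <- FALSE
    if (any(fire)) {
      t_now <- step * dt
      acc_state[[step]] <- c("REPULSION", "ATTRACTION", "NONE")[st[fire] + 1L]
      acc_dwell[[step]] <- t_now - since[fire] - dt / 2
      st[fire] <- nxt[st[fire] + 1L]
      since[fire] <- t_now
    }
  }
  tibble::tibble(state = unlist(acc_state), dwell = unlist(acc_dwell))
}
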