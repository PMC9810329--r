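# Extended-XYZ trajectory I/O.  One frame per snapshot: an atom count
# line, a comment line with key=value metadata (Properties, Time,
# geometry), then one `species x y z` row per bead.

#' Write a trajectory (or single state) to extended XYZ
#'
#' @param traj A `bd_trajectory` or [sim_state()].
#' @param path Output file.
#' @param digits Coordinate precision.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, digits = 10) {
  states <- as_state_list(traj)
  geom <- if (inherits(traj, "bd_trajectory")) traj$params$geometry else NULL
  con <- file(path, "w")
  on.exit(close(con))
  for (st in states) {
    n <- nrow(st$positions)
    meta <- sprintf('Properties=species:S:1:pos:R:3 Time=%.10g', st$time)
    if (!is.null(geom)) {
      meta <- paste(meta, if (geom$type == "sphere") {
        sprintf("Geometry=sphere CavityDiameter=%.10g", geom$d_ct)
      } else {
        sprintf("Geometry=slab Lx=%.10g Ly=%.10g Lz=%.10g",
                geom$Lx, geom$Ly, geom$Lz)
      })
    }
    writeLines(as.character(n), con)
    writeLines(meta, con)
    writeLines(sprintf(paste0("%s %.", digits, "g %.", digits, "g %.",
                              digits, "g"),
                       st$species, st$positions[, 1], st$positions[, 2],
                       st$positions[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' @param path Input file with A/B species labels.
#' @return A list of [sim_state()] objects (length 1 for a single
#'   snapshot); frame times are taken from the `Time=` comment key when
#'   present.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  states <- list()
  k <- 1L
  frame_line <- 0L
  while (k <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[k])) {
      stop(sprintf("malformed extended XYZ at line %d: expected atom count",
                   k), call. = FALSE)
    }
    n <- as.integer(lines[k])
    comment <- lines[k + 1L]
    time <- 0
    tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]]
    if (length(tm) == 2) time <- as.numeric(tm[2])
    rows <- lines[(k + 2L):(k + 1L + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    bad <- which(lengths(parts) < 4)
    if (length(bad) > 0) {
      stop(sprintf("malformed extended XYZ at line %d", k + 1L + bad[1]),
           call. = FALSE)
    }
    species <- vapply(parts, `[`, character(1), 1)
    if (!all(species %in% c("A", "B"))) {
      stop("species labels other than A/B in trajectory", call. = FALSE)
    }
    pos <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    if (anyNA(pos)) {
      stop(sprintf("non-numeric coordinates in frame starting at line %d", k),
           call. = FALSE)
    }
    states[[length(states) + 1L]] <- sim_state(pos, species, time = time)
    k <- k + 2L + n
  }
  states
}
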