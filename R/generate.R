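#' Named goal-pattern templates
#'
#' Goal layouts used in the micropatterning and swarm-exchange tasks. All
#' patterns are centred in the field of view and scaled to a 480 um
#' workspace; coordinates are in um. Patterns:
#' \describe{
#'   \item{trapezoid}{5 points on a trapezoid outline.}
#'   \item{arrow}{7 points forming an arrow pointing to the lower right.}
#'   \item{radial-lobule}{n points on 6 spokes of a hexagon-like radial
#'     layout mimicking a liver lobule (default n = 18, 3 per spoke).}
#'   \item{swap-swarms}{two 4-point blocks in opposite corners, each
#'     reserved for the particle type that starts in the *other* corner.}
#' }
#'
#' @param pattern pattern name, or an n x 2 matrix of explicit coordinates.
#' @param n number of goals (patterns with a fixed count ignore it).
#' @param ws an `oet_workspace` (patterns scale with its extent).
#' @return Data frame with columns `x`, `y`, `required_type` (NA unless the
#'   pattern is typed).
#' @export
goal_pattern <- function(pattern, n = NULL, ws = workspace()) {
  ext <- workspace_extent(ws)
  sc <- min(ext) / 480           # templates are drawn on a 480 um canvas
  shift <- ws$origin
  pt <- function(m, type = NA_character_) {
    data.frame(x = m[, 1] * sc + shift[1], y = m[, 2] * sc + shift[2],
               required_type = type, stringsAsFactors = FALSE)
  }
  if (is.matrix(pattern)) {
    return(data.frame(x = pattern[, 1], y = pattern[, 2],
                      required_type = NA_character_))
  }
  switch(pattern,
    "trapezoid" = pt(rbind(
      c(150, 310), c(240, 310), c(330, 310), c(195, 220), c(285, 220))),
    "arrow" = pt(rbind(
      c(340, 340), c(270, 270), c(200, 200), c(130, 130), c(60, 60),
      c(220, 340), c(340, 220))),
    "radial-lobule" = {
      if (is.null(n)) n <- 18L
      spokes <- 6L
      rings <- ceiling(n / spokes)
      radii <- c(80, 160, 235, seq(280, by = 45,
                                   length.out = max(0, rings - 3)))[seq_len(rings)]
      ang <- (seq_len(spokes) - 1) * pi / 3
      ctr <- c(240, 240)
      pts <- do.call(rbind, lapply(radii, function(r) {
        cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang))
      }))
      pt(pts[seq_len(n), , drop = FALSE])
    },
    "swap-swarms" = {
      # goals for the swarm starting in the lower-left go to the upper
      # right and vice versa; blocks are kept a clear corridor away from
      # the workspace walls so parked arrivals never seal a passage
      ur <- rbind(c(280, 120), c(360, 120), c(280, 200), c(360, 200))
      ll <- rbind(c(120, 280), c(200, 280), c(120, 360), c(200, 360))
      rbind(pt(ur), pt(ll))
    },
    stop(sprintf("unknown goal pattern '%s'", pattern)))
}

place_points <- function(n, ws, min_sep, avoid = NULL, avoid_sep = min_sep,
                         inset = 20, max_tries = 4000) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  ext <- workspace_extent(ws)
  lo <- ws$origin + inset
  hi <- ws$origin + ext - inset
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf(
        "infeasible packing: placed %d of %d points at separation %g um after %d tries",
        placed, n, min_sep, max_tries))
    }
    cand <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
    ok <- TRUE
    if (placed > 0L) {
      d2 <- (pts[seq_len(placed), 1] - cand[1])^2 +
            (pts[seq_len(placed), 2] - cand[2])^2
      ok <- all(d2 >= min_sep^2)
    }
    if (ok && !is.null(avoid) && nrow(avoid)) {
      d2 <- (avoid[, 1] - cand[1])^2 + (avoid[, 2] - cand[2])^2
      ok <- all(d2 >= avoid_sep^2)
    }
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  pts
}

#' Generate a seeded synthetic scenario
#'
#' Deterministic for a fixed seed: particle starts are drawn by rejection
#' sampling at the configured minimum separation, goals come from a named
#' pattern template or explicit coordinates, and everything downstream draws
#' from streams derived from the one root seed.
#'
#' @param config a list with elements:
#' \describe{
#'   \item{targets}{named integer vector: number of target particles per
#'     type name (types resolved via [preset_type()] unless supplied in
#'     `types`).}
#'   \item{n_obstacles}{number of free obstacles (default 0).}
#'   \item{obstacle_type}{type name for obstacles (default `"bead10"`).}
#'   \item{pattern}{goal pattern name or explicit n x 2 coordinate matrix
#'     (see [goal_pattern()]); `NULL` for no goals.}
#'   \item{goal_types}{optional character vector of `required_type` per
#'     goal, overriding the pattern's own typing.}
#'   \item{min_separation}{minimum pairwise start separation, um
#'     (default 80).}
#'   \item{start_positions}{optional explicit n x 2 matrix of target starts
#'     (bypasses random placement, still separation-checked against
#'     obstacles).}
#'   \item{workspace, medium, types, safety_margin, sim}{optional overrides.}
#' }
#' @param seed root integer seed.
#' @return An `oet_scenario`.
#' @export
generate_scenario <- function(config, seed) {
  ws <- config$workspace %||% workspace()
  med <- config$medium %||% medium()
  min_sep <- config$min_separation %||% 80
  tgt_counts <- config$targets %||% c(bead10 = 1L)
  n_obs <- config$n_obstacles %||% 0L
  obs_type <- config$obstacle_type %||% "bead10"
  type_names <- unique(c(names(tgt_counts), if (n_obs > 0) obs_type))
  types <- config$types %||% setNames(lapply(type_names, preset_type), type_names)
  for (nm in type_names) {
    if (is.null(types[[nm]])) types[[nm]] <- preset_type(nm)
  }

  goals <- NULL
  if (!is.null(config$pattern)) {
    goals <- goal_pattern(config$pattern, n = sum(tgt_counts), ws = ws)
    if (!is.null(config$goal_types)) {
      stopifnot(length(config$goal_types) == nrow(goals))
      goals$required_type <- config$goal_types
    }
    goals$id <- seq_len(nrow(goals))
    goals <- goals[, c("id", "x", "y", "required_type")]
  }

  with_local_seed(derive_seed(seed, "scenario"), {
    n_tgt <- sum(tgt_counts)
    if (!is.null(config$start_positions)) {
      starts <- as.matrix(config$start_positions)
      stopifnot(nrow(starts) == n_tgt)
    } else {
      starts <- place_points(n_tgt, ws, min_sep)
    }
    # obstacles keep clear of target starts and of goal positions, so the
    # task is not born (or doomed to end) in a collision state
    avoid <- starts
    if (!is.null(goals)) avoid <- rbind(avoid, as.matrix(goals[, c("x", "y")]))
    obst <- place_points(n_obs, ws, min_sep, avoid = avoid,
                         avoid_sep = config$obstacle_clearance %||% min_sep,
                         max_tries = 20000)

    ptypes <- rep(names(tgt_counts), times = tgt_counts)
    particles <- data.frame(
      id = seq_len(n_tgt + n_obs),
      type = c(ptypes, rep(obs_type, n_obs)),
      x = c(starts[, 1], obst[, 1]),
      y = c(starts[, 2], obst[, 2]),
      status = c(rep("trapped", n_tgt), rep("free-obstacle", n_obs)),
      goal_id = NA_integer_,
      stringsAsFactors = FALSE)

    scenario(ws, med, particles,
             goals %||% data.frame(id = integer(0), x = numeric(0),
                                   y = numeric(0),
                                   required_type = character(0)),
             types, seed = seed,
             safety_margin = config$safety_margin %||% 5,
             sim = config$sim %||% sim_config(seed = derive_seed(seed, "sim")))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
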