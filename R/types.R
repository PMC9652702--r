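#' Particle type and its virtual-electrode geometry
#'
#' Each type of microparticle is driven by an annular light pattern (the
#' "virtual electrode") whose inner radius and annulus width set the trap
#' geometry. The defaults (inner radius 20 um, width 15 um) are the sizes at
#' which the horizontal trapping force is maximised for ~10-20 um dielectric
#' particles; a smaller inner circle lets particles escape too easily and a
#' wider annulus flattens the local field gradient.
#'
#' @param name type label (e.g. `"bead10"`, `"cell"`).
#' @param radius particle radius in um (> 0).
#' @param electrode_inner_radius inner radius of the annular light pattern,
#'   um (>= particle radius).
#' @param electrode_width annulus width, um (> 0); the outer radius is
#'   `electrode_inner_radius + electrode_width`.
#' @param cm_factor_real real part of the Clausius-Mossotti factor; sets the
#'   sign and strength of the dielectrophoretic response.
#' @param preset_speed transport speed commanded to the electrode, um/s.
#' @return An object of class `oet_particle_type`.
#' @export
particle_type <- function(name, radius,
                          electrode_inner_radius = 20,
                          electrode_width = 15,
                          cm_factor_real = 0.5,
                          preset_speed = 30) {
  stopifnot(radius > 0, electrode_inner_radius >= radius, electrode_width > 0,
            preset_speed > 0)
  structure(
    list(name = as.character(name), radius = as.numeric(radius),
         electrode_inner_radius = as.numeric(electrode_inner_radius),
         electrode_width = as.numeric(electrode_width),
         cm_factor_real = as.numeric(cm_factor_real),
         preset_speed = as.numeric(preset_speed)),
    class = "oet_particle_type")
}

#' Outer radius of a type's virtual electrode
#' @param type an `oet_particle_type`.
#' @return `electrode_inner_radius + electrode_width`, um.
#' @export
electrode_outer_radius <- function(type) {
  type$electrode_inner_radius + type$electrode_width
}

#' Built-in particle types
#'
#' Three presets mirroring the experimental targets: 10 um and 20 um
#' polystyrene beads and ~15 um fibroblast cells. The 10 um bead gets a
#' proportionally smaller electrode (outer diameter 50 um vs 70 um), which
#' is what the first-level priority rule keys on.
#'
#' @param name one of `"bead10"`, `"bead20"`, `"cell"`.
#' @return An `oet_particle_type`.
#' @export
preset_type <- function(name = c("bead10", "bead20", "cell")) {
  switch(match.arg(name),
    bead10 = particle_type("bead10", radius = 5,
                           electrode_inner_radius = 10, electrode_width = 15),
    bead20 = particle_type("bead20", radius = 10,
                           electrode_inner_radius = 20, electrode_width = 15),
    cell   = particle_type("cell", radius = 7.5,
                           electrode_inner_radius = 20, electrode_width = 15))
}

#' Suspension medium properties
#'
#' @param permittivity medium permittivity in F/m; default is the
#'   78 * epsilon_0 of an aqueous low-conductivity suspension.
#' @param viscosity dynamic viscosity in Pa s (default 1 mPa s, water).
#' @param diffusion_coefficient translational diffusion coefficient of the
#'   suspended particles, um^2/s; 0 gives deterministic dynamics for tests.
#' @return An object of class `oet_medium`.
#' @export
medium <- function(permittivity = 78 * 8.8541878128e-12,
                   viscosity = 1e-3,
                   diffusion_coefficient = 0.2) {
  stopifnot(permittivity > 0, viscosity > 0, diffusion_coefficient >= 0)
  structure(
    list(permittivity = permittivity, viscosity = viscosity,
         diffusion_coefficient = diffusion_coefficient),
    class = "oet_medium")
}

#' Assemble a scenario
#'
#' A scenario is the full world description for one manipulation task:
#' workspace geometry, medium, particles (targets and free obstacles), goal
#' positions, the root seed, and the safety margin used for collision
#' thresholds. Usually produced by [generate_scenario()] or
#' [scenario_preset()] rather than by hand.
#'
#' @param ws an `oet_workspace`.
#' @param med an `oet_medium`.
#' @param particles data frame with columns `id`, `type`, `x`, `y`,
#'   `status` (one of trapped/escaped/free-obstacle/arrived), `goal_id`.
#' @param goals data frame with columns `id`, `x`, `y`, `required_type`
#'   (NA = any type).
#' @param types named list of `oet_particle_type` covering every type used.
#' @param seed root integer seed for all stochastic components.
#' @param safety_margin extra clearance added to collision thresholds, um.
#' @param sim an `oet_sim_config` ([sim_config()]).
#' @return An object of class `oet_scenario`.
#' @export
scenario <- function(ws, med, particles, goals, types, seed,
                     safety_margin = 5, sim = sim_config()) {
  stopifnot(inherits(ws, "oet_workspace"), inherits(med, "oet_medium"))
  particles <- as.data.frame(particles)
  goals <- as.data.frame(goals)
  needed <- c("id", "type", "x", "y", "status", "goal_id")
  stopifnot(all(needed %in% names(particles)))
  if (anyDuplicated(particles$id)) stop("particle ids must be unique")
  if (nrow(goals)) {
    stopifnot(all(c("id", "x", "y") %in% names(goals)))
    if (is.null(goals$required_type)) goals$required_type <- NA_character_
    if (anyDuplicated(goals$id)) stop("goal ids must be unique")
  }
  if (!all(particles$type %in% names(types))) {
    stop("every particle type must appear in `types`")
  }
  ext <- workspace_extent(ws)
  inb <- function(x, y) {
    x > ws$origin[1] & x < ws$origin[1] + ext[1] &
      y > ws$origin[2] & y < ws$origin[2] + ext[2]
  }
  if (!all(inb(particles$x, particles$y))) {
    stop("particle positions must lie strictly inside the workspace")
  }
  if (nrow(goals) && !all(inb(goals$x, goals$y))) {
    stop("goal positions must lie strictly inside the workspace")
  }
  # typed goals cannot outnumber the targets able to serve them
  tgt <- particles[particles$status != "free-obstacle", ]
  if (nrow(goals)) {
    for (tp in unique(stats::na.omit(goals$required_type))) {
      if (sum(goals$required_type %in% tp) > sum(tgt$type == tp)) {
        stop(sprintf("more goals require type '%s' than targets of that type", tp))
      }
    }
    if (nrow(goals) > nrow(tgt)) stop("more goals than target particles")
  }
  structure(
    list(workspace = ws, medium = med, particles = particles, goals = goals,
         types = types, seed = as.integer(seed),
         safety_margin = as.numeric(safety_margin), sim = sim),
    class = "oet_scenario")
}

#' @export
print.oet_scenario <- function(x, ...) {
  tgt <- sum(x$particles$status != "free-obstacle")
  obs <- sum(x$particles$status == "free-obstacle")
  cat(sprintf(
    "<oet_scenario> %d targets, %d free obstacles, %d goals | %d x %d grid, %g um/cell | seed %d\n",
    tgt, obs, nrow(x$goals), x$workspace$nx, x$workspace$ny,
    x$workspace$cell_size, x$seed))
  invisible(x)
}

target_indices <- function(sc) which(sc$particles$status != "free-obstacle")
obstacle_indices <- function(sc) which(sc$particles$status == "free-obstacle")

type_of <- function(sc, i) sc$types[[sc$particles$type[i]]]
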