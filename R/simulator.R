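#' Simulator configuration
#'
#' Parameters of the stochastic stand-in for the physical platform:
#' integration timestep, Brownian diffusion, the trap-escape model, obstacle
#' drift and the peak field-gradient magnitude of the annular electrode.
#'
#' The trap is modelled as a first-order pull toward the electrode centre
#' whose maximum speed comes from the dipole-approximation
#' dielectrophoretic force balanced against Stokes drag. A particle escapes
#' (with probability `escape_prob` per offending step) when its offset from
#' the electrode centre exceeds `escape_threshold_frac` times the inner
#' radius, or when the electrode is dragged faster than the trap can follow.
#'
#' @param timestep integration step, s.
#' @param escape_threshold_frac fraction of the electrode inner radius
#'   beyond which the particle is at risk of escaping.
#' @param escape_prob escape probability per offending step.
#' @param obstacle_drift constant drift speed of free obstacles, um/s
#'   (direction drawn once per obstacle from the scenario seed).
#' @param grad_E2_peak peak magnitude of grad |E|^2 at the electrode inner
#'   edge, V^2/m^3. The default (1.7e13) gives a ~50 um/s speed limit for a
#'   10 um bead in water, comfortably above the 30 um/s preset transport
#'   speed.
#' @param seed stream seed for the simulator's own noise.
#' @return An object of class `oet_sim_config`.
#' @export
sim_config <- function(timestep = 0.05,
                       escape_threshold_frac = 0.8,
                       escape_prob = 0.5,
                       obstacle_drift = 0,
                       grad_E2_peak = 1.7e13,
                       seed = 1L) {
  stopifnot(timestep > 0, escape_threshold_frac > 0,
            escape_prob >= 0, escape_prob <= 1, obstacle_drift >= 0)
  structure(
    list(timestep = timestep,
         escape_threshold_frac = escape_threshold_frac,
         escape_prob = escape_prob,
         obstacle_drift = obstacle_drift,
         grad_E2_peak = grad_E2_peak,
         seed = as.integer(seed)),
    class = "oet_sim_config")
}

#' Dipole-approximation dielectrophoresis force
#'
#' Time-averaged DEP force on a spherical particle in a non-uniform field:
#' `F = 2 pi r^3 eps_m Re(K) grad|E|^2`. The sign follows the real part of
#' the Clausius-Mossotti factor: negative values push the particle toward
#' field minima.
#'
#' @param radius particle radius, um.
#' @param permittivity medium permittivity, F/m.
#' @param cm_factor_real real part of the Clausius-Mossotti factor.
#' @param grad_E2 gradient of the squared field magnitude, V^2/m^3
#'   (scalar or vector; the force inherits its shape).
#' @return Force in newtons, same shape as `grad_E2`.
#' @export
dep_force_dipole <- function(radius, permittivity, cm_factor_real, grad_E2) {
  stopifnot(radius > 0, permittivity > 0)
  2 * pi * (radius * 1e-6)^3 * permittivity * cm_factor_real * grad_E2
}

#' Stokes-drag speed limit of a trap
#'
#' The fastest the electrode can drag a particle: trap force balanced
#' against low-Reynolds-number drag, `v = F / (6 pi mu r)`.
#'
#' @param force trap force magnitude, N.
#' @param radius particle radius, um.
#' @param viscosity dynamic viscosity, Pa s.
#' @return Speed in um/s.
#' @export
max_trap_speed <- function(force, radius, viscosity) {
  stopifnot(radius > 0, viscosity > 0)
  force / (6 * pi * viscosity * radius * 1e-6) * 1e6
}

#' Steady-state trailing distance of a dragged particle
#'
#' Under the first-order trap model a particle dragged at the preset speed
#' trails its electrode centre by `preset_speed * tau`, where `tau` is the
#' trap relaxation time. The collision guard adds this lag for both members
#' of a pair on top of the hard threshold.
#'
#' @param type an `oet_particle_type`.
#' @param med an `oet_medium`.
#' @param cfg an `oet_sim_config`.
#' @return Lag distance in um.
#' @export
trap_lag <- function(type, med, cfg) {
  vmax <- type_max_speed(type, med, cfg)
  tau <- cfg$escape_threshold_frac * type$electrode_inner_radius / vmax
  type$preset_speed * tau
}

type_max_speed <- function(type, med, cfg) {
  f <- abs(dep_force_dipole(type$radius, med$permittivity,
                            type$cm_factor_real, cfg$grad_E2_peak))
  max_trap_speed(f, type$radius, med$viscosity)
}

#' Brownian displacement step
#'
#' Per-axis displacement over one timestep, drawn from a zero-mean Gaussian
#' with variance `2 * D * dt` (free diffusion).
#'
#' @param diffusion diffusion coefficient D, um^2/s.
#' @param timestep dt, s.
#' @param n number of particles (rows).
#' @return n x 2 matrix of displacements in um. Exactly zero when `D = 0`.
#' @export
brownian_step <- function(diffusion, timestep, n = 1L) {
  stopifnot(diffusion >= 0, timestep > 0)
  if (diffusion == 0) return(matrix(0, n, 2))
  matrix(rnorm(2 * n, sd = sqrt(2 * diffusion * timestep)), n, 2)
}

#' Build an electrode command
#'
#' @param particle_id id of the (trapped) particle the electrode carries.
#' @param center electrode centre, um (length-2).
#' @param type the particle's `oet_particle_type` (for trap geometry).
#' @param speed commanded translation speed, um/s; capped at the type's
#'   preset speed.
#' @return A one-row data frame in the command schema used by [sim_step()].
#' @export
electrode_command <- function(particle_id, center, type, speed = type$preset_speed) {
  data.frame(particle_id = particle_id, cx = center[1], cy = center[2],
             inner_radius = type$electrode_inner_radius,
             width = type$electrode_width,
             speed = min(speed, type$preset_speed))
}

#' Advance the simulated world by one timestep
#'
#' Trapped particles relax toward their electrode centres (first-order lag
#' with the time constant implied by the trap's speed limit) plus Brownian
#' noise; particles that fall too far behind the electrode, or whose
#' electrode moved faster than the trap limit, escape with the configured
#' probability. Free obstacles take Brownian steps plus optional constant
#' drift. Positions are clipped to the workspace (with a wall event).
#'
#' @param world list with elements `particles` (scenario particle frame),
#'   `types`, `workspace`, `medium`, `time`, and internal fields managed by
#'   the function (`prev_centers`, `drift_dirs`).
#' @param commands data frame of electrode commands ([electrode_command()]);
#'   every referenced particle must be trapped.
#' @param cfg an `oet_sim_config`.
#' @return The updated world, with `events` (data frame of escape/wall
#'   events this step) and advanced `time`. RNG: uses the current stream;
#'   wrap in a seeded context for reproducibility.
#' @export
sim_step <- function(world, commands, cfg) {
  p <- world$particles
  dt <- cfg$timestep
  events <- list()
  if (nrow(commands)) {
    st <- p$status[match(commands$particle_id, p$id)]
    if (any(st != "trapped" & st != "arrived")) {
      stop("electrode command issued for a non-trapped particle")
    }
  }

  D <- world$medium$diffusion_coefficient
  noise <- brownian_step(D, dt, nrow(p))

  # electrode translation speed (for the escape rule) vs previous centres
  prev <- world$prev_centers
  cmd_id <- commands$particle_id
  cmd_cx <- commands$cx; cmd_cy <- commands$cy
  vmax_tab <- world$vmax
  if (is.null(vmax_tab)) {
    vmax_tab <- vapply(world$types, type_max_speed, numeric(1),
                       med = world$medium, cfg = cfg)
  }
  for (k in seq_len(nrow(commands))) {
    i <- match(cmd_id[k], p$id)
    ty <- world$types[[p$type[i]]]
    vmax <- vmax_tab[[p$type[i]]]
    ctr <- c(cmd_cx[k], cmd_cy[k])
    moved <- if (!is.null(prev[[as.character(cmd_id[k])]])) {
      sqrt(sum((ctr - prev[[as.character(cmd_id[k])]])^2)) / dt
    } else 0
    tau <- cfg$escape_threshold_frac * ty$electrode_inner_radius / vmax
    alpha <- 1 - exp(-dt / tau)
    pos <- c(p$x[i], p$y[i])
    newpos <- pos + alpha * (ctr - pos) + noise[i, ]
    off <- sqrt(sum((newpos - ctr)^2))
    escaped <- FALSE
    if (off > cfg$escape_threshold_frac * ty$electrode_inner_radius ||
        moved > vmax) {
      if (runif(1) < cfg$escape_prob) {
        escaped <- TRUE
        p$status[i] <- "escaped"
        events[[length(events) + 1]] <- data.frame(
          time_s = world$time + dt, event = "escape", particle_id = p$id[i],
          detail = sprintf("offset=%.2fum electrode_speed=%.1fum/s", off, moved))
      }
    }
    if (!escaped) {
      p$x[i] <- newpos[1]; p$y[i] <- newpos[2]
    } else {
      # an escaped particle is no longer pulled; it keeps its lagged position
      p$x[i] <- newpos[1]; p$y[i] <- newpos[2]
    }
    prev[[as.character(cmd_id[k])]] <- ctr
  }

  # escaped targets and free obstacles diffuse (and obstacles may drift)
  loose <- which(p$status == "escaped" | p$status == "free-obstacle")
  loose <- setdiff(loose, match(commands$particle_id, p$id))
  if (length(loose)) {
    p$x[loose] <- p$x[loose] + noise[loose, 1]
    p$y[loose] <- p$y[loose] + noise[loose, 2]
    if (cfg$obstacle_drift > 0) {
      obs <- loose[p$status[loose] == "free-obstacle"]
      for (i in obs) {
        dd <- world$drift_dirs[[as.character(p$id[i])]]
        if (is.null(dd)) {
          th <- runif(1, 0, 2 * pi)
          dd <- c(cos(th), sin(th))
          world$drift_dirs[[as.character(p$id[i])]] <- dd
        }
        p$x[i] <- p$x[i] + cfg$obstacle_drift * dt * dd[1]
        p$y[i] <- p$y[i] + cfg$obstacle_drift * dt * dd[2]
      }
    }
  }

  # clip to workspace
  ws <- world$workspace
  ext <- workspace_extent(ws)
  eps <- 1e-6
  lo <- ws$origin + eps; hi <- ws$origin + ext - eps
  hit <- p$x < lo[1] | p$x > hi[1] | p$y < lo[2] | p$y > hi[2]
  if (any(hit)) {
    p$x <- pmin(pmax(p$x, lo[1]), hi[1])
    p$y <- pmin(pmax(p$y, lo[2]), hi[2])
    events[[length(events) + 1]] <- data.frame(
      time_s = world$time + dt, event = "wall",
      particle_id = p$id[hit], detail = "clipped to workspace boundary")
  }

  world$particles <- p
  world$prev_centers <- prev
  world$time <- world$time + dt
  world$events <- if (length(events)) do.call(rbind, events) else
    data.frame(time_s = numeric(0), event = character(0),
               particle_id = integer(0), detail = character(0))
  world
}

#' Initialise simulator world state from a scenario
#' @param sc an `oet_scenario`.
#' @return A world list consumable by [sim_step()].
#' @export
sim_world <- function(sc) {
  vmax <- vapply(sc$types, type_max_speed, numeric(1), med = sc$medium,
                 cfg = sc$sim)
  list(particles = sc$particles, types = sc$types, workspace = sc$workspace,
       medium = sc$medium, time = 0, prev_centers = list(),
       drift_dirs = list(), vmax = vmax)
}
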