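#' Two-level priority order
#'
#' Every target particle carries two priorities, recomputed before every
#' motion decision: the first level is the outer diameter of its virtual
#' electrode (larger first — big electrodes cost more to detour), and among
#' equal first levels the second level is the current distance to the
#' assigned goal, nearer first. Remaining ties go to the lower particle id.
#'
#' @param sc an `oet_scenario` (current particle positions).
#' @param matching an `oet_matching`; every target must be matched.
#' @return Data frame (one row per target, highest priority first) with
#'   columns `id`, `first_level` (electrode outer diameter, um),
#'   `second_level` (distance to goal, cells).
#' @export
assign_priorities <- function(sc, matching) {
  ti <- target_indices(sc)
  p <- sc$particles
  ids <- p$id[ti]
  gids <- matching$pairs[as.character(ids)]
  if (any(is.na(gids))) stop("every target particle must be matched to a goal")
  grow <- match(gids, sc$goals$id)
  first <- vapply(ti, function(i) 2 * electrode_outer_radius(type_of(sc, i)),
                  numeric(1))
  second <- vapply(seq_along(ti), function(k) {
    i <- ti[k]
    as.numeric(manhattan_distance(c(p$x[i], p$y[i]),
                                  c(sc$goals$x[grow[k]], sc$goals$y[grow[k]]),
                                  sc$workspace))
  }, numeric(1))
  ord <- order(-first, second, ids)
  data.frame(id = ids[ord], first_level = first[ord],
             second_level = second[ord])
}

# mark cells within `radius_um` of each source cell centre as (weighted)
# obstacle belief; weights taper with distance so the planner prefers the
# outside of a blocked zone. Combined across sources by max.
dilate_obstacle_field <- function(field, ws, src_states, src_weights, radius_um) {
  rc <- ceiling(radius_um / ws$cell_size)
  offs <- expand.grid(dc = -rc:rc, dr = -rc:rc)
  d <- sqrt(offs$dc^2 + offs$dr^2) * ws$cell_size
  keep <- d <= radius_um
  offs <- offs[keep, ]; d <- d[keep]
  taper <- pmax(0.2, 1 - 0.8 * d / radius_um)
  cr <- state_colrow(src_states, ws)
  for (k in seq_along(src_states)) {
    col <- cr[k, 1] + offs$dc; row <- cr[k, 2] + offs$dr
    inb <- col >= 0 & col < ws$nx & row >= 0 & row < ws$ny
    idx <- row[inb] * ws$nx + col[inb] + 1L
    w <- src_weights[k] * taper[inb]
    field[idx] <- pmax(field[idx], w)
  }
  field
}

#' One period of prioritised motion decisions
#'
#' Decisions are made strictly in priority order. For each particle the
#' planner clamps its matched goal cell at 100, injects every free (and
#' escaped) particle and every higher-priority particle's predicted
#' next-state set — its belief pushed through the transition model under
#' its already-chosen action — as weighted obstacle belief (dilated to the
#' pairwise collision radius), runs value iteration, and picks the QMDP
#' action under the particle's own belief. Intended (modal) next cells are
#' kept pairwise distinct: a particle whose best action lands on a cell
#' already taken falls back to its best non-conflicting action, or to
#' "stay" with a replan flag if none exists.
#'
#' @param sc an `oet_scenario` whose particle positions are the current
#'   (estimated) ones.
#' @param matching an `oet_matching`.
#' @param priority data frame from [assign_priorities()].
#' @param ctx planner context from [planner_context()].
#' @return Data frame (one row per target, priority order): `id`, `action`,
#'   `action_name`, `intended_state`, `replan`.
#' @export
plan_step <- function(sc, matching, priority, ctx) {
  ws <- sc$workspace
  p <- sc$particles
  n <- n_states(ws)
  goals <- sc$goals

  # static sources: free obstacles and escaped targets at their current cells
  loose <- which(p$status %in% c("free-obstacle", "escaped", "lost"))
  loose_cells <- if (length(loose)) {
    grid_state_of(cbind(p$x[loose], p$y[loose]), ws)
  } else integer(0)

  taken <- integer(0)
  pred <- list()   # id -> list(states, weights, type)
  out <- list()
  for (k in seq_len(nrow(priority))) {
    id <- priority$id[k]
    i <- match(id, p$id)
    ty <- type_of(sc, i)
    b <- ctx$beliefs[[as.character(id)]]
    if (is.null(b)) b <- belief(ws, at = grid_state_of(c(p$x[i], p$y[i]), ws))
    s_mode <- which.max(b)

    if (p$status[i] == "arrived") {
      act <- 9L
      intended <- s_mode
      replan <- FALSE
    } else {
      lag_i <- trap_lag(ty, sc$medium, sc$sim)
      goal_row <- match(matching$pairs[as.character(id)], goals$id)
      gpos <- c(goals$x[goal_row], goals$y[goal_row])
      gstate <- grid_state_of(gpos, ws)
      ctr <- state_center(seq_len(n), ws)
      near_goal <- (ctr[, 1] - gpos[1])^2 + (ctr[, 2] - gpos[2])^2 <=
        (1.5 * ws$cell_size)^2
      # blocked radii normally exceed the collision threshold by the trap
      # lags plus one cell of grid quantization, so avoidance engages
      # before the execution-time guard would have to intervene
      build_field <- function(level) {
        inflate <- level == 1L
        field <- numeric(n)
        for (j in seq_along(loose)) {
          r_block <- electrode_outer_radius(ty) +
            sc$types[[p$type[loose[j]]]]$radius + sc$safety_margin +
            if (inflate) lag_i + ws$cell_size else 0
          field <- dilate_obstacle_field(field, ws, loose_cells[j], 1, r_block)
        }
        grace_um <- 1.5 * ws$cell_size
        for (hid in names(pred)) {
          pr <- pred[[hid]]
          r_block <- electrode_outer_radius(ty) +
            electrode_outer_radius(sc$types[[pr$type]]) + sc$safety_margin
          # moving neighbours get extra clearance; parked ones are blocked
          # only to the hard threshold, otherwise goals spaced just above
          # it would be sealed off. At level 3 parked dilation shrinks by
          # the grace radius: proximity to a neighbour sitting on its own
          # goal is grace territory, and without the shrink a ring of
          # parked arrivals can seal a goal completely
          if (!pr$arrived && inflate) {
            r_block <- r_block + lag_i +
              trap_lag(sc$types[[pr$type]], sc$medium, sc$sim) + ws$cell_size
          }
          if (pr$arrived && level >= 3L) {
            r_block <- max(ws$cell_size, r_block - grace_um)
          }
          field <- dilate_obstacle_field(field, ws, pr$states, pr$weights,
                                         r_block)
        }
        # the grace pocket around the particle's own goal is never blocked:
        # goal spacing (not the planner) guarantees clearance there
        field[near_goal] <- 0
        field[gstate] <- 0
        field
      }
      solve_level <- function(level) {
        field <- build_field(level)
        occ <- which(field > 0)
        key <- paste(level, gstate, length(occ), sum(occ),
                     signif(sum(field[occ]), 12),
                     signif(sum(field[occ] * occ), 12), sep = "|")
        kid <- paste(id, level, sep = "/")
        # an unchanged planning problem (same goal, same obstacle field)
        # reuses the converged solution from the previous period
        if (identical(ctx$vkeys[[kid]], key)) return(ctx$vsol[[kid]])
        init <- init_value_function(ws, gstate, field)
        vf <- value_iteration(init, ctx$tm, eta = ctx$eta, tol = ctx$tol,
                              warm_start = ctx$vcache[[kid]])
        ctx$vcache[[kid]] <- vf$V
        ctx$vkeys[[kid]] <- key
        ctx$vsol[[kid]] <- vf
        vf
      }
      # fall back through progressively less conservative dilations when
      # the particle is enclosed (no positive-value route); the execution
      # guard still enforces physical clearance on the way
      for (level in 1:3) {
        vf <- solve_level(level)
        dec <- qmdp_action(b, vf)
        if (max(dec$scores) > 1e-9) break
      }
      act <- dec$action
      intended <- ctx$tm$T1[s_mode, act]
      replan <- FALSE
      if (intended %in% taken) {
        ord <- order(dec$scores, decreasing = TRUE)
        act <- NA_integer_
        for (a2 in ord) {
          cand <- ctx$tm$T1[s_mode, a2]
          if (!(cand %in% taken)) { act <- a2; intended <- cand; break }
        }
        if (is.na(act)) { act <- 9L; intended <- s_mode; replan <- TRUE }
        if (act == 9L && intended %in% taken) replan <- TRUE
      }
    }
    taken <- c(taken, intended)
    # predicted next-state set for lower-priority decisions
    bn <- numeric(n)
    sup <- which(b > 1e-6)
    for (s in sup) {
      bn[ctx$tm$T1[s, act]] <- bn[ctx$tm$T1[s, act]] + ctx$tm$p[1] * b[s]
      bn[ctx$tm$T2[s, act]] <- bn[ctx$tm$T2[s, act]] + ctx$tm$p[2] * b[s]
      bn[ctx$tm$T3[s, act]] <- bn[ctx$tm$T3[s, act]] + ctx$tm$p[3] * b[s]
    }
    ps <- which(bn > 0)
    pred[[as.character(id)]] <- list(states = ps, weights = bn[ps],
                                     type = p$type[i],
                                     arrived = p$status[i] == "arrived")
    out[[length(out) + 1]] <- data.frame(
      id = id, action = act, action_name = rownames(action_set())[act],
      intended_state = intended, replan = replan)
  }
  do.call(rbind, out)
}

#' Planner context shared across control periods
#'
#' Bundles the transition and observation models, discount, tolerance,
#' per-particle beliefs and the per-particle warm-start cache for value
#' iteration.
#'
#' @param ws an `oet_workspace`.
#' @param slip_prob transition slip probability.
#' @param eta discount rate.
#' @param tol value-iteration tolerance for in-the-loop replanning. The
#'   control loop uses a looser tolerance than the standalone solver
#'   default: the policy argmax is insensitive to value errors far below
#'   the cell-to-cell value differences (which are of order
#'   `(1 - eta) * V`), and the planner re-solves every period anyway.
#' @param om an `oet_observation_model`.
#' @return An environment of class `oet_planner_context`.
#' @export
planner_context <- function(ws, slip_prob = 0.1, eta = 0.95, tol = 1e-4,
                            om = observation_model()) {
  ctx <- new.env(parent = emptyenv())
  ctx$tm <- build_transition_model(ws, slip_prob)
  ctx$om <- om
  ctx$eta <- eta
  ctx$tol <- tol
  ctx$beliefs <- list()
  ctx$vcache <- list()
  ctx$vkeys <- list()
  ctx$vsol <- list()
  class(ctx) <- "oet_planner_context"
  ctx
}

#' Detect potential collisions between entities
#'
#' Flags every pair of entities whose centre distance is below the sum of
#' their effective radii plus the safety margin. By convention targets
#' contribute their electrode outer radius and free obstacles their
#' particle radius; obstacle-obstacle pairs are not monitored.
#'
#' @param positions n x 2 matrix of centres, um.
#' @param radii effective radius per entity, um.
#' @param kinds character vector, `"target"` or `"obstacle"` per entity.
#' @param safety_margin extra clearance, um.
#' @param ids entity ids (default row index).
#' @param time timestamp attached to the events.
#' @return Data frame of collision events: `time_s`, `id_a`, `id_b`,
#'   `distance_um`, `threshold_um` (empty if none).
#' @export
detect_potential_collision <- function(positions, radii, kinds, safety_margin,
                                       ids = seq_len(nrow(positions)),
                                       time = 0) {
  n <- nrow(positions)
  empty <- data.frame(time_s = numeric(0), id_a = integer(0),
                      id_b = integer(0), distance_um = numeric(0),
                      threshold_um = numeric(0))
  if (n < 2L) return(empty)
  d <- as.matrix(stats::dist(positions))
  thr <- outer(radii, radii, `+`) + safety_margin
  obs <- kinds == "obstacle"
  hit <- d < thr & upper.tri(d) & !outer(obs, obs, `&`)
  if (!any(hit)) return(empty)
  idx <- which(hit, arr.ind = TRUE)
  data.frame(time_s = time, id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
             distance_um = d[hit], threshold_um = thr[hit])
}

#' Retrap an escaped particle
#'
#' Recentres the particle's virtual electrode on its freshly detected
#' position and flips its status back to trapped. A no-op for particles
#' that are already trapped. If no position estimate is available the
#' particle is marked lost and the task continues for the others.
#'
#' @param world simulator world ([sim_world()]).
#' @param particle_id id of the escaped particle.
#' @param observed_pos detected position, um, or `NULL` if detection failed.
#' @return List: `world` (updated), `center` (new electrode centre or NULL),
#'   `event` (one-row data frame or NULL).
#' @export
retrap <- function(world, particle_id, observed_pos) {
  i <- match(particle_id, world$particles$id)
  if (is.na(i)) stop("unknown particle id")
  st <- world$particles$status[i]
  if (st == "trapped" || st == "arrived") {
    return(list(world = world, center = NULL, event = NULL))
  }
  if (is.null(observed_pos)) {
    world$particles$status[i] <- "lost"
    ev <- data.frame(time_s = world$time, event = "lost",
                     particle_id = particle_id,
                     detail = "no position estimate; particle abandoned")
    return(list(world = world, center = NULL, event = ev))
  }
  world$particles$status[i] <- "trapped"
  ev <- data.frame(time_s = world$time, event = "retrap",
                   particle_id = particle_id,
                   detail = sprintf("electrode recentered at (%.1f, %.1f)",
                                    observed_pos[1], observed_pos[2]))
  list(world = world, center = observed_pos, event = ev)
}

grace_exempt <- function(pos_a, pos_b, id_a, id_b, starts, goal_pos, grace_um) {
  near <- function(id, pos) {
    key <- as.character(id)
    (key %in% names(starts) &&
       sqrt(sum((pos - starts[[key]])^2)) <= grace_um) ||
      (key %in% names(goal_pos) &&
         sqrt(sum((pos - goal_pos[[key]])^2)) <= grace_um)
  }
  near(id_a, pos_a) || near(id_b, pos_b)
}

#' Run a complete transport task
#'
#' The full control loop: goal assignment once at the start, then per
#' control period — recompute priorities, make prioritised single-step
#' decisions, drive the electrodes toward the temporary target cells at the
#' preset speed through the stochastic simulator, monitor collisions
#' (suspending implicated particles and flagging a replan), retrap
#' escapees, and update per-particle beliefs from observations. The task
#' ends when every target is within the arrival tolerance of its goal, or
#' at the period cap.
#'
#' @param sc an `oet_scenario` (goals required).
#' @param config optional list of overrides:
#' \describe{
#'   \item{seed}{root seed (default the scenario's).}
#'   \item{max_periods}{period cap (default `50 * max(nx, ny)`).}
#'   \item{arrival_tol}{um; default half a cell.}
#'   \item{grace_cells}{start/goal grace radius in cells (default 1.5)
#'     within which sub-threshold proximity is logged but not counted.}
#'   \item{collision_buffer}{um of pre-emptive clearance; an approaching
#'     pair is suspended before it breaches the hard threshold (default 5).}
#'   \item{obs_sigma}{observation noise on detected positions, um
#'     (default 1; 0 gives exact feedback).}
#'   \item{use_vision}{run the synthetic rendering + detection + tracking
#'     chain for feedback instead of direct noisy observations.}
#'   \item{slip_prob, eta, tol}{planner parameters.}
#'   \item{substep_cap}{simulator substeps per period (default 120).}
#' }
#' @return An object of class `oet_task_log`: list with `trajectory`
#'   (data frame: time_s, particle_id, x_um, y_um, status), `events`
#'   (data frame: time_s, event, particle_id, detail), `collisions`
#'   (collision events with a `grace` flag), `summary`, `matching`,
#'   `scenario`.
#' @export
run_task <- function(sc, config = list()) {
  cfg <- utils::modifyList(list(
    seed = sc$seed, max_periods = 50L * max(sc$workspace$nx, sc$workspace$ny),
    arrival_tol = sc$workspace$cell_size / 2, grace_cells = 1.5,
    collision_buffer = 5, obs_sigma = 1, use_vision = FALSE,
    slip_prob = 0.1, eta = 0.95, tol = 1e-4, substep_cap = 120L), config)
  ws <- sc$workspace
  grace_um <- cfg$grace_cells * ws$cell_size

  matching <- assign_goals(sc)
  sc <- apply_matching(sc, matching)
  ti <- target_indices(sc)
  tids <- sc$particles$id[ti]

  world <- sim_world(sc)
  ctx <- planner_context(ws, slip_prob = cfg$slip_prob, eta = cfg$eta,
                         tol = cfg$tol)
  vis <- if (cfg$use_vision) {
    vision_state(cfg$vision_optics %||% list(pixel_size = 1, noise_sd = 0.02),
                 cell_size = ws$cell_size)
  } else NULL

  starts <- setNames(lapply(ti, function(i) c(sc$particles$x[i], sc$particles$y[i])),
                     as.character(tids))
  goal_pos <- list()
  for (id in tids) {
    g <- matching$pairs[as.character(id)]
    if (!is.na(g)) {
      gr <- match(g, sc$goals$id)
      goal_pos[[as.character(id)]] <- c(sc$goals$x[gr], sc$goals$y[gr])
    }
  }
  # per-type physics, cached once for the hot execution loop
  outer_tab <- vapply(sc$types, electrode_outer_radius, numeric(1))
  radius_tab <- vapply(sc$types, function(t) t$radius, numeric(1))
  lag_tab <- vapply(sc$types, trap_lag, numeric(1), med = sc$medium,
                    cfg = sc$sim)
  speed_tab <- vapply(sc$types, function(t) t$preset_speed, numeric(1))
  inner_tab <- vapply(sc$types, function(t) t$electrode_inner_radius,
                      numeric(1))
  width_tab <- vapply(sc$types, function(t) t$electrode_width, numeric(1))
  radii_of <- function(p) {
    ifelse(p$status == "free-obstacle", radius_tab[p$type], outer_tab[p$type])
  }
  kinds_of <- function(p) ifelse(p$status == "free-obstacle", "obstacle", "target")

  traj <- list(); events <- list(); collisions <- list()
  n_replans <- 0L; n_escapes <- 0L; n_retraps <- 0L
  centers <- setNames(lapply(ti, function(i) c(sc$particles$x[i], sc$particles$y[i])),
                      as.character(tids))

  log_state <- function(w) {
    p <- w$particles
    traj[[length(traj) + 1]] <<- data.frame(
      time_s = w$time, particle_id = p$id, x_um = p$x, y_um = p$y,
      status = p$status)
  }
  push_events <- function(ev) {
    if (!is.null(ev) && nrow(ev)) events[[length(events) + 1]] <<- ev
  }
  check_collisions <- function(w) {
    p <- w$particles
    pos <- cbind(p$x, p$y)
    ev <- detect_potential_collision(pos, radii_of(p), kinds_of(p),
                                     sc$safety_margin, ids = p$id,
                                     time = w$time)
    if (!nrow(ev)) return(ev)
    ev$grace <- vapply(seq_len(nrow(ev)), function(r) {
      ia <- match(ev$id_a[r], p$id); ib <- match(ev$id_b[r], p$id)
      grace_exempt(c(p$x[ia], p$y[ia]), c(p$x[ib], p$y[ib]),
                   ev$id_a[r], ev$id_b[r], starts, goal_pos, grace_um)
    }, logical(1))
    collisions[[length(collisions) + 1]] <<- ev
    ev
  }

  res <- with_local_seed(derive_seed(cfg$seed, "run"), {
    observe <- function(w) {
      if (cfg$use_vision) {
        est <- observe_vision(w, vis)
        if (!is.null(est)) return(est)
      }
      p <- w$particles
      noise <- if (cfg$obs_sigma > 0) {
        matrix(rnorm(2 * nrow(p), sd = cfg$obs_sigma), ncol = 2)
      } else matrix(0, nrow(p), 2)
      est <- cbind(p$x, p$y) + noise
      ext <- workspace_extent(ws)
      est[, 1] <- pmin(pmax(est[, 1], ws$origin[1] + 1e-6),
                       ws$origin[1] + ext[1] - 1e-6)
      est[, 2] <- pmin(pmax(est[, 2], ws$origin[2] + 1e-6),
                       ws$origin[2] + ext[2] - 1e-6)
      rownames(est) <- as.character(p$id)
      est
    }

    log_state(world)
    est <- observe(world)
    for (id in tids) {
      i <- match(id, world$particles$id)
      ctx$beliefs[[as.character(id)]] <-
        belief(ws, at = grid_state_of(est[as.character(id), ], ws))
    }

    period <- 0L
    completed <- FALSE
    repeat {
      # arrival bookkeeping from estimated positions
      p <- world$particles
      for (id in tids) {
        i <- match(id, p$id)
        gp <- goal_pos[[as.character(id)]]
        if (!is.null(gp) && p$status[i] %in% c("trapped", "arrived")) {
          d <- sqrt(sum((est[as.character(id), ] - gp)^2))
          if (d <= cfg$arrival_tol && p$status[i] == "trapped") {
            p$status[i] <- "arrived"
            push_events(data.frame(time_s = world$time, event = "arrived",
                                   particle_id = id, detail = ""))
          }
        }
      }
      world$particles <- p
      if (all(p$status[match(tids, p$id)] == "arrived")) {
        completed <- TRUE
        break
      }
      if (period >= cfg$max_periods) break
      period <- period + 1L

      # plan on estimated positions
      sc_est <- sc
      sc_est$particles <- world$particles
      sc_est$particles$x <- est[as.character(sc$particles$id), 1]
      sc_est$particles$y <- est[as.character(sc$particles$id), 2]
      prio <- assign_priorities(sc_est, matching)
      plan <- plan_step(sc_est, matching, prio, ctx)

      # temporary target positions per particle
      temp <- list()
      for (r in seq_len(nrow(plan))) {
        id <- plan$id[r]
        i <- match(id, world$particles$id)
        if (world$particles$status[i] == "arrived") {
          temp[[as.character(id)]] <- goal_pos[[as.character(id)]]
        } else if (world$particles$status[i] != "trapped") {
          temp[[as.character(id)]] <- NULL
        } else {
          gp <- goal_pos[[as.character(id)]]
          gstate <- grid_state_of(gp, ws)
          tgt <- if (plan$action[r] == 9L) {
            # a stay decision in the goal's neighbourhood is the final
            # fine-positioning move onto the exact goal position
            est_i <- est[as.character(id), ]
            if (sqrt(sum((est_i - gp)^2)) <= 1.5 * ws$cell_size) gp
            else centers[[as.character(id)]]
          } else if (plan$intended_state[r] == gstate) {
            gp
          } else {
            as.numeric(state_center(plan$intended_state[r], ws))
          }
          temp[[as.character(id)]] <- tgt
        }
        if (plan$replan[r]) n_replans <- n_replans + 1L
      }

      prio_rank <- setNames(seq_len(nrow(prio)), as.character(prio$id))
      suspended <- character(0)
      substep <- 0L
      repeat {
        substep <- substep + 1L
        p <- world$particles
        active <- tids[p$status[match(tids, p$id)] %in% c("trapped", "arrived")]
        active <- setdiff(active, as.integer(suspended))
        # tentative electrode moves toward the temporary targets
        tentative <- centers
        for (id in active) {
          key <- as.character(id)
          tgt <- temp[[key]]
          if (is.null(tgt)) next
          cur <- centers[[key]]
          delta <- tgt - cur
          dist <- sqrt(sum(delta^2))
          stp <- min(speed_tab[[p$type[match(id, p$id)]]] * sc$sim$timestep,
                     dist)
          if (dist > 1e-9) tentative[[key]] <- cur + delta / dist * stp
        }
        # pre-emptive guard: never let an approaching pair close below
        # threshold + buffer; the lower-priority member halts
        ids_all <- p$id
        for (idk in names(prio_rank)[order(prio_rank, decreasing = TRUE)]) {
          id <- as.integer(idk)
          if (!(id %in% active)) next
          i <- match(id, ids_all)
          ti_pos <- tentative[[idk]]
          pos_i <- c(p$x[i], p$y[i])
          # a particle in final approach to its own goal is exempt: goal
          # spacing guarantees clearance there and proximity is grace-logged
          gp_i <- goal_pos[[idk]]
          if (!is.null(gp_i) &&
              sqrt(sum((pos_i - gp_i)^2)) <= grace_um) next
          lag_i <- lag_tab[[p$type[i]]]
          out_i <- outer_tab[[p$type[i]]]
          for (j in seq_along(ids_all)) {
            if (ids_all[j] == id) next
            if (p$status[j] == "free-obstacle") {
              other <- c(p$x[j], p$y[j])
              thr <- out_i + radius_tab[[p$type[j]]] + sc$safety_margin + lag_i
            } else {
              jk <- as.character(ids_all[j])
              other <- if (!is.null(tentative[[jk]])) tentative[[jk]] else
                c(p$x[j], p$y[j])
              hard <- out_i + outer_tab[[p$type[j]]] + sc$safety_margin
              # yield early to higher-priority targets; against
              # lower-priority ones (whose own planner is responsible for
              # avoidance) only an emergency brake just above the hard
              # collision threshold applies, so clustered equals cannot
              # gridlock each other
              thr <- if (!is.na(prio_rank[jk]) &&
                         prio_rank[jk] < prio_rank[idk]) {
                hard + lag_i + lag_tab[[p$type[j]]]
              } else {
                hard + lag_i + lag_tab[[p$type[j]]] - cfg$collision_buffer + 2
              }
              # a neighbour parked at its own goal is cleared by the goal
              # spacing; approaching it is grace territory
              gp_j <- goal_pos[[jk]]
              if (!is.null(gp_j) &&
                  sqrt(sum((c(p$x[j], p$y[j]) - gp_j)^2)) <= grace_um) next
            }
            dnew <- sqrt(sum((ti_pos - other)^2))
            dold <- sqrt(sum((pos_i - other)^2))
            if (dnew < thr + cfg$collision_buffer && dnew < dold) {
              tentative[[idk]] <- centers[[idk]]
              break
            }
          }
        }
        centers <- tentative
        cmds <- if (length(active)) {
          it <- p$type[match(active, p$id)]
          ctr_m <- do.call(rbind, centers[as.character(active)])
          data.frame(particle_id = active, cx = ctr_m[, 1], cy = ctr_m[, 2],
                     inner_radius = inner_tab[it], width = width_tab[it],
                     speed = speed_tab[it])
        } else data.frame()
        world <- sim_step(world, cmds, sc$sim)
        if (nrow(world$events)) {
          esc <- world$events[world$events$event == "escape", ]
          n_escapes <- n_escapes + nrow(esc)
          push_events(world$events)
        }
        ev <- check_collisions(world)
        if (nrow(ev)) {
          hard <- ev[!ev$grace, ]
          for (r in seq_len(nrow(hard))) {
            pair <- c(hard$id_a[r], hard$id_b[r])
            ranks <- prio_rank[as.character(pair)]
            low <- pair[which.max(ifelse(is.na(ranks), -Inf, ranks))]
            if (!(as.character(low) %in% suspended)) {
              suspended <- c(suspended, as.character(low))
              n_replans <- n_replans + 1L
              push_events(data.frame(
                time_s = world$time, event = "suspend", particle_id = low,
                detail = sprintf("collision with %d; strategy redetermined",
                                 setdiff(pair, low))))
            }
          }
        }
        # period end: electrodes at targets and particles settled
        p <- world$particles
        done <- TRUE
        for (id in active) {
          key <- as.character(id)
          if (p$status[match(id, p$id)] != "trapped" &&
              p$status[match(id, p$id)] != "arrived") next
          tgt <- temp[[key]]
          if (is.null(tgt)) next
          i <- match(id, p$id)
          if (sqrt(sum((centers[[key]] - tgt)^2)) > 1e-6 ||
              sqrt(sum((c(p$x[i], p$y[i]) - centers[[key]])^2)) > 2) {
            done <- FALSE
            break
          }
        }
        if (done || substep >= cfg$substep_cap) break
      }

      # retrap escapees using fresh observations
      est <- observe(world)
      p <- world$particles
      escaped_now <- as.character(p$id[p$status == "escaped"])
      for (id in tids) {
        i <- match(id, p$id)
        if (p$status[i] == "escaped") {
          rt <- retrap(world, id, est[as.character(id), ])
          world <- rt$world
          if (!is.null(rt$center)) {
            centers[[as.character(id)]] <- rt$center
            n_retraps <- n_retraps + 1L
          }
          push_events(rt$event)
        }
      }
      # belief updates from executed actions and fresh observations
      for (r in seq_len(nrow(plan))) {
        id <- plan$id[r]
        key <- as.character(id)
        # suspended or escaped particles did not execute their command
        act <- if (key %in% suspended || key %in% escaped_now) 9L
               else plan$action[r]
        ctx$beliefs[[key]] <- update_belief(
          ctx$beliefs[[key]], act, est[key, ], ctx$tm, ctx$om)
      }
      log_state(world)
    }

    p <- world$particles
    arrived <- sum(p$status[match(tids, p$id)] == "arrived")
    coll <- if (length(collisions)) do.call(rbind, collisions) else
      data.frame(time_s = numeric(0), id_a = integer(0), id_b = integer(0),
                 distance_um = numeric(0), threshold_um = numeric(0),
                 grace = logical(0))
    list(
      trajectory = do.call(rbind, traj),
      events = if (length(events)) do.call(rbind, events) else
        data.frame(time_s = numeric(0), event = character(0),
                   particle_id = integer(0), detail = character(0)),
      collisions = coll,
      summary = list(
        arrivals = arrived, n_targets = length(tids), periods = period,
        completed = completed,
        collision_events = sum(!coll$grace),
        collision_events_grace = sum(coll$grace),
        escapes = n_escapes, retraps = n_retraps, replans = n_replans,
        assignment_converged = matching$converged,
        total_time_s = world$time),
      matching = matching, scenario = sc)
  })
  class(res) <- "oet_task_log"
  res
}

#' @export
print.oet_task_log <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<oet_task_log> %d/%d arrived in %d periods (%.1f s sim time)%s\n",
    s$arrivals, s$n_targets, s$periods, s$total_time_s,
    if (s$completed) "" else " [incomplete]"))
  cat(sprintf("  collisions: %d (+%d within start/goal grace) | escapes %d, retraps %d, replans %d\n",
              s$collision_events, s$collision_events_grace,
              s$escapes, s$retraps, s$replans))
  invisible(x)
}
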